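# Ten-zone scalp region scheme: five sites per hemisphere.

.zone_lists <- list(
  left_frontal          = c("Fp1", "AF3", "F5", "F3", "F1"),
  right_frontal         = c("Fp2", "AF4", "F6", "F4", "F2"),
  left_frontocentral    = c("FC5", "FC3", "FC1", "C5", "C3", "C1"),
  right_frontocentral   = c("FC6", "FC4", "FC2", "C6", "C4", "C2"),
  left_temporal         = c("F7", "FT7", "T7", "TP7"),
  right_temporal        = c("F8", "FT8", "T8", "TP8"),
  left_centroparietal   = c("CP5", "CP3", "CP1", "P7", "P5", "P3", "P1"),
  right_centroparietal  = c("CP6", "CP4", "CP2", "P8", "P6", "P4", "P2"),
  left_occipitoparietal = c("PO7", "PO5", "PO3", "O1"),
  right_occipitoparietal = c("PO8", "PO6", "PO4", "O2")
)

#' Ten-zone scalp region scheme
#'
#' The grouping of EEG channels used for reporting connectivity changes:
#' frontal, frontocentral, temporal, centroparietal and occipitoparietal
#' sites, separately for the left and right hemisphere. Midline and auxiliary
#' channels belong to no zone.
#'
#' @return Named list of 10 character vectors (class `snn_region_scheme`).
#' @export
#' @examples
#' region_scheme()$left_centroparietal
region_scheme <- function() {
  structure(.zone_lists, class = "snn_region_scheme")
}

#' Zone membership of an electrode
#'
#' @param label channel name present in the montage.
#' @param scheme a region scheme, from [region_scheme()].
#' @param montage montage used to validate `label`; default montage if `NULL`.
#' @return The zone name, or `"unassigned"` for montage channels (midline,
#'   auxiliary) outside every zone.
#' @export
#' @examples
#' electrode_zone("P3")
#' electrode_zone("Fp2")
electrode_zone <- function(label, scheme = region_scheme(), montage = NULL) {
  montage <- montage %||% make_default_montage()
  if (!label %in% montage$labels)
    stop("unknown channel label: ", label)
  hit <- vapply(scheme, function(z) label %in% z, logical(1))
  if (!any(hit)) return("unassigned")
  names(scheme)[which(hit)]
}

zone_hemisphere <- function(zone) {
  if (startsWith(zone, "left_")) "left"
  else if (startsWith(zone, "right_")) "right"
  else NA_character_
}
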