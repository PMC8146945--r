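# Scalp montage: channel labels plus 3D template-space coordinates.

# Idealized spherical 10-10 layout. Each label is placed on a unit sphere from
# two angles -- a sagittal angle (degrees from vertex, positive towards nasion)
# set by its row letter, and a lateral angle set by its numeric index -- then
# projected onto the template ellipsoid (semi-axes 70 x 85 x 65 mm; x right,
# y anterior, z superior).
.row_angle <- c(Fp = 72, AF = 54, F = 36, FC = 18, C = 0,
                CP = -18, P = -36, PO = -54, O = -72, I = -90)
.lat_angle <- c("0" = 0, "1" = 18, "2" = 18, "3" = 36, "4" = 36,
                "5" = 54, "6" = 54, "7" = 72, "8" = 72)
.ellipsoid_axes <- c(x = 70, y = 85, z = 65)

# T/FT/TP sit on the C/FC/CP rows at the outermost (72 deg) lateral position.
.label_position <- function(label) {
  if (label %in% c("AUX1", "AUX2")) {
    return(c(if (label == "AUX1") -80 else 80, -20, -40))
  }
  if (grepl("z$", label)) {
    row <- sub("z$", "", label)
    k <- 0L
  } else {
    m <- regmatches(label, regexec("^([A-Za-z]+)([0-9]+)$", label))[[1]]
    if (length(m) != 3L) stop("cannot parse electrode label: ", label)
    row <- m[2]
    k <- as.integer(m[3])
  }
  row <- switch(row, T = "C", FT = "FC", TP = "CP", row)
  if (!row %in% names(.row_angle)) stop("unknown electrode row in label: ", label)
  s <- .row_angle[[row]] * pi / 180
  L <- if (k == 0L) 0 else .lat_angle[[as.character(k)]] * pi / 180
  side <- if (k == 0L) 0 else if (k %% 2L == 1L) -1 else 1
  p <- c(side * cos(s) * sin(L), sin(s), cos(s) * cos(L))
  p * .ellipsoid_axes
}

.midline_labels <- c("Fpz", "AFz", "Fz", "FCz", "Cz", "CPz", "Pz", "POz", "Oz", "Iz")
.extra_labels <- c("AF7", "AF8")
.aux_labels <- c("AUX1", "AUX2")

#' Default 66-channel scalp montage
#'
#' Builds the recording montage used throughout the package: 64 cap electrodes
#' laid out on the international 10-10 grid (all electrodes of the ten scalp
#' zones, the ten midline sites and AF7/AF8) plus two auxiliary surface
#' channels (`AUX1`, `AUX2`) that take part in recording but not in zone
#' aggregation. Positions are idealized spherical 10-10 coordinates projected
#' onto the template ellipsoid, in mm (x right, y anterior, z superior).
#'
#' @return An object of class `snn_montage`: a list with `labels` (character,
#'   length 66) and `positions` (66 x 3 numeric matrix, rownames = labels).
#' @export
#' @examples
#' m <- make_default_montage()
#' length(m$labels)
make_default_montage <- function() {
  zone_labels <- unlist(region_scheme(), use.names = FALSE)
  labels <- c(zone_labels, .midline_labels, .extra_labels, .aux_labels)
  pos <- t(vapply(labels, .label_position, numeric(3)))
  colnames(pos) <- c("x", "y", "z")
  montage(labels, pos)
}

#' Construct a montage
#'
#' @param labels character vector of unique channel names.
#' @param positions numeric matrix, one xyz row (mm) per label.
#' @return `snn_montage` object.
#' @export
montage <- function(labels, positions) {
  labels <- as.character(labels)
  positions <- as.matrix(positions)
  if (anyDuplicated(labels)) stop("montage labels must be unique")
  if (nrow(positions) != length(labels))
    stop("positions must have one row per label")
  if (ncol(positions) != 3L) stop("positions must have 3 columns (x, y, z)")
  rownames(positions) <- labels
  structure(list(labels = labels, positions = positions),
            class = "snn_montage")
}

#' @export
print.snn_montage <- function(x, ...) {
  cat("<snn_montage> ", length(x$labels), " channels: ",
      paste(utils::head(x$labels, 6), collapse = ", "), ", ...\n", sep = "")
  invisible(x)
}

#' Write / read a montage as plain text
#'
#' Serialized as whitespace-delimited `label x y z` rows.
#'
#' @param montage an `snn_montage`.
#' @param path file path.
#' @return `read_montage` returns an `snn_montage`; `write_montage` returns
#'   `path` invisibly.
#' @export
write_montage <- function(montage, path) {
  df <- data.frame(label = montage$labels, montage$positions,
                   check.names = FALSE)
  write.table(df, path, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_montage
#' @export
read_montage <- function(path) {
  df <- read.table(path, header = FALSE,
                   col.names = c("label", "x", "y", "z"))
  montage(df$label, as.matrix(df[, c("x", "y", "z")]))
}
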