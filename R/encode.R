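# Step Forward (SF) spike encoding: fixed threshold, moving baseline.

#' Encoder parameters
#'
#' @param sf_threshold per-channel amplitude threshold(s) SFthr (microvolts,
#'   > 0); recycled across channels. Ignored when `optimize = TRUE`.
#' @param baseline_init baseline initialization rule: the channel's first
#'   sample (default) or its mean.
#' @param optimize if `TRUE`, pick per-channel thresholds from
#'   `candidate_grid` by reconstruction RMSE before encoding.
#' @param candidate_grid thresholds scanned during optimization, as multiples
#'   of each channel's standard deviation. Default: 21 log-spaced values in
#'   [0.01, 1].
#' @return `snn_encoder_params` object.
#' @export
encoder_params <- function(sf_threshold = 0.1,
                           baseline_init = c("first-sample", "mean"),
                           optimize = FALSE,
                           candidate_grid = exp(seq(log(0.01), log(1),
                                                    length.out = 21))) {
  baseline_init <- match.arg(baseline_init)
  if (any(sf_threshold <= 0)) stop("sf_threshold must be > 0")
  if (optimize && !length(candidate_grid)) stop("candidate grid is empty")
  structure(list(sf_threshold = sf_threshold, baseline_init = baseline_init,
                 optimize = optimize, candidate_grid = candidate_grid),
            class = "snn_encoder_params")
}

.baseline0 <- function(x, rule) {
  if (rule == "mean") rowMeans(x) else x[, 1]
}

#' Encode a recording into ternary spike trains
#'
#' Per channel, starting from baseline B0: at each sample, if the signal rises
#' more than SFthr above the baseline a positive spike is emitted and the
#' baseline steps up by SFthr; if it falls more than SFthr below, a negative
#' spike is emitted and the baseline steps down; otherwise no spike. At most
#' one spike (and one baseline step) per sample.
#'
#' @param recording an [eeg_recording()] (finite-valued).
#' @param params an [encoder_params()].
#' @return `snn_spike_raster`: list with `spikes` (channels x samples integer
#'   matrix in \{-1, 0, +1\}), `rate`, `params` (including the per-channel
#'   `thresholds` and `baseline0` actually used) and `montage`.
#' @export
#' @examples
#' rec <- eeg_recording(matrix(c(0, 0.6, 0.3, 1.2), 1,
#'                             dimnames = list("C1", NULL)), rate = 256)
#' sf_encode(rec, encoder_params(sf_threshold = 0.5))$spikes
sf_encode <- function(recording, params = encoder_params()) {
  stopifnot(inherits(recording, "eeg_recording"))
  x <- recording$data
  bad <- which(!is.finite(x), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-finite value in channel %s at sample %d",
                 rownames(x)[bad[1, 1]] %||% bad[1, 1], bad[1, 2]))
  n_ch <- nrow(x)
  if (params$optimize) {
    params <- optimize_threshold(recording,
                                 grid = params$candidate_grid,
                                 baseline_init = params$baseline_init,
                                 relative = TRUE)
  }
  thr <- rep_len(params$sf_threshold, n_ch)
  b0 <- .baseline0(x, params$baseline_init)
  enc <- sf_encode_core(x, thr, b0)
  spikes <- enc$spikes
  dimnames(spikes) <- dimnames(x)
  params$thresholds <- thr
  params$baseline0 <- b0
  structure(list(spikes = spikes, rate = recording$rate, params = params,
                 montage = recording$montage,
                 condition = recording$condition),
            class = "snn_spike_raster")
}

#' @export
print.snn_spike_raster <- function(x, ...) {
  cat(sprintf("<snn_spike_raster> %d ch x %d samples, %d spikes (%d+/%d-)\n",
              nrow(x$spikes), ncol(x$spikes), sum(x$spikes != 0),
              sum(x$spikes > 0), sum(x$spikes < 0)))
  invisible(x)
}

#' Decode a spike raster back to its baseline trajectory
#'
#' The inverse of the SF rule: the reconstruction is the moving baseline,
#' `B(n) = B0 + SFthr * cumsum(spikes)`. When per-sample signal increments do
#' not exceed SFthr, `|x(n) - B(n)| <= SFthr` for all n.
#'
#' @param raster an `snn_spike_raster` from [sf_encode()].
#' @return Channels x samples matrix of reconstructed values.
#' @export
sf_decode <- function(raster) {
  stopifnot(inherits(raster, "snn_spike_raster"))
  thr <- raster$params$thresholds %||%
    rep_len(raster$params$sf_threshold, nrow(raster$spikes))
  b0 <- raster$params$baseline0
  if (is.null(b0)) stop("raster lacks the encoder's initial baselines")
  out <- raster$spikes * 0.0
  for (c in seq_len(nrow(out)))
    out[c, ] <- b0[c] + thr[c] * cumsum(raster$spikes[c, ])
  out
}

#' Optimize SF thresholds by reconstruction error
#'
#' For each channel, scans a grid of candidate thresholds and keeps the one
#' minimizing the RMSE between the signal and its decoded baseline
#' trajectory. Ties break deterministically to the smaller threshold.
#'
#' @param recording an [eeg_recording()].
#' @param grid positive candidate thresholds (at least 2). If
#'   `relative = TRUE` they are multiples of each channel's standard
#'   deviation, otherwise absolute microvolts.
#' @param baseline_init baseline rule, as in [encoder_params()].
#' @param relative interpret the grid relative to channel SD (default).
#' @return An [encoder_params()] whose `sf_threshold` holds the per-channel
#'   winners, with the achieved `rmse` attached.
#' @export
optimize_threshold <- function(recording,
                               grid = exp(seq(log(0.01), log(1),
                                              length.out = 21)),
                               baseline_init = "first-sample",
                               relative = TRUE) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (length(grid) < 2) stop("candidate grid needs at least 2 thresholds")
  if (any(grid <= 0)) stop("candidate thresholds must be > 0")
  grid <- sort(grid)
  x <- recording$data
  b0 <- .baseline0(x, baseline_init)
  n_ch <- nrow(x)
  thr <- numeric(n_ch); best_rmse <- numeric(n_ch)
  for (c in seq_len(n_ch)) {
    scale <- if (relative) stats::sd(x[c, ]) else 1
    if (!is.finite(scale) || scale == 0) scale <- 1
    cand <- grid * scale
    rmse <- sf_grid_rmse(x[c, ], cand, b0[c])
    k <- which.min(rmse)           # ascending grid => smallest-threshold tie-break
    thr[c] <- cand[k]; best_rmse[c] <- rmse[k]
  }
  out <- encoder_params(sf_threshold = thr, baseline_init = baseline_init,
                        optimize = FALSE, candidate_grid = grid)
  out$rmse <- best_rmse
  out
}
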