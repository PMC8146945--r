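# Synthetic EEG with planted lagged couplings.
#
# The generative model is deliberately simple: seeded Gaussian noise per
# channel (optionally 1/f-shaped) plus linear lagged mixing along a set of
# planted directed edges, x_t(n) = noise_t(n) + sum_e g_e * x_s(n - L_e).
# This is the minimal spatiotemporal structure that spike-timing-based
# connectivity learning should be able to recover, and the planted layout is
# carried as metadata so recovery can be scored.

.conditions <- c("Pre", "Sound1", "Sound2", "Sound3", "Post", "Post3Month")

#' Condition levels of the recording schedule
#'
#' Quiet baseline, three windows during the one-hour stepped-morphing file
#' (first, middle and last 10 minutes), quiet immediately after, and quiet at
#' the three-month follow-up.
#' @return Character vector of the six condition names, in schedule order.
#' @export
condition_levels <- function() .conditions

#' Specify planted lagged couplings
#'
#' @param edges data.frame with columns `source`, `target` (channel labels),
#'   `lag` (samples, >= 1) and `gain` (unitless). May have zero rows.
#' @param noise_sd per-channel noise standard deviation (microvolts).
#' @param seed integer seed controlling noise generation.
#' @return `snn_coupling_spec` object.
#' @export
coupling_spec <- function(edges = NULL, noise_sd = 0.1, seed = 1L) {
  if (is.null(edges))
    edges <- data.frame(source = character(), target = character(),
                        lag = integer(), gain = numeric())
  edges <- as.data.frame(edges)
  stopifnot(all(c("source", "target", "lag", "gain") %in% names(edges)))
  if (nrow(edges)) {
    if (any(edges$lag < 1)) stop("coupling lags must be >= 1 sample")
    if (any(!is.finite(edges$gain))) stop("coupling gains must be finite")
    if (any(edges$source == edges$target)) stop("self-couplings not allowed")
  }
  stop_if_not_scalar_number(noise_sd, "noise_sd")
  structure(list(edges = edges, noise_sd = noise_sd, seed = as.integer(seed)),
            class = "snn_coupling_spec")
}

#' Condition profile for simulation
#'
#' @param condition one of [condition_levels()].
#' @param coupling an `snn_coupling_spec`.
#' @param duration segment duration in seconds.
#' @return `snn_condition_profile` object.
#' @export
condition_profile <- function(condition, coupling = coupling_spec(),
                              duration = 60) {
  condition <- match.arg(condition, .conditions)
  stop_if_not_scalar_number(duration, "duration", positive = TRUE)
  structure(list(condition = condition, coupling = coupling,
                 duration = duration),
            class = "snn_condition_profile")
}

#' EEG recording container
#'
#' @param data channels x samples numeric matrix; rownames are channel labels.
#' @param rate sampling rate in Hz.
#' @param condition condition tag (free string, typically a condition level).
#' @param montage the `snn_montage` the channels follow.
#' @return `eeg_recording` object.
#' @export
eeg_recording <- function(data, rate, condition = NA_character_,
                          montage = NULL) {
  data <- as.matrix(data)
  if (is.null(rownames(data))) stop("recording data needs channel rownames")
  stop_if_not_scalar_number(rate, "rate", positive = TRUE)
  structure(list(data = data, rate = rate, condition = condition,
                 montage = montage),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d ch x %d samples @ %g Hz, condition = %s\n",
              nrow(x$data), ncol(x$data), x$rate, x$condition))
  invisible(x)
}

.gen_noise <- function(n_ch, n_samp, noise_sd, seed, pink = FALSE) {
  with_seed(seed, {
    noise <- matrix(rnorm(n_ch * n_samp, sd = noise_sd), nrow = n_ch)
    if (pink) {
      # 1/f amplitude shaping in the frequency domain, per channel
      for (ch in seq_len(n_ch)) {
        sp <- fft(noise[ch, ])
        f <- c(1, seq_len(n_samp - 1))
        f <- pmin(f, n_samp - f + 1)      # symmetric frequency index
        sp <- sp / sqrt(f)
        x <- Re(fft(sp, inverse = TRUE)) / n_samp
        noise[ch, ] <- x * (noise_sd / stats::sd(x))
      }
    }
    noise
  })
}

.apply_coupling <- function(x, edges, labels) {
  if (!nrow(edges)) return(x)
  unknown <- setdiff(unique(c(edges$source, edges$target)), labels)
  if (length(unknown))
    stop("coupling edges reference unknown channel(s): ",
         paste(unknown, collapse = ", "))
  n <- ncol(x)
  # Topological order over the channel-dependency graph when acyclic lets us
  # use vectorized shift-adds; lags >= 1 keep a cyclic system causal, so fall
  # back to a per-sample sweep otherwise.
  nodes <- unique(c(edges$source, edges$target))
  order_ok <- character(0)
  remaining <- nodes
  repeat {
    free <- remaining[vapply(remaining, function(t)
      !any(edges$target == t & edges$source %in% remaining), logical(1))]
    if (!length(free)) break
    order_ok <- c(order_ok, free)
    remaining <- setdiff(remaining, free)
    if (!length(remaining)) break
  }
  if (!length(remaining)) {
    for (t_lab in order_ok) {
      sub <- edges[edges$target == t_lab, , drop = FALSE]
      if (!nrow(sub)) next
      ti <- match(t_lab, labels)
      for (k in seq_len(nrow(sub))) {
        si <- match(sub$source[k], labels)
        L <- sub$lag[k]
        if (L < n)
          x[ti, (L + 1):n] <- x[ti, (L + 1):n] + sub$gain[k] * x[si, 1:(n - L)]
      }
    }
  } else {
    tgt <- match(edges$target, labels)
    src <- match(edges$source, labels)
    for (nn in seq_len(n)) {
      for (k in seq_along(tgt)) {
        if (edges$lag[k] < nn)
          x[tgt[k], nn] <- x[tgt[k], nn] +
            edges$gain[k] * x[src[k], nn - edges$lag[k]]
      }
    }
  }
  x
}

#' Simulate one EEG condition segment
#'
#' Seeded Gaussian noise per channel with planted lagged linear couplings:
#' every edge (s -> t, lag L, gain g) contributes `g * x_s(n - L)` to channel
#' t. Identical seed and profile give bit-identical output.
#'
#' @param profile an `snn_condition_profile`.
#' @param montage recording montage (defaults to [make_default_montage()]).
#' @param rate sampling rate in Hz (the acquisition profile uses 8192 or 256).
#' @param pink if `TRUE`, shape the noise spectrum as 1/f; default white.
#' @param noise optional pre-generated channels x samples noise matrix
#'   (shared background across conditions); overrides seeded generation.
#' @return An [eeg_recording()].
#' @export
#' @examples
#' prof <- condition_profile("Pre", coupling_spec(noise_sd = 1), duration = 2)
#' rec <- simulate_recording(prof, rate = 256)
#' dim(rec$data)
simulate_recording <- function(profile, montage = make_default_montage(),
                               rate = 256, pink = FALSE, noise = NULL) {
  stopifnot(inherits(profile, "snn_condition_profile"))
  n_ch <- length(montage$labels)
  n_samp <- round(profile$duration * rate)
  cs <- profile$coupling
  if (is.null(noise)) {
    noise <- .gen_noise(n_ch, n_samp, cs$noise_sd, cs$seed, pink = pink)
  } else {
    stopifnot(nrow(noise) == n_ch, ncol(noise) == n_samp)
  }
  rownames(noise) <- montage$labels
  x <- .apply_coupling(noise, cs$edges, montage$labels)
  eeg_recording(x, rate = rate, condition = profile$condition,
                montage = montage)
}

# Fixed planted layouts: lateral temporo-parietal sites, mirrored across
# hemispheres. Lateral (rather than para-midline) electrodes keep the two
# hemispheres' coupling neighbourhoods separated at grid resolution, and
# match the scalp sites where the acute-protocol changes are reported.
.left_edges <- data.frame(
  source = c("CP5", "P7", "TP7", "P5"),
  target = c("P5", "PO7", "P7", "PO7"),
  lag = c(2L, 3L, 4L, 5L),
  gain = NA_real_)
.right_edges <- data.frame(
  source = c("CP6", "P8", "TP8", "P6"),
  target = c("P6", "PO8", "P8", "PO8"),
  lag = c(2L, 3L, 4L, 5L),
  gain = NA_real_)

.condition_edges <- function(condition, gain) {
  e <- switch(condition,
    Pre        = .left_edges[0, ],
    Sound1     = .left_edges,
    Sound2     = rbind(.left_edges[1:2, ], .right_edges[1:2, ]),
    Sound3     = rbind(.left_edges, .right_edges),
    Post       = .right_edges,
    Post3Month = .right_edges)
  if (nrow(e)) e$gain <- gain
  e
}

#' Study fixture: six condition recordings with planted couplings
#'
#' Generates the six-condition recording set that emulates the acute study
#' design: one shared seeded noise background, on top of which each condition
#' has its own planted lagged couplings. Sound1 plants left-posterior edges
#' only, Sound2/Sound3 bilateral edges, Post and Post3Month right-posterior
#' edges only; Pre is pure noise. The planted layout (including the zone of
#' each endpoint) is returned as metadata for recovery scoring.
#'
#' @param seed integer seed (noise only; the edge topology is fixed).
#' @param duration per-condition duration in seconds. Desk-scale default 60;
#'   the acquisition protocol's segments are 600.
#' @param rate sampling rate in Hz.
#' @param gain coupling gain for every planted edge.
#' @param noise_sd noise standard deviation (microvolts).
#' @param conditions subset of [condition_levels()] to generate.
#' @param pink 1/f-shaped noise if `TRUE`.
#' @return `snn_fixture`: list with `recordings` (named list of
#'   [eeg_recording()]), `planted` (named list of edge data.frames with
#'   `source_zone`/`target_zone` columns), `montage` and `seed`.
#' @export
#' @examples
#' fx <- make_study_fixture(seed = 1, duration = 2,
#'                          conditions = c("Pre", "Sound1"))
#' names(fx$recordings)
make_study_fixture <- function(seed = 1L, duration = 60, rate = 256,
                               gain = 0.9, noise_sd = 0.1,
                               conditions = condition_levels(),
                               pink = FALSE) {
  conditions <- match.arg(conditions, .conditions, several.ok = TRUE)
  conditions <- .conditions[.conditions %in% conditions]
  montage <- make_default_montage()
  n_samp <- round(duration * rate)
  base_noise <- .gen_noise(length(montage$labels), n_samp, noise_sd,
                           seed, pink = pink)
  scheme <- region_scheme()
  recs <- list(); planted <- list()
  for (cond in conditions) {
    edges <- .condition_edges(cond, gain)
    prof <- condition_profile(cond,
                              coupling_spec(edges, noise_sd = noise_sd,
                                            seed = as.integer(seed)),
                              duration = duration)
    recs[[cond]] <- simulate_recording(prof, montage, rate = rate,
                                       noise = base_noise)
    if (nrow(edges)) {
      edges$source_zone <- vapply(edges$source, electrode_zone, character(1),
                                  scheme = scheme, montage = montage)
      edges$target_zone <- vapply(edges$target, electrode_zone, character(1),
                                  scheme = scheme, montage = montage)
    } else {
      edges$source_zone <- character(0); edges$target_zone <- character(0)
    }
    planted[[cond]] <- edges
  }
  structure(list(recordings = recs, planted = planted, montage = montage,
                 seed = as.integer(seed)),
            class = "snn_fixture")
}
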