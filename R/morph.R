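# Tinnitus-avatar synthesis and stepped cross-fade morphing.

.bandwidth_ladder <- c(0, 1/24, 1/12, 1/6, 1/3, 1/2, 1, 2, 3, 4)

#' Tinnitus avatar parameters
#'
#' Psychoacoustic match of an individual's tinnitus percept: pitch in
#' half-octave-matched Hz between 250 and 16000, bandwidth from the octave
#' ladder 0, 1/24, 1/12, 1/6, 1/3, 1/2, 1, 2, 3, 4, relative RMS level, and a
#' stereo balance in `[-1, 1]` standing in for perceived location.
#'
#' @param pitch centre frequency (Hz), in `[250, 16000]`.
#' @param bandwidth octaves, one of the ladder values.
#' @param level target RMS (unitless, > 0).
#' @param balance stereo pan in `[-1, 1]` (-1 left, +1 right, 0 centre).
#' @return `snn_avatar_spec` object.
#' @export
avatar_spec <- function(pitch, bandwidth = 0, level = 0.1, balance = 0) {
  stop_if_not_scalar_number(pitch, "pitch")
  if (pitch < 250 || pitch > 16000)
    stop("avatar pitch must lie in [250, 16000] Hz")
  if (!any(abs(bandwidth - .bandwidth_ladder) < 1e-12))
    stop("bandwidth must be one of the ladder values: ",
         paste(round(.bandwidth_ladder, 4), collapse = ", "))
  stop_if_not_scalar_number(level, "level", positive = TRUE)
  if (abs(balance) > 1) stop("balance must lie in [-1, 1]")
  structure(list(pitch = pitch, bandwidth = bandwidth, level = level,
                 balance = balance),
            class = "snn_avatar_spec")
}

#' Synthesize a tinnitus avatar waveform
#'
#' Bandwidth 0 gives a pure sinusoid at the pitch; positive bandwidth b gives
#' Gaussian noise band-limited to `[pitch * 2^(-b/2), pitch * 2^(b/2)]`
#' (geometric centre = pitch). The output is scaled so that its total RMS
#' (power summed over both stereo channels) equals `level`, and panned with an
#' equal-power law.
#'
#' @param spec an `snn_avatar_spec`.
#' @param rate sample rate (Hz). If below four times the upper band edge the
#'   band is clipped at Nyquist with a warning.
#' @param duration seconds.
#' @param seed integer seed for the noise phase.
#' @return Numeric matrix, samples x 2 (left, right), class `snn_waveform`
#'   with attribute `rate`.
#' @export
#' @examples
#' w <- synthesize_avatar(avatar_spec(1000, 1), rate = 8000, duration = 0.5)
#' dim(w)
synthesize_avatar <- function(spec, rate, duration, seed = 1L) {
  stopifnot(inherits(spec, "snn_avatar_spec"))
  n <- round(rate * duration)
  f_hi <- spec$pitch * 2^(spec$bandwidth / 2)
  f_lo <- spec$pitch * 2^(-spec$bandwidth / 2)
  if (rate < 4 * f_hi) {
    if (f_lo >= rate / 2)
      stop("sample rate too low: entire avatar band is above Nyquist")
    warning("sample rate < 4x upper band edge; band clipped at Nyquist")
    f_hi <- min(f_hi, rate / 2)
  }
  if (spec$bandwidth == 0) {
    mono <- sin(2 * pi * spec$pitch * seq_len(n) / rate)
  } else {
    mono <- with_seed(seed, rnorm(n))
    mono <- band_filter(mono, rate, f_lo, f_hi)
  }
  mono <- mono * (spec$level / sqrt(mean(mono^2)))
  theta <- (spec$balance + 1) * pi / 4
  wav <- cbind(left = cos(theta) * mono, right = sin(theta) * mono)
  structure(wav, rate = rate, class = c("snn_waveform", class(wav)))
}

#' Brick-wall band-pass filter via FFT
#'
#' @param x numeric vector.
#' @param rate sample rate (Hz).
#' @param f_lo,f_hi band edges (Hz); bins outside `[f_lo, f_hi]` are zeroed.
#' @return Filtered vector.
#' @export
band_filter <- function(x, rate, f_lo, f_hi) {
  n <- length(x)
  sp <- fft(x)
  f <- (seq_len(n) - 1) * rate / n
  f <- pmin(f, rate - f)          # fold to [0, rate/2]
  sp[f < f_lo | f > f_hi] <- 0+0i
  Re(fft(sp, inverse = TRUE)) / n
}

#' Morph schedule
#'
#' A piecewise avatar-vs-environment intensity-ratio function over the
#' duration of a sound file. Segments must tile `[0, duration]` without gaps
#' or overlap; evaluation is right-continuous at boundaries.
#'
#' @param duration seconds.
#' @param segments data.frame with columns `start`, `end`, `r0`, `r1`
#'   (avatar intensity ratio at segment start/end, in `[0, 1]`) and `interp`
#'   (`"constant"` or `"linear"`).
#' @return `snn_morph_schedule` object.
#' @export
morph_schedule <- function(duration, segments) {
  segments <- as.data.frame(segments)
  stopifnot(all(c("start", "end", "r0", "r1", "interp") %in% names(segments)))
  segments <- segments[order(segments$start), ]
  if (abs(segments$start[1]) > 1e-9 ||
      abs(segments$end[nrow(segments)] - duration) > 1e-9 ||
      (nrow(segments) > 1 &&
       any(abs(segments$end[-nrow(segments)] - segments$start[-1]) > 1e-9)))
    stop("segments must tile [0, duration] without gaps or overlap")
  if (any(segments$r0 < 0 | segments$r0 > 1 | segments$r1 < 0 | segments$r1 > 1))
    stop("intensity ratios must lie in [0, 1]")
  structure(list(duration = duration, segments = segments),
            class = "snn_morph_schedule")
}

#' Evaluate a morph schedule
#'
#' @param schedule an `snn_morph_schedule`.
#' @param t times in seconds (vectorized).
#' @return Avatar intensity ratio r(t) in `[0, 1]`.
#' @export
#' @examples
#' schedule_ratio(acute_schedule(), c(300, 1800, 3500))
schedule_ratio <- function(schedule, t) {
  seg <- schedule$segments
  vapply(t, function(tt) {
    if (tt < 0 || tt > schedule$duration + 1e-9)
      stop("time outside schedule duration")
    i <- findInterval(tt, seg$start)       # right-continuous
    i <- max(1L, min(i, nrow(seg)))
    if (tt >= seg$end[nrow(seg)] - 1e-12) i <- nrow(seg)
    s <- seg[i, ]
    if (s$interp == "constant" || s$end == s$start) {
      if (tt >= s$end - 1e-12 && s$interp == "linear") s$r1 else s$r0
    } else {
      s$r0 + (s$r1 - s$r0) * min(1, (tt - s$start) / (s$end - s$start))
    }
  }, numeric(1))
}

#' Acute (one-hour) stepped-morphing schedule
#'
#' The avatar holds a 90% intensity share for the first 10 minutes, decreases
#' steadily (linearly) to 10% across the middle 40 minutes — passing 50% at
#' the half-hour mark — and holds 10% for the last 10 minutes.
#'
#' @return `snn_morph_schedule` of duration 3600 s.
#' @export
acute_schedule <- function() {
  morph_schedule(3600, data.frame(
    start = c(0, 600, 3000),
    end   = c(600, 3000, 3600),
    r0    = c(0.90, 0.90, 0.10),
    r1    = c(0.90, 0.10, 0.10),
    interp = c("constant", "linear", "constant")))
}

#' Chronic trial schedule ladder
#'
#' Four one-hour versions used across the three-month trial: (1) constant
#' 100% avatar, (2) 100% to 50%, (3) 50% to 10%, (4) 10% to 0% (pure
#' environmental sound), each morphing linearly over the hour.
#'
#' @return List of four `snn_morph_schedule`s.
#' @export
chronic_schedules <- function() {
  mk <- function(r0, r1, interp = "linear")
    morph_schedule(3600, data.frame(start = 0, end = 3600, r0 = r0, r1 = r1,
                                    interp = interp))
  list(mk(1.0, 1.0, "constant"), mk(1.0, 0.5), mk(0.5, 0.1), mk(0.1, 0.0))
}

#' Render a stepped-morphing file
#'
#' Cross-fades the avatar stem into the environment stem so that the avatar's
#' share of output *power* follows the schedule: the amplitude weights are
#' `sqrt(r(t))` and `sqrt(1 - r(t))`. Stems should be normalized to equal
#' long-term RMS beforehand (see [equalize_rms()]).
#'
#' @param avatar,environment numeric vectors (mono) or samples x 2 matrices,
#'   equal length and rate.
#' @param schedule an `snn_morph_schedule` covering the stems' duration.
#' @param rate sample rate (Hz).
#' @return Waveform of the same shape as the stems, class `snn_waveform`.
#' @export
render_morph <- function(avatar, environment, schedule, rate) {
  a <- as.matrix(avatar); e <- as.matrix(environment)
  if (!all(dim(a) == dim(e))) stop("stems must have identical length/shape")
  r_a <- attr(avatar, "rate"); r_e <- attr(environment, "rate")
  if (!is.null(r_a) && !is.null(r_e) && r_a != r_e)
    stop("stems must share one sample rate")
  n <- nrow(a)
  tt <- (seq_len(n) - 1) / rate
  if (n / rate > schedule$duration + 1e-6)
    stop("stems are longer than the schedule")
  r <- schedule_ratio_fast(schedule, tt)
  out <- sqrt(r) * a + sqrt(1 - r) * e
  structure(out, rate = rate, class = c("snn_waveform", class(out)))
}

# Vectorized schedule evaluation used by the renderer (same semantics as
# schedule_ratio, without the per-element overhead).
schedule_ratio_fast <- function(schedule, t) {
  seg <- schedule$segments
  i <- findInterval(t, seg$start)
  i[i < 1L] <- 1L; i[i > nrow(seg)] <- nrow(seg)
  r0 <- seg$r0[i]; r1 <- seg$r1[i]
  s0 <- seg$start[i]; s1 <- seg$end[i]
  lin <- seg$interp[i] == "linear" & s1 > s0
  frac <- ifelse(lin, pmin(1, pmax(0, (t - s0) / (s1 - s0))), 0)
  r0 + (r1 - r0) * frac
}

#' Equalize stems to a common long-term RMS
#'
#' @param ... waveforms (vectors or samples x channel matrices).
#' @param rms target RMS (total across channels); default 0.1.
#' @return List of rescaled waveforms.
#' @export
equalize_rms <- function(..., rms = 0.1) {
  lapply(list(...), function(w) {
    m <- as.matrix(w)
    scale <- rms / sqrt(mean(rowSums(m^2)))
    out <- m * scale
    attr(out, "rate") <- attr(w, "rate")
    out
  })
}

#' Avatar power share of a rendered morph
#'
#' Measures, over a time window, the fraction of output power that falls in
#' the avatar's spectral band — the measurement behind the intensity-ratio
#' checks, valid when the two stems occupy disjoint bands.
#'
#' @param mix rendered waveform (vector or samples x channels).
#' @param rate sample rate (Hz).
#' @param window `c(t0, t1)` seconds.
#' @param avatar_band,env_band `c(f_lo, f_hi)` Hz for each stem.
#' @return Avatar share of total (avatar + environment band) power, in
#'   percent.
#' @export
avatar_power_share <- function(mix, rate, window, avatar_band, env_band) {
  m <- as.matrix(mix)
  i0 <- max(1L, floor(window[1] * rate) + 1L)
  i1 <- min(nrow(m), floor(window[2] * rate))
  band_power <- function(band) {
    p <- 0
    for (ch in seq_len(ncol(m))) {
      x <- m[i0:i1, ch]
      sp <- Mod(fft(x))^2
      n <- length(x)
      f <- (seq_len(n) - 1) * rate / n
      f <- pmin(f, rate - f)
      p <- p + sum(sp[f >= band[1] & f <= band[2]])
    }
    p
  }
  pa <- band_power(avatar_band); pe <- band_power(env_band)
  100 * pa / (pa + pe)
}
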