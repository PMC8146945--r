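# Recording readers/writers (TSV, EDF 16-bit, BDF 24-bit) and downsampling.
# EDF/BDF are written with a single data record covering the whole segment;
# the condition tag travels in the recording-identification header field.

.pad <- function(x, n) {
  s <- substr(as.character(x), 1, n)
  paste0(s, strrep(" ", n - nchar(s)))
}

.fmt_num <- function(x, n) .pad(formatC(x, digits = n - 3, format = "g"), n)

# Largest representable value <= v ("down") or smallest >= v ("up") that fits
# in n ASCII characters as fixed-point; keeps physical ranges outside the data.
.bound_num <- function(v, n, dir) {
  for (d in 6:0) {
    val <- if (dir == "down") floor(v * 10^d) / 10^d else ceiling(v * 10^d) / 10^d
    s <- formatC(val, format = "f", digits = d)
    if (nchar(s) <= n) return(s)
  }
  stop("value does not fit in EDF header field: ", v)
}

#' Write a recording to disk
#'
#' @param recording an [eeg_recording()].
#' @param path output file.
#' @param format `"tsv"` (delimited text with a `# rate=... condition=...`
#'   header line), `"edf"` (16-bit) or `"bdf"` (24-bit).
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path,
                            format = c("tsv", "edf", "bdf")) {
  format <- match.arg(format)
  x <- recording$data
  if (format == "tsv") {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(sprintf("# rate=%g condition=%s", recording$rate,
                       recording$condition), con)
    writeLines(paste(rownames(x), collapse = "\t"), con)
    write.table(t(x), con, sep = "\t", row.names = FALSE, col.names = FALSE)
    return(invisible(path))
  }
  bits <- if (format == "edf") 16L else 24L
  full <- 2^(bits - 1)
  n_sig <- nrow(x); n_samp <- ncol(x)
  pmin_ <- apply(x, 1, min); pmax_ <- apply(x, 1, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmin_[flat] <- pmin_[flat] - 1; pmax_[flat] <- pmax_[flat] + 1
  # quantize against the ASCII header values the reader will see, rounded
  # outward so no sample falls outside the physical range
  pmin_s <- vapply(pmin_, .bound_num, character(1), n = 8, dir = "down")
  pmax_s <- vapply(pmax_, .bound_num, character(1), n = 8, dir = "up")
  pmin_ <- as.numeric(pmin_s); pmax_ <- as.numeric(pmax_s)
  dmin <- -full; dmax <- full - 1
  con <- file(path, "wb"); on.exit(close(con))
  wc <- function(s) writeChar(s, con, eos = NULL)
  if (format == "edf") {
    wc(.pad("0", 8))
  } else {
    writeBin(as.raw(255), con); wc(.pad("BIOSEMI", 7))
  }
  wc(.pad("synthetic EEG", 80))
  wc(.pad(sprintf("condition=%s", recording$condition), 80))
  wc("01.01.00"); wc("00.00.00")
  wc(.pad(256 * (1 + n_sig), 8))
  wc(.pad(if (format == "bdf") "24BIT" else "", 44))
  wc(.pad(1, 8))                                   # one data record
  wc(.fmt_num(n_samp / recording$rate, 8))         # record duration (s)
  wc(.pad(n_sig, 4))
  for (f in list(function(i) .pad(rownames(x)[i], 16),
                 function(i) .pad("", 80),
                 function(i) .pad("uV", 8),
                 function(i) .pad(pmin_s[i], 8),
                 function(i) .pad(pmax_s[i], 8),
                 function(i) .pad(dmin, 8),
                 function(i) .pad(dmax, 8),
                 function(i) .pad("", 80),
                 function(i) .pad(n_samp, 8),
                 function(i) .pad("", 32)))
    for (i in seq_len(n_sig)) wc(f(i))
  for (i in seq_len(n_sig)) {
    # physical -> digital, clamped
    q <- round((x[i, ] - pmin_[i]) / (pmax_[i] - pmin_[i]) *
                 (dmax - dmin) + dmin)
    q <- as.integer(pmax(pmin(q, dmax), dmin))
    if (bits == 16) {
      writeBin(q, con, size = 2, endian = "little")
    } else {
      u <- ifelse(q < 0, q + 2^24, q)
      writeBin(as.raw(rbind(u %% 256, (u %/% 256) %% 256, u %/% 65536)), con)
    }
  }
  invisible(path)
}

.read_edf_bdf <- function(path, format) {
  bits <- if (format == "edf") 16L else 24L
  con <- file(path, "rb"); on.exit(close(con))
  rc <- function(n) readChar(con, n, useBytes = TRUE)
  if (format == "edf") rc(8) else { readBin(con, raw(), 1); rc(7) }
  rc(80)
  recfield <- trimws(rc(80))
  rc(8); rc(8); rc(8); rc(44)
  n_rec <- as.integer(trimws(rc(8)))
  dur <- as.numeric(trimws(rc(8)))
  n_sig <- as.integer(trimws(rc(4)))
  labels <- trimws(vapply(seq_len(n_sig), function(i) rc(16), character(1)))
  for (k in 1:2) for (i in seq_len(n_sig)) rc(c(80, 8)[k])
  pmin_ <- as.numeric(trimws(vapply(seq_len(n_sig), function(i) rc(8),
                                    character(1))))
  pmax_ <- as.numeric(trimws(vapply(seq_len(n_sig), function(i) rc(8),
                                    character(1))))
  dmin <- as.numeric(trimws(vapply(seq_len(n_sig), function(i) rc(8),
                                   character(1))))
  dmax <- as.numeric(trimws(vapply(seq_len(n_sig), function(i) rc(8),
                                   character(1))))
  for (i in seq_len(n_sig)) rc(80)
  nsamp <- as.integer(trimws(vapply(seq_len(n_sig), function(i) rc(8),
                                    character(1))))
  for (i in seq_len(n_sig)) rc(32)
  x <- matrix(0, n_sig, nsamp[1] * n_rec)
  for (r in seq_len(n_rec)) for (i in seq_len(n_sig)) {
    if (bits == 16) {
      q <- readBin(con, integer(), n = nsamp[i], size = 2, signed = TRUE,
                   endian = "little")
    } else {
      b <- as.integer(readBin(con, raw(), n = 3 * nsamp[i]))
      u <- b[c(TRUE, FALSE, FALSE)] + 256 * b[c(FALSE, TRUE, FALSE)] +
        65536 * b[c(FALSE, FALSE, TRUE)]
      q <- ifelse(u >= 2^23, u - 2^24, u)
    }
    cols <- ((r - 1) * nsamp[i] + 1):(r * nsamp[i])
    x[i, cols] <- (q - dmin[i]) / (dmax[i] - dmin[i]) *
      (pmax_[i] - pmin_[i]) + pmin_[i]
  }
  rownames(x) <- labels
  rate <- nsamp[1] / dur
  condition <- sub("^condition=", "", recfield)
  list(data = x, rate = rate, condition = condition)
}

#' Read a recording
#'
#' Channels are reordered to match the montage; missing montage channels are
#' an error, extra file channels are an error.
#'
#' @param path input file.
#' @param format `"tsv"`, `"edf"` or `"bdf"`; guessed from the extension by
#'   default.
#' @param montage montage to validate and order channels against.
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path, format = c("auto", "tsv", "edf", "bdf"),
                           montage = make_default_montage()) {
  format <- match.arg(format)
  if (format == "auto")
    format <- switch(tolower(tools::file_ext(path)),
                     edf = "edf", bdf = "bdf", "tsv")
  if (format == "tsv") {
    lines <- readLines(path, n = 1)
    m <- regmatches(lines, regexec("# rate=([0-9.]+) condition=(\\S+)",
                                   lines))[[1]]
    if (length(m) == 3) {
      rate <- as.numeric(m[2]); condition <- m[3]; skip <- 1
    } else { rate <- NA_real_; condition <- NA_character_; skip <- 0 }
    df <- read.table(path, header = TRUE, sep = "\t", skip = skip,
                     check.names = FALSE)
    raw <- list(data = t(as.matrix(df)), rate = rate, condition = condition)
    rownames(raw$data) <- names(df)
  } else {
    raw <- .read_edf_bdf(path, format)
  }
  missing <- setdiff(montage$labels, rownames(raw$data))
  if (length(missing))
    stop("file lacks montage channel(s): ", paste(missing, collapse = ", "))
  extra <- setdiff(rownames(raw$data), montage$labels)
  if (length(extra))
    stop("file has unknown channel(s): ", paste(extra, collapse = ", "))
  eeg_recording(raw$data[montage$labels, , drop = FALSE], rate = raw$rate,
                condition = raw$condition, montage = montage)
}

# Zero-phase windowed-sinc (Hamming) low-pass kernel, odd length.
fir_lowpass <- function(n_taps, fc_norm) {
  if (n_taps %% 2 == 0) n_taps <- n_taps + 1
  m <- (n_taps - 1) / 2
  k <- -m:m
  h <- 2 * fc_norm * sinc(2 * fc_norm * k)
  h <- h * (0.54 + 0.46 * cos(pi * k / m))
  h / sum(h)
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

# FFT-based symmetric-kernel filtering with reflection padding (zero phase).
.filter_zero_phase <- function(x, h) {
  m <- (length(h) - 1) / 2
  n <- length(x)
  pad <- pmin(m, n - 1)
  xe <- c(rev(x[2:(pad + 1)]), x, rev(x[(n - pad):(n - 1)]))
  L <- length(xe) + length(h) - 1
  nf <- nextn(L)
  y <- Re(fft(fft(c(xe, rep(0, nf - length(xe)))) *
              fft(c(h, rep(0, nf - length(h)))), inverse = TRUE)) / nf
  y[(m + pad + 1):(m + pad + n)]
}

#' Downsample a recording
#'
#' Anti-alias low-pass (zero-phase FIR, cutoff 0.4 x target rate) followed by
#' integer-factor decimation.
#'
#' @param recording an [eeg_recording()].
#' @param target target rate (Hz); must divide the source rate.
#' @return Downsampled [eeg_recording()].
#' @export
downsample <- function(recording, target) {
  stopifnot(inherits(recording, "eeg_recording"))
  factor <- recording$rate / target
  if (abs(factor - round(factor)) > 1e-9)
    stop("target rate must divide the source rate")
  factor <- as.integer(round(factor))
  if (factor == 1L) return(recording)
  h <- fir_lowpass(16L * factor + 1L, 0.4 * target / recording$rate)
  x <- recording$data
  idx <- seq(1L, ncol(x), by = factor)
  out <- matrix(0, nrow(x), length(idx), dimnames = list(rownames(x), NULL))
  for (c in seq_len(nrow(x)))
    out[c, ] <- .filter_zero_phase(x[c, ], h)[idx]
  eeg_recording(out, rate = target, condition = recording$condition,
                montage = recording$montage)
}
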