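# Minimal RIFF/WAVE reader and writer (PCM 16/24-bit and IEEE float32).
# No audio package ships in the target environment, so this is implemented
# directly over readBin/writeBin.

#' Write a waveform to a WAV file
#'
#' @param wav numeric vector (mono) or samples x channels matrix with values
#'   nominally in `[-1, 1]` (clipped for integer formats).
#' @param path output file.
#' @param rate sample rate (Hz); taken from `attr(wav, "rate")` if missing.
#' @param bits 16 or 24 (integer PCM) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(wav, path, rate = attr(wav, "rate"), bits = 16) {
  m <- as.matrix(wav)
  if (is.null(rate)) stop("sample rate required")
  if (!bits %in% c(16, 24, 32)) stop("bits must be 16, 24 or 32")
  n_ch <- ncol(m); n <- nrow(m)
  block <- n_ch * bits / 8
  data_bytes <- n * block
  fmt_code <- if (bits == 32) 3L else 1L
  con <- file(path, "wb"); on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(n_ch, con, size = 2, endian = "little")
  writeBin(as.integer(rate), con, size = 4, endian = "little")
  writeBin(as.integer(rate * block), con, size = 4, endian = "little")
  writeBin(as.integer(block), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  inter <- as.numeric(t(m))                      # interleave channels
  if (bits == 32) {
    writeBin(inter, con, size = 4, endian = "little")
  } else {
    full <- 2^(bits - 1)
    q <- as.integer(pmax(pmin(round(inter * full), full - 1), -full))
    if (bits == 16) {
      writeBin(q, con, size = 2, endian = "little")
    } else {
      u <- ifelse(q < 0, q + 2^24, q)            # two's complement, 3 bytes
      raw3 <- rbind(u %% 256, (u %/% 256) %% 256, u %/% 65536)
      writeBin(as.raw(raw3), con)
    }
  }
  invisible(path)
}

#' Read a WAV file
#'
#' @param path input file.
#' @return samples x channels matrix with attribute `rate`, values in
#'   `[-1, 1]` for PCM input.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file: ", path)
  readBin(con, integer(), size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file: ", path)
  fmt <- NULL; data <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- list(
        code = readBin(con, integer(), size = 2, endian = "little"),
        n_ch = readBin(con, integer(), size = 2, endian = "little"),
        rate = readBin(con, integer(), size = 4, endian = "little"),
        brate = readBin(con, integer(), size = 4, endian = "little"),
        block = readBin(con, integer(), size = 2, endian = "little"),
        bits = readBin(con, integer(), size = 2, endian = "little"))
      if (sz > 16) readBin(con, raw(), n = sz - 16)
    } else if (id == "data") {
      data <- readBin(con, raw(), n = sz)
      break
    } else {
      readBin(con, raw(), n = sz)
    }
  }
  if (is.null(fmt) || is.null(data)) stop("malformed WAV: ", path)
  if (fmt$bits == 32 && fmt$code == 3) {
    x <- readBin(data, numeric(), n = length(data) / 4, size = 4,
                 endian = "little")
  } else if (fmt$bits == 16) {
    x <- readBin(data, integer(), n = length(data) / 2, size = 2,
                 signed = TRUE, endian = "little") / 32768
  } else if (fmt$bits == 24) {
    b <- as.integer(data)
    u <- b[c(TRUE, FALSE, FALSE)] + 256 * b[c(FALSE, TRUE, FALSE)] +
      65536 * b[c(FALSE, FALSE, TRUE)]
    x <- ifelse(u >= 2^23, u - 2^24, u) / 2^23
  } else stop("unsupported WAV format (code ", fmt$code, ", ",
              fmt$bits, " bits)")
  m <- matrix(x, ncol = fmt$n_ch, byrow = TRUE)
  structure(m, rate = fmt$rate, class = c("snn_waveform", class(m)))
}
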