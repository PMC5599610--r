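#' Construct a waveform object
#'
#' A `waveform` is the carrier of all stimulus operations: a mono sequence of
#' dimensionless amplitude samples together with its sampling rate.
#'
#' @param samples Numeric vector of finite sample values (length >= 1).
#' @param rate_hz Sampling rate in samples per second (> 0).
#' @return An object of class `waveform` with elements `samples` and `rate_hz`.
#' @examples
#' w <- waveform(sin(2 * pi * 220 * seq(0, 0.1, by = 1 / 8000)), 8000)
#' duration_s(w)
#' @export
waveform <- function(samples, rate_hz) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("waveform must contain at least one sample")
  if (!all(is.finite(samples))) stop("waveform samples must all be finite")
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || rate_hz <= 0) {
    stop("rate_hz must be a single positive number")
  }
  structure(list(samples = samples, rate_hz = as.numeric(rate_hz)),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform: %d samples @ %g Hz (%.1f ms), RMS %.4g>\n",
              length(x$samples), x$rate_hz,
              1000 * length(x$samples) / x$rate_hz, rms(x)))
  invisible(x)
}

#' Duration of a waveform in seconds
#' @param w A `waveform`.
#' @return Duration in seconds.
#' @export
duration_s <- function(w) length(w$samples) / w$rate_hz

#' Root-mean-square amplitude
#' @param w A `waveform` or numeric vector.
#' @return The RMS value.
#' @export
rms <- function(w) {
  x <- if (inherits(w, "waveform")) w$samples else as.numeric(w)
  sqrt(mean(x^2))
}

#' Normalize a waveform to a target RMS amplitude
#'
#' All stimuli in a bank are equalized to the same average intensity by
#' rescaling to a common RMS; the waveform shape is unchanged up to a positive
#' scalar.
#'
#' @param w A `waveform`.
#' @param target_rms Positive target RMS.
#' @return The rescaled `waveform`.
#' @export
rms_normalize <- function(w, target_rms = 0.05) {
  stopifnot(inherits(w, "waveform"))
  if (target_rms <= 0) stop("target_rms must be positive")
  r <- rms(w)
  if (r == 0) stop("cannot RMS-normalize an all-zero waveform")
  waveform(w$samples * (target_rms / r), w$rate_hz)
}

#' Apply a raised-cosine offset ramp
#'
#' Fades the waveform out ending at `end_ms`: the `ramp_ms` milliseconds before
#' `end_ms` are multiplied by a raised cosine falling from 1 to 0, and all
#' samples after `end_ms` are set to zero. Samples before the ramp are
#' unchanged.
#'
#' @param w A `waveform`.
#' @param end_ms Offset time in ms (<= waveform duration).
#' @param ramp_ms Ramp length in ms (<= `end_ms`); default 5 ms.
#' @return The ramped `waveform`.
#' @export
apply_offset_ramp <- function(w, end_ms, ramp_ms = 5) {
  stopifnot(inherits(w, "waveform"))
  dur_ms <- 1000 * duration_s(w)
  # tolerate sub-sample overshoot from ms-to-sample rounding
  if (end_ms > dur_ms + 1000 / w$rate_hz) stop("end_ms exceeds waveform duration")
  end_ms <- min(end_ms, dur_ms)
  if (ramp_ms > end_ms) stop("ramp_ms must not exceed end_ms")
  x <- w$samples
  t_ms <- 1000 * (seq_along(x) - 1) / w$rate_hz
  gain <- rep(1, length(x))
  in_ramp <- t_ms >= (end_ms - ramp_ms) & t_ms <= end_ms
  gain[in_ramp] <- 0.5 * (1 + cos(pi * (t_ms[in_ramp] - (end_ms - ramp_ms)) / ramp_ms))
  gain[t_ms > end_ms] <- 0
  waveform(x * gain, w$rate_hz)
}

#' Apply a raised-cosine onset ramp
#'
#' Symmetric counterpart of [apply_offset_ramp()]: the first `ramp_ms`
#' milliseconds rise from 0 to 1 with a raised cosine. Used at bank-building
#' time to avoid onset clicks.
#'
#' @param w A `waveform`.
#' @param ramp_ms Ramp length in ms.
#' @return The ramped `waveform`.
#' @export
apply_onset_ramp <- function(w, ramp_ms = 5) {
  stopifnot(inherits(w, "waveform"))
  if (ramp_ms > 1000 * duration_s(w)) stop("ramp longer than signal")
  x <- w$samples
  t_ms <- 1000 * (seq_along(x) - 1) / w$rate_hz
  gain <- rep(1, length(x))
  in_ramp <- t_ms < ramp_ms
  gain[in_ramp] <- 0.5 * (1 - cos(pi * t_ms[in_ramp] / ramp_ms))
  waveform(x * gain, w$rate_hz)
}

#' Write a waveform to a mono RIFF WAV file
#'
#' Writes 16-bit PCM (samples clipped to \[-1, 1\]) or IEEE float32.
#'
#' @param w A `waveform`.
#' @param path Output file path.
#' @param format `"pcm16"` or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(w, path, format = c("pcm16", "float32")) {
  stopifnot(inherits(w, "waveform"))
  format <- match.arg(format)
  n <- length(w$samples)
  rate <- as.integer(round(w$rate_hz))
  con <- file(path, "wb")
  on.exit(close(con))
  if (format == "pcm16") {
    bytes_per <- 2L; fmt_tag <- 1L; bits <- 16L
  } else {
    bytes_per <- 4L; fmt_tag <- 3L; bits <- 32L
  }
  data_len <- n * bytes_per
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_len), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_tag, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(rate, con, size = 4, endian = "little")
  writeBin(rate * bytes_per, con, size = 4, endian = "little")
  writeBin(bytes_per, con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_len), con, size = 4, endian = "little")
  if (format == "pcm16") {
    x <- pmax(-1, pmin(1, w$samples))
    writeBin(as.integer(round(x * 32767)), con, size = 2, endian = "little")
  } else {
    writeBin(w$samples, con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a mono WAV file written by [write_wav()]
#'
#' Supports mono PCM16 and IEEE float32 RIFF files with a plain fmt/data
#' chunk layout.
#'
#' @param path WAV file path.
#' @return A `waveform`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF file")
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4)
  if (!identical(wave, "WAVE")) stop("not a WAVE file")
  fmt_tag <- NULL; rate <- NULL; bits <- NULL; n_chan <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4L) stop("no data chunk found")
    len <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_tag <- readBin(con, "integer", 1, size = 2, endian = "little")
      n_chan <- readBin(con, "integer", 1, size = 2, endian = "little")
      rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
      invisible(readBin(con, "integer", 1, size = 2, endian = "little"))
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (len > 16) invisible(readBin(con, "raw", len - 16))
    } else if (identical(id, "data")) {
      if (is.null(fmt_tag)) stop("data chunk before fmt chunk")
      if (n_chan != 1L) stop("only mono WAV supported")
      if (fmt_tag == 1L && bits == 16L) {
        x <- readBin(con, "integer", len / 2, size = 2, endian = "little") / 32767
      } else if (fmt_tag == 3L && bits == 32L) {
        x <- readBin(con, "numeric", len / 4, size = 4, endian = "little")
      } else {
        stop("unsupported WAV encoding")
      }
      return(waveform(x, rate))
    } else {
      invisible(readBin(con, "raw", len))
    }
  }
}

# Evaluate code with a temporarily seeded RNG, restoring global RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}
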