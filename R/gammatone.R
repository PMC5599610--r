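#' Equivalent rectangular bandwidth at a frequency
#'
#' Glasberg & Moore ERB formula: `ERB(f) = 24.7 (4.37 f/1000 + 1)`.
#'
#' @param f_hz Frequency in Hz.
#' @return ERB in Hz.
#' @export
erb_hz <- function(f_hz) 24.7 * (4.37 * f_hz / 1000 + 1)

#' Frequency to ERB-rate (ERB-number scale)
#' @param f_hz Frequency in Hz.
#' @return ERB-rate.
#' @export
hz_to_erbrate <- function(f_hz) 21.4 * log10(4.37 * f_hz / 1000 + 1)

#' ERB-rate to frequency
#' @param e ERB-rate value(s).
#' @return Frequency in Hz.
#' @export
erbrate_to_hz <- function(e) (10^(e / 21.4) - 1) * 1000 / 4.37

#' ERB-spaced center frequencies
#' @param lo_hz,hi_hz Frequency bounds.
#' @param n Number of channels.
#' @return Strictly increasing center frequencies in Hz.
#' @export
erb_space <- function(lo_hz, hi_hz, n) {
  erbrate_to_hz(seq(hz_to_erbrate(lo_hz), hz_to_erbrate(hi_hz), length.out = n))
}

#' Filterbank configuration
#' @param n_channels Number of channels (default 64).
#' @param cf_lo_hz,cf_hi_hz Center-frequency bounds (defaults 80 and 8000 Hz).
#' @param lp_hz Envelope low-pass cutoff (default 70 Hz).
#' @param frame_rate_hz Auditory-spectrogram frame rate (default 200 Hz).
#' @return A configuration list.
#' @export
fb_config <- function(n_channels = 64, cf_lo_hz = 80, cf_hi_hz = 8000,
                      lp_hz = 70, frame_rate_hz = 200) {
  stopifnot(n_channels >= 2, cf_lo_hz > 0, cf_hi_hz > cf_lo_hz)
  list(n_channels = as.integer(n_channels), cf_lo_hz = cf_lo_hz,
       cf_hi_hz = cf_hi_hz, lp_hz = lp_hz, frame_rate_hz = frame_rate_hz)
}

#' Gammatone filterbank decomposition
#'
#' Splits a waveform into ERB-spaced frequency bands with the 4th-order
#' gammatone magnitude response, `|H(f)| = [1 + ((f-cf)/b)^2]^-2` with
#' `b = 1.019 ERB(cf)`, applied with zero phase in the frequency domain so
#' that band signals sum coherently (exact band-level chimera resynthesis).
#'
#' @param w A `waveform`.
#' @param config A [fb_config()] list (or pass `n_channels` etc. there).
#' @return A `band_decomposition`: list with `bands` (channel x sample
#'   matrix), `cf_hz`, `rate_hz`.
#' @export
gammatone_filterbank <- function(w, config = fb_config()) {
  stopifnot(inherits(w, "waveform"))
  if (config$cf_hi_hz >= w$rate_hz / 2) {
    stop("cf_hi_hz must be below the Nyquist frequency")
  }
  x <- w$samples
  n <- length(x)
  # zero-pad past the longest filter ringing to avoid circular wrap
  npad <- stats::nextn(n + round(0.05 * w$rate_hz), 2)
  X <- stats::fft(c(x, numeric(npad - n)))
  f <- (seq_len(npad) - 1) / npad * w$rate_hz
  f <- pmin(f, w$rate_hz - f)                 # physical frequency of each bin
  cfs <- erb_space(config$cf_lo_hz, config$cf_hi_hz, config$n_channels)
  bands <- matrix(0, nrow = config$n_channels, ncol = n)
  for (k in seq_len(config$n_channels)) {
    b <- 1.019 * erb_hz(cfs[k])
    H <- (1 + ((f - cfs[k]) / b)^2)^(-2)
    y <- Re(stats::fft(X * H, inverse = TRUE)) / npad
    bands[k, ] <- y[seq_len(n)]
  }
  structure(list(bands = bands, cf_hz = cfs, rate_hz = w$rate_hz),
            class = "band_decomposition")
}

#' @export
print.band_decomposition <- function(x, ...) {
  cat(sprintf("<band_decomposition: %d channels (%.0f-%.0f Hz) x %d samples @ %g Hz>\n",
              nrow(x$bands), min(x$cf_hz), max(x$cf_hz), ncol(x$bands), x$rate_hz))
  invisible(x)
}

#' Construct an auditory spectrogram object
#'
#' @param env Nonnegative channel x frame envelope matrix.
#' @param cf_hz Channel center frequencies (ascending, length = nrow(env)).
#' @param frame_rate_hz Frame rate in Hz.
#' @return An `auditory_spectrogram`.
#' @export
auditory_spectrogram <- function(env, cf_hz, frame_rate_hz) {
  env <- as.matrix(env)
  if (any(env < 0)) stop("auditory spectrogram envelopes must be nonnegative")
  if (nrow(env) != length(cf_hz)) stop("one cf per envelope row required")
  if (is.unsorted(cf_hz, strictly = TRUE)) stop("cf_hz must be strictly increasing")
  structure(list(env = env, cf_hz = as.numeric(cf_hz),
                 frame_rate_hz = frame_rate_hz),
            class = "auditory_spectrogram")
}

#' Envelope extraction: band signals to auditory spectrogram
#'
#' Per band: half-wave rectification, 4th-order Butterworth low-pass at
#' `lp_hz` applied with zero phase, then decimation to the spectrogram frame
#' rate. Small negative values produced by the low-pass filter are clamped to
#' zero so envelopes are nonnegative.
#'
#' @param bands A `band_decomposition`.
#' @param lp_hz Low-pass cutoff (default 70 Hz).
#' @param frame_rate_hz Output frame rate (default 200 Hz).
#' @return An `auditory_spectrogram`.
#' @export
envelope_extract <- function(bands, lp_hz = 70, frame_rate_hz = 200) {
  stopifnot(inherits(bands, "band_decomposition"))
  if (lp_hz >= bands$rate_hz / 2) stop("lp_hz must be below Nyquist")
  n <- ncol(bands$bands)
  bf <- signal::butter(4, lp_hz / (bands$rate_hz / 2), type = "low")
  n_frames <- max(1L, floor(n / bands$rate_hz * frame_rate_hz))
  idx <- pmin(n, round((seq_len(n_frames) - 1) / frame_rate_hz * bands$rate_hz) + 1)
  env <- matrix(0, nrow = nrow(bands$bands), ncol = n_frames)
  for (k in seq_len(nrow(bands$bands))) {
    rect <- pmax(bands$bands[k, ], 0)
    smooth <- signal::filtfilt(bf, rect)
    env[k, ] <- pmax(smooth[idx], 0)
  }
  auditory_spectrogram(env, bands$cf_hz, frame_rate_hz)
}

#' Time-averaged auditory spectrum
#'
#' Per-channel time mean of the auditory spectrogram envelope.
#'
#' @param sg An `auditory_spectrogram`.
#' @return An `auditory_spectrum`: list with `level` and `cf_hz`.
#' @export
auditory_spectrum <- function(sg) {
  stopifnot(inherits(sg, "auditory_spectrogram"))
  if (ncol(sg$env) < 1L) stop("spectrogram must contain at least one frame")
  structure(list(level = rowMeans(sg$env), cf_hz = sg$cf_hz),
            class = "auditory_spectrum")
}

#' Full waveform-to-spectrogram front end
#'
#' Convenience chain: gammatone filterbank, then envelope extraction.
#'
#' @param w A `waveform`.
#' @param config A [fb_config()].
#' @return An `auditory_spectrogram`.
#' @export
auditory_front_end <- function(w, config = fb_config()) {
  envelope_extract(gammatone_filterbank(w, config),
                   lp_hz = config$lp_hz, frame_rate_hz = config$frame_rate_hz)
}

#' Write an auditory spectrogram to a TSV file
#'
#' First column `cf_hz`, remaining columns one per frame; a comment header
#' records the frame rate.
#'
#' @param sg An `auditory_spectrogram`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrogram_tsv <- function(sg, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# frame_rate_hz=%g", sg$frame_rate_hz), con)
  df <- data.frame(cf_hz = sg$cf_hz, sg$env, check.names = FALSE)
  colnames(df) <- c("cf_hz", sprintf("f%04d", seq_len(ncol(sg$env))))
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an auditory spectrogram written by [write_spectrogram_tsv()]
#' @param path TSV path.
#' @return An `auditory_spectrogram`.
#' @export
read_spectrogram_tsv <- function(path) {
  first <- readLines(path, n = 1)
  fr <- as.numeric(sub("# frame_rate_hz=", "", first, fixed = TRUE))
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  auditory_spectrogram(unname(as.matrix(df[, -1, drop = FALSE])), df$cf_hz, fr)
}
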