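# Normalized cross-correlation r(lag) of a vector over a range of lags.
.norm_xcorr <- function(x, lags) {
  n <- length(x)
  vapply(lags, function(l) {
    a <- x[1:(n - l)]
    b <- x[(1 + l):n]
    den <- sqrt(sum(a^2) * sum(b^2))
    if (den == 0) 0 else sum(a * b) / den
  }, numeric(1))
}

# Parabolic interpolation of a peak at index i of r; returns c(offset, value).
.parabolic_peak <- function(r, i) {
  if (i <= 1L || i >= length(r)) return(c(0, r[i]))
  denom <- r[i - 1] - 2 * r[i] + r[i + 1]
  if (denom >= 0) return(c(0, r[i]))
  d <- 0.5 * (r[i - 1] - r[i + 1]) / denom
  c(d, r[i] - 0.25 * (r[i - 1] - r[i + 1]) * d)
}

#' Estimate the fundamental frequency of a harmonic sound
#'
#' Autocorrelation-peak period estimation: the normalized cross-correlation is
#' evaluated over lags corresponding to the 100-600 Hz search range, the
#' smallest lag within 1% of the global maximum is taken as the period (this
#' resolves the octave ambiguity of strongly periodic sounds), and the lag is
#' refined by parabolic interpolation.
#'
#' @param w A `waveform`.
#' @param f_min_hz,f_max_hz Pitch search range (defaults 100 and 600 Hz).
#' @param voicing_threshold Minimum peak correlation to accept the input as
#'   voiced (default 0.5).
#' @return Estimated f0 in Hz.
#' @export
estimate_f0 <- function(w, f_min_hz = 100, f_max_hz = 600,
                        voicing_threshold = 0.5) {
  stopifnot(inherits(w, "waveform"))
  x <- w$samples - mean(w$samples)
  lag_min <- max(2L, floor(w$rate_hz / f_max_hz))
  lag_max <- ceiling(w$rate_hz / f_min_hz)
  if (length(x) < 2 * lag_max) stop("waveform too short for the pitch floor")
  lags <- lag_min:lag_max
  r <- .norm_xcorr(x, lags)
  rmax <- max(r)
  if (rmax < voicing_threshold) stop("unvoiced input: no autocorrelation peak")
  # local maxima within 1% of the global maximum; choose the smallest lag
  is_peak <- c(FALSE, diff(sign(diff(r))) < 0, FALSE) & r >= rmax - 0.01
  i <- if (any(is_peak)) which(is_peak)[1] else which.max(r)
  pk <- .parabolic_peak(r, i)
  w$rate_hz / (lags[i] + pk[1])
}

#' Harmonic-to-noise ratio (cross-correlation method)
#'
#' Frame-wise normalized autocorrelation at the pitch-period lag: in 40-ms
#' windows with a 10-ms hop, the peak normalized cross-correlation `r` over
#' the 100-600 Hz lag range is refined by parabolic interpolation and turned
#' into a per-frame HNR of `10 log10(r / (1 - r))` dB. Frames with `r` above
#' the voicing threshold count as voiced; the result is the mean over voiced
#' frames (over all frames when none reach threshold, as for noise), capped at
#' +60 dB.
#'
#' @param w A `waveform`.
#' @param frame_ms,hop_ms Analysis window and hop (defaults 40 and 10 ms).
#' @param f_min_hz,f_max_hz Pitch search range.
#' @param voicing_threshold Voiced-frame criterion on `r` (default 0.3).
#' @param cap_db Upper HNR cap (default +60).
#' @return HNR in dB.
#' @export
hnr <- function(w, frame_ms = 40, hop_ms = 10, f_min_hz = 100,
                f_max_hz = 600, voicing_threshold = 0.3, cap_db = 60) {
  stopifnot(inherits(w, "waveform"))
  rate <- w$rate_hz
  frame_n <- round(frame_ms / 1000 * rate)
  hop_n <- max(1L, round(hop_ms / 1000 * rate))
  lag_min <- max(2L, floor(rate / f_max_hz))
  lag_max <- ceiling(rate / f_min_hz)
  if (frame_n <= 2 * lag_max) {
    stop("waveform frames too short for two pitch periods at the pitch floor")
  }
  x <- w$samples
  if (length(x) < frame_n) stop("waveform shorter than one analysis frame")
  starts <- seq(1L, length(x) - frame_n + 1L, by = hop_n)
  lags <- lag_min:lag_max
  r_cap <- 1 - 10^(-cap_db / 10)            # r mapping exactly to cap_db
  vals <- numeric(0)
  voiced <- logical(0)
  for (s in starts) {
    fr <- x[s:(s + frame_n - 1L)]
    fr <- fr - mean(fr)
    if (sum(fr^2) == 0) next
    r <- .norm_xcorr(fr, lags)
    i <- which.max(r)
    rp <- min(max(.parabolic_peak(r, i)[2], 1e-12), r_cap)
    vals <- c(vals, 10 * log10(rp / (1 - rp)))
    voiced <- c(voiced, rp > voicing_threshold)
  }
  if (length(vals) == 0) stop("no analyzable frames (silent input)")
  if (any(voiced)) mean(vals[voiced]) else mean(vals)
}

#' Spectral centroid of an auditory spectrum
#'
#' Level-weighted mean of the channel center frequencies on the linear
#' frequency axis (Hz): the center of gravity of the average rectified,
#' low-passed band envelopes, the brightness correlate used for matching.
#'
#' @param spec An `auditory_spectrum`.
#' @return Centroid in Hz.
#' @export
spectral_centroid <- function(spec) {
  stopifnot(inherits(spec, "auditory_spectrum"))
  tot <- sum(spec$level)
  if (tot <= 0) stop("all-zero auditory spectrum has no centroid")
  sum(spec$level * spec$cf_hz) / tot
}

#' Construct a rate-scale modulation energy plane
#'
#' @param energy Nonnegative matrix, rows indexed by temporal modulation rate
#'   and columns by spectral modulation scale.
#' @param rate_axis_hz Ascending rate axis (Hz), length = nrow(energy).
#' @param scale_axis_cpo Ascending scale axis (cycles/octave), length =
#'   ncol(energy).
#' @return A `rate_scale_plane`.
#' @export
rate_scale_plane <- function(energy, rate_axis_hz, scale_axis_cpo) {
  energy <- as.matrix(energy)
  if (any(energy < 0)) stop("modulation energy must be nonnegative")
  if (nrow(energy) != length(rate_axis_hz) ||
      ncol(energy) != length(scale_axis_cpo)) {
    stop("axis lengths must match energy dimensions")
  }
  if (is.unsorted(rate_axis_hz, strictly = TRUE) ||
      is.unsorted(scale_axis_cpo, strictly = TRUE)) {
    stop("axes must be strictly increasing")
  }
  structure(list(energy = energy, rate_axis_hz = as.numeric(rate_axis_hz),
                 scale_axis_cpo = as.numeric(scale_axis_cpo)),
            class = "rate_scale_plane")
}

#' Spectrotemporal modulation spectrum of an auditory spectrogram
#'
#' Cortical-model style rate-scale analysis: the envelope matrix is
#' interpolated onto a uniform log2-frequency grid, compressed with
#' `log(1 + env / eps)` (mild by default, `eps = 4 max(env)`, which stabilizes
#' near-silent cells without introducing strong harmonic distortion of the
#' modulation content), mean-subtracted, and 2-D Fourier transformed over
#' (time, log2-frequency). Negative and positive temporal rates are folded by
#' magnitude; the scale axis is in cycles per octave.
#'
#' @param sg An `auditory_spectrogram` with at least 2 channels and 2 frames.
#' @param eps_rel Compression constant as a multiple of the envelope maximum
#'   (default 4; larger values compress less and keep the modulation content
#'   of strongly modulated envelopes nearly undistorted).
#' @return A `rate_scale_plane`.
#' @export
modulation_spectrum <- function(sg, eps_rel = 4) {
  stopifnot(inherits(sg, "auditory_spectrogram"))
  M <- nrow(sg$env); N <- ncol(sg$env)
  if (M < 2L || N < 2L) stop("need at least 2 channels and 2 frames")
  x <- log2(sg$cf_hz)
  xg <- seq(x[1], x[M], length.out = M)
  envg <- apply(sg$env, 2, function(col) stats::approx(x, col, xout = xg)$y)
  mx <- max(envg)
  L <- if (mx > 0) log1p(envg / (eps_rel * mx)) else envg
  L <- L - mean(L)
  FF <- stats::fft(L)                       # 2-D DFT: rows = scale, cols = rate
  n_s <- floor(M / 2) + 1L
  n_r <- floor(N / 2) + 1L
  E <- matrix(0, nrow = n_r, ncol = n_s)
  for (ri in seq_len(n_r)) {
    r0 <- ri - 1L
    neg <- (N - r0) %% N + 1L
    for (si in seq_len(n_s)) {
      E[ri, si] <- Mod(FF[si, ri]) +
        if (r0 > 0 && neg != ri) Mod(FF[si, neg]) else 0
    }
  }
  d_oct <- (x[M] - x[1]) / (M - 1)          # octaves per channel step
  rate_axis <- (seq_len(n_r) - 1) * sg$frame_rate_hz / N
  scale_axis <- (seq_len(n_s) - 1) / (M * d_oct)
  rate_scale_plane(E, rate_axis, scale_axis)
}

#' Dominant rate and dominant scale of a modulation plane
#'
#' Energy-weighted centroid of the (folded) temporal rate axis and of the
#' spectral scale axis, over configurable integration windows that exclude
#' the DC terms.
#'
#' @param plane A `rate_scale_plane`.
#' @param rate_window_hz Rate integration window (default 1-32 Hz).
#' @param scale_window_cpo Scale integration window (default 0.25-8 cyc/oct).
#' @return Named numeric vector `c(dom_rate_hz=, dom_scale_cpo=)`.
#' @export
dominant_rate_scale <- function(plane, rate_window_hz = c(1, 32),
                                scale_window_cpo = c(0.25, 8)) {
  stopifnot(inherits(plane, "rate_scale_plane"))
  sel_r <- plane$rate_axis_hz >= rate_window_hz[1] &
    plane$rate_axis_hz <= rate_window_hz[2]
  sel_s <- plane$scale_axis_cpo >= scale_window_cpo[1] &
    plane$scale_axis_cpo <= scale_window_cpo[2]
  if (!any(sel_r) || !any(sel_s)) stop("integration windows select no axis bins")
  E <- plane$energy[sel_r, sel_s, drop = FALSE]
  tot <- sum(E)
  if (tot <= 0) stop("zero-energy modulation plane in the integration window")
  c(dom_rate_hz = sum(rowSums(E) * plane$rate_axis_hz[sel_r]) / tot,
    dom_scale_cpo = sum(colSums(E) * plane$scale_axis_cpo[sel_s]) / tot)
}

#' Full acoustic descriptor profile of a stimulus
#'
#' Assembles the five descriptors used for matching and as parametric
#' modulators: fundamental frequency, harmonic-to-noise ratio, spectral
#' centroid, dominant temporal-modulation rate and dominant spectral scale.
#'
#' @param w A `waveform`.
#' @param config Filterbank configuration for the auditory-model descriptors.
#' @param rate_window_hz,scale_window_cpo Integration windows for
#'   [dominant_rate_scale()].
#' @return An `acoustic_profile` list with fields `f0_hz`, `hnr_db`,
#'   `centroid_hz`, `dom_rate_hz`, `dom_scale_cpo`.
#' @export
acoustic_profile <- function(w, config = fb_config(),
                             rate_window_hz = c(1, 32),
                             scale_window_cpo = c(0.25, 8)) {
  sg <- auditory_front_end(w, config)
  drs <- dominant_rate_scale(modulation_spectrum(sg),
                             rate_window_hz, scale_window_cpo)
  structure(list(f0_hz = estimate_f0(w),
                 hnr_db = hnr(w),
                 centroid_hz = spectral_centroid(auditory_spectrum(sg)),
                 dom_rate_hz = unname(drs["dom_rate_hz"]),
                 dom_scale_cpo = unname(drs["dom_scale_cpo"])),
            class = "acoustic_profile")
}

#' @export
print.acoustic_profile <- function(x, ...) {
  cat(sprintf(paste0("f0 = %.1f Hz, HNR = %.1f dB, centroid = %.0f Hz,\n",
                     "dominant rate = %.1f Hz, dominant scale = %.2f cyc/oct\n"),
              x$f0_hz, x$hnr_db, x$centroid_hz, x$dom_rate_hz, x$dom_scale_cpo))
  invisible(x)
}

#' Feature table for a stimulus bank
#'
#' One row per stimulus with its identifiers and the five acoustic
#' descriptors.
#'
#' @param bank A `stimulus_bank` (or any list of entries with `id`,
#'   `category`, `pitch`, `wave`).
#' @param config Filterbank configuration.
#' @return A data.frame with columns id, category, pitch, f0_hz, hnr_db,
#'   centroid_hz, dom_rate_hz, dom_scale_cpo.
#' @export
profile_table <- function(bank, config = fb_config()) {
  rows <- lapply(bank, function(e) {
    p <- acoustic_profile(e$wave, config)
    data.frame(id = e$id, category = e$category,
               pitch = if (!is.null(e$pitch)) e$pitch else NA_character_,
               f0_hz = p$f0_hz, hnr_db = p$hnr_db, centroid_hz = p$centroid_hz,
               dom_rate_hz = p$dom_rate_hz, dom_scale_cpo = p$dom_scale_cpo,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a feature table to CSV or TSV
#' @param tab A feature table data.frame.
#' @param path Output path; a `.tsv` extension selects tab separation.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(tab, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(tab, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
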