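# Shared fixtures, built in code at test time.

# pure (optionally AM) tone waveform
mk_tone <- function(f_hz, dur_s = 0.5, rate = 16000, am_hz = NULL, ramp = TRUE) {
  t <- (0:(round(dur_s * rate) - 1)) / rate
  x <- sin(2 * pi * f_hz * t)
  if (!is.null(am_hz)) x <- x * (1 - cos(2 * pi * am_hz * t)) / 2
  w <- waveform(x, rate)
  if (ramp) {
    w <- apply_onset_ramp(w, 5)
    w <- apply_offset_ramp(w, 1000 * dur_s, 5)
  }
  w
}

# harmonic + band-limited noise mixture at an exact in-band power ratio
mk_mixture <- function(hnr_db, f0 = 220, dur_s = 0.25, rate = 44100, seed = 1) {
  n <- round(dur_s * rate)
  t <- (0:(n - 1)) / rate
  harm <- rowSums(sapply(1:20, function(k) (1 / k) * sin(2 * pi * k * f0 * t)))
  set.seed(seed)
  z <- rnorm(n)
  Z <- fft(z)
  f <- (0:(n - 1)) / n * rate
  f <- pmin(f, rate - f)
  Z[f > 5000] <- 0
  noise <- Re(fft(Z, inverse = TRUE)) / n
  g <- sqrt(mean(harm^2) / (mean(noise^2) * 10^(hnr_db / 10)))
  waveform(harm + g * noise, rate)
}

# drifting-ripple auditory spectrogram on a uniform log2 frequency grid
mk_ripple <- function(rate_hz = 8, scale_cpo = 2, n_ch = 64, n_fr = 200,
                      frame_rate = 100, cf_lo = 100, n_oct = 6) {
  cfs <- cf_lo * 2^seq(0, n_oct, length.out = n_ch)
  tt <- (0:(n_fr - 1)) / frame_rate
  env <- outer(log2(cfs / cf_lo), tt,
               function(x, t) 1 + cos(2 * pi * (rate_hz * t + scale_cpo * x)))
  auditory_spectrogram(env, cfs, frame_rate)
}

# small filterbank configuration used throughout the unit tests
cfg_small <- fb_config(n_channels = 32, cf_lo_hz = 100, cf_hi_hz = 4000)

# two-pitch chimera donors shared by the chimera unit tests
donors_2p <- build_chimera_donors(pitches = c("A3", "D#4"), seed = 7,
                                  rate_hz = 22050)

# cosine similarity between two spectra
cosim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# broadband envelope (channel-summed auditory spectrogram)
broadband_env <- function(w, cfg) colSums(auditory_front_end(w, cfg)$env)
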