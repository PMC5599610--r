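test_that("f0 estimation recovers pure and harmonic pitches and flags noise", {
  expect_equal(estimate_f0(mk_tone(330, 0.25, rate = 44100)), 330,
               tolerance = 1 / 330)
  w <- synth_vowel(tone_spec("vowel", "o", 261.6, seed = 2))
  expect_equal(estimate_f0(w), 261.6, tolerance = 1 / 261.6)
  set.seed(3)
  expect_error(estimate_f0(waveform(rnorm(22050), 44100)), "unvoiced")
})

test_that("HNR recovers constructed power ratios within 2 dB from 0 to 40 dB", {
  for (h in c(0, 10, 20, 30, 40)) {
    est <- hnr(mk_mixture(h, seed = h + 1))
    expect_lt(abs(est - h), 2)
  }
})

test_that("HNR saturates high for clean tones and goes negative for noise", {
  clean <- mk_mixture(90, seed = 1)        # essentially noiseless
  expect_gte(hnr(clean), 40)
  expect_lte(hnr(clean), 60)               # cap
  set.seed(4)
  expect_lte(hnr(waveform(rnorm(22050), 44100)), 0)
  expect_error(hnr(waveform(rep(0, 22050), 44100)), "silent")
})

test_that("spectral centroid is the level-weighted cf mean", {
  lvl <- rep(0, 5)
  lvl[3] <- 2
  sp <- structure(list(level = lvl, cf_hz = c(100, 200, 400, 800, 1600)),
                  class = "auditory_spectrum")
  expect_equal(spectral_centroid(sp), 400)
  lvl2 <- c(1, 0, 0, 0, 1)
  sp2 <- structure(list(level = lvl2, cf_hz = sp$cf_hz),
                   class = "auditory_spectrum")
  expect_equal(spectral_centroid(sp2), (100 + 1600) / 2)
  sp0 <- structure(list(level = rep(0, 5), cf_hz = sp$cf_hz),
                   class = "auditory_spectrum")
  expect_error(spectral_centroid(sp0), "all-zero")
})

test_that("centroid is gain-invariant and strictly increases with brightness", {
  spec_of <- function(br) {
    w <- synth_instrument(tone_spec("instrument", "oboe", 220,
                                    duration_ms = 250, brightness = br,
                                    seed = 5))
    auditory_spectrum(auditory_front_end(w, cfg_small))
  }
  cents <- sapply(c(-24, -18, -12, -6), function(b) spectral_centroid(spec_of(b)))
  expect_true(all(diff(cents) > 0))
  sp <- spec_of(-12)
  sp_scaled <- sp
  sp_scaled$level <- 7 * sp$level
  expect_equal(spectral_centroid(sp_scaled), spectral_centroid(sp))
})

test_that("modulation spectrum localizes ripples and keeps energy nonnegative", {
  p <- modulation_spectrum(mk_ripple(8, 2))
  expect_true(all(p$energy >= 0))
  idx <- which(p$energy == max(p$energy), arr.ind = TRUE)
  expect_equal(p$rate_axis_hz[idx[1]], 8, tolerance = 0.51 / 8)
  expect_equal(p$scale_axis_cpo[idx[2]], 2, tolerance = 0.2)
  # static spectrum: everything at rate ~ 0
  env <- matrix(rep(1:32, 50), nrow = 32)
  cfs <- 100 * 2^seq(0, 5, length.out = 32)
  ps <- modulation_spectrum(auditory_spectrogram(env, cfs, 100))
  marg <- rowSums(ps$energy)
  expect_gt(marg[1] / sum(marg), 0.95)
  expect_error(modulation_spectrum(auditory_spectrogram(matrix(1, 1, 5),
                                                        200, 100)),
               "at least 2")
})

test_that("dominant rate/scale is exact on point planes and averages pairs", {
  E <- matrix(0, 4, 4)
  E[2, 3] <- 5
  plane <- rate_scale_plane(E, c(2, 4, 8, 16), c(0.5, 1, 2, 4))
  d <- dominant_rate_scale(plane)
  expect_equal(unname(d), c(4, 2))
  E2 <- matrix(0, 4, 4)
  E2[1, 1] <- 1
  E2[3, 3] <- 1
  d2 <- dominant_rate_scale(rate_scale_plane(E2, c(2, 4, 8, 16),
                                             c(0.5, 1, 2, 4)))
  expect_equal(unname(d2), c((2 + 8) / 2, (0.5 + 2) / 2))
  expect_error(dominant_rate_scale(rate_scale_plane(matrix(0, 4, 4),
                                                    c(2, 4, 8, 16),
                                                    c(0.5, 1, 2, 4))),
               "zero-energy")
})

test_that("dominant scale increases with ripple density", {
  doms <- sapply(c(0.5, 1, 2, 4), function(s) {
    dominant_rate_scale(modulation_spectrum(mk_ripple(8, s)))["dom_scale_cpo"]
  })
  expect_true(all(diff(doms) > 0))
})

test_that("dominant rate tracks AM frequency within 1 Hz over 4-16 Hz", {
  for (fm in c(4, 8, 12, 16)) {
    w <- mk_tone(1000, 2, am_hz = fm)
    d <- dominant_rate_scale(modulation_spectrum(auditory_front_end(w, cfg_small)))
    expect_lt(abs(d[["dom_rate_hz"]] - fm), 1)
  }
})

test_that("acoustic profiles assemble all five descriptors deterministically", {
  w <- synth_vowel(tone_spec("vowel", "a", 220, target_hnr_db = 60, seed = 6))
  p <- acoustic_profile(w)
  expect_equal(p$f0_hz, 220, tolerance = 1 / 220)
  expect_gte(p$hnr_db, 40)
  expect_gt(p$centroid_hz, 0)
  expect_gt(p$dom_scale_cpo, 0)
  expect_gte(p$dom_rate_hz, 0)
  p2 <- acoustic_profile(waveform(w$samples, w$rate_hz))
  expect_equal(unclass(p), unclass(p2))
})

test_that("feature tables have one row per stimulus and survive writing", {
  entries <- list(
    list(id = "v1", category = "voice", pitch = "A3",
         wave = synth_vowel(tone_spec("vowel", "a", 220, seed = 1))),
    list(id = "i1", category = "instrument", pitch = "A3",
         wave = synth_instrument(tone_spec("instrument", "violin", 220, seed = 1))))
  tab <- profile_table(entries, cfg_small)
  expect_equal(nrow(tab), 2L)
  expect_named(tab, c("id", "category", "pitch", "f0_hz", "hnr_db",
                      "centroid_hz", "dom_rate_hz", "dom_scale_cpo"))
  path <- tempfile(fileext = ".tsv")
  write_feature_table(tab, path)
  back <- read.delim(path)
  expect_equal(back$f0_hz, tab$f0_hz, tolerance = 1e-6)
  unlink(path)
})
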