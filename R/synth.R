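#' Equal-tempered pitch grid over one octave from A3
#'
#' Twelve semitones A3..G#4 in equal temperament with A3 = 220 Hz; covers the
#' pitch range of the stimulus set.
#'
#' @param a3_hz Reference frequency for A3 (default 220).
#' @return Named numeric vector of 12 fundamental frequencies (Hz).
#' @export
pitch_grid <- function(a3_hz = 220) {
  notes <- c("A3", "A#3", "B3", "C4", "C#4", "D4", "D#4",
             "E4", "F4", "F#4", "G4", "G#4")
  stats::setNames(a3_hz * 2^((0:11) / 12), notes)
}

#' Convert a note name on the A3..G#4 grid to Hz
#' @param note Note name(s), e.g. "C4".
#' @param a3_hz Reference A3 frequency.
#' @return Fundamental frequency in Hz.
#' @export
note_to_hz <- function(note, a3_hz = 220) {
  g <- pitch_grid(a3_hz)
  if (!all(note %in% names(g))) stop("unknown note name(s): ",
                                     paste(setdiff(note, names(g)), collapse = ", "))
  unname(g[note])
}

# Vowel formant table (Hz), three formants per vowel, with bandwidths.
# Values follow classic measured adult formant frequencies.
.vowel_formants <- list(
  a = list(f = c(730, 1090, 2440), bw = c(90, 110, 160)),
  e = list(f = c(530, 1840, 2480), bw = c(80, 120, 160)),
  i = list(f = c(270, 2290, 3010), bw = c(60, 120, 180)),
  o = list(f = c(570, 840, 2410), bw = c(80, 100, 160))
)

# Per-"singer" vocal-tract length scale factors (two male, two female).
.singer_scale <- c(s1 = 0.95, s2 = 1.00, s3 = 1.10, s4 = 1.18)

#' Registry of the 16 instrument timbres
#'
#' Additive-synthesis parameters standing in for the instrument categories of
#' the stimulus set: spectral tilt (dB/octave), even-harmonic attenuation,
#' attack time, exponential decay time constant (NA = sustained), vibrato flag
#' (bowed strings) and inharmonicity coefficient (struck/plucked strings).
#'
#' @return A data.frame with one row per instrument.
#' @export
instrument_registry <- function() {
  data.frame(
    timbre = c("oboe", "clarinet", "bassoon", "saxophone", "trumpet",
               "trombone", "horn", "guitar", "mandolin", "ukulele",
               "harpsichord", "piano", "marimba", "violin", "viola", "cello"),
    tilt_db_oct = c(-3, -6, -9, -5, -2, -4, -8, -9, -7, -8,
                    -5, -10, -18, -6, -7, -8),
    even_atten = c(1, 0.25, 1, 0.8, 1, 1, 1, 1, 1, 1, 1, 1, 0.6, 1, 1, 1),
    attack_ms = c(20, 25, 25, 15, 10, 15, 20, 3, 2, 3, 2, 4, 2, 60, 65, 70),
    decay_tau_ms = c(NA, NA, NA, NA, NA, NA, NA, 150, 100, 120,
                     200, 300, 120, NA, NA, NA),
    vibrato = c(rep(FALSE, 13), TRUE, TRUE, TRUE),
    inharmonicity = c(rep(0, 7), 1e-4, 2e-4, 1e-4, 1e-4, 3e-4, 0, 0, 0, 0),
    stringsAsFactors = FALSE
  )
}

#' Specify a tone to synthesize
#'
#' @param kind `"vowel"` or `"instrument"`.
#' @param timbre_id For vowels, one of `"a"`, `"e"`, `"i"`, `"o"`, optionally
#'   with a singer suffix (`"a_s3"`); for instruments, a name from
#'   [instrument_registry()].
#' @param f0_hz Fundamental frequency in Hz.
#' @param duration_ms Tone duration in ms (128 and 250 are the replication
#'   configurations).
#' @param target_hnr_db Target harmonic-to-noise ratio in dB.
#' @param brightness Source spectral tilt in dB/octave (vowels; instruments
#'   take their tilt from the registry plus this offset).
#' @param seed Integer seed making the synthesis deterministic.
#' @param rate_hz Sampling rate (default 44100, CD standard).
#' @return A `tone_spec` list.
#' @export
tone_spec <- function(kind = c("vowel", "instrument"), timbre_id, f0_hz,
                      duration_ms = 128, target_hnr_db = 24,
                      brightness = -12, seed = 1L, rate_hz = 44100) {
  kind <- match.arg(kind)
  stopifnot(f0_hz > 0, duration_ms > 0, rate_hz > 0)
  structure(list(kind = kind, timbre_id = timbre_id, f0_hz = f0_hz,
                 duration_ms = duration_ms, target_hnr_db = target_hnr_db,
                 brightness = brightness, seed = as.integer(seed),
                 rate_hz = rate_hz),
            class = "tone_spec")
}

# Magnitude response of a parallel bank of second-order resonators,
# each normalized to unit gain at its center frequency.
.formant_gain <- function(f, centers, bws, weights = c(1, 0.6, 0.35)) {
  g <- 0
  for (j in seq_along(centers)) {
    Fj <- centers[j]; Bj <- bws[j]
    g <- g + weights[j] * (Fj * Bj) / sqrt((Fj^2 - f^2)^2 + (Bj * f)^2)
  }
  g
}

# Shape white noise by an arbitrary magnitude response, band-limited to fmax.
.shaped_noise <- function(n, rate, gain_fun, fmax) {
  z <- stats::rnorm(n)
  Z <- stats::fft(z)
  f <- (seq_len(n) - 1) / n * rate
  f <- pmin(f, rate - f)                       # fold to physical frequency
  H <- gain_fun(pmax(f, 1e-6))
  H[f > fmax] <- 0
  Re(stats::fft(Z * H, inverse = TRUE)) / n
}

# Mix a harmonic part and a noise part at a target dB power ratio.
.mix_at_hnr <- function(harm, noise, hnr_db) {
  ph <- mean(harm^2)
  pn <- mean(noise^2)
  if (pn == 0) return(harm)
  g <- sqrt(ph / (pn * 10^(hnr_db / 10)))
  harm + g * noise
}

#' Synthesize a sung-vowel-like tone
#'
#' Harmonic source (spectral tilt `brightness` dB/octave) shaped by three
#' vowel formant resonances, mixed with formant-shaped aspiration noise scaled
#' so the realized harmonic-to-noise ratio approximates `target_hnr_db`.
#' Harmonics and noise are band-limited to 5 kHz, the band over which the HNR
#' power ratio is solved. Deterministic given `spec$seed`.
#'
#' @param spec A `tone_spec` with `kind = "vowel"`; `timbre_id` is a vowel in
#'   `{a, e, i, o}`, optionally suffixed `_s1`..`_s4` to select a singer
#'   (vocal-tract scale factor).
#' @return A `waveform`.
#' @export
synth_vowel <- function(spec) {
  stopifnot(inherits(spec, "tone_spec"))
  if (spec$kind != "vowel") stop("spec$kind must be 'vowel'")
  parts <- strsplit(spec$timbre_id, "_", fixed = TRUE)[[1]]
  vowel <- parts[1]
  if (!vowel %in% names(.vowel_formants)) {
    stop("unknown vowel id: ", spec$timbre_id)
  }
  scale <- if (length(parts) > 1) {
    if (!parts[2] %in% names(.singer_scale)) stop("unknown singer id: ", parts[2])
    .singer_scale[[parts[2]]]
  } else 1.0
  rate <- spec$rate_hz
  if (spec$f0_hz >= rate / 4) stop("f0 too high for sampling rate")
  n <- round(spec$duration_ms / 1000 * rate)
  t <- (seq_len(n) - 1) / rate
  fm <- .vowel_formants[[vowel]]
  centers <- fm$f * scale
  bws <- fm$bw
  fmax <- min(5000, 0.45 * rate)
  kmax <- max(1L, floor(fmax / spec$f0_hz))
  harm <- numeric(n)
  for (k in seq_len(kmax)) {
    amp <- 10^(spec$brightness * log2(k) / 20) *
      .formant_gain(k * spec$f0_hz, centers, bws)
    harm <- harm + amp * sin(2 * pi * k * spec$f0_hz * t)
  }
  with_seed(spec$seed, {
    noise <- .shaped_noise(n, rate, function(f) .formant_gain(f, centers, bws),
                           fmax)
    waveform(.mix_at_hnr(harm, noise, spec$target_hnr_db), rate)
  })
}

#' Synthesize an instrument-like tone
#'
#' Additive harmonic tone with a timbre-specific harmonic amplitude profile
#' (spectral tilt, even-harmonic attenuation, slight inharmonicity for struck
#' or plucked strings), an attack/decay amplitude envelope, low-rate vibrato
#' for the bowed strings, and tilt-shaped noise scaled toward
#' `spec$target_hnr_db`. Deterministic given `spec$seed`.
#'
#' @param spec A `tone_spec` with `kind = "instrument"` and `timbre_id` from
#'   [instrument_registry()].
#' @return A `waveform`.
#' @export
synth_instrument <- function(spec) {
  stopifnot(inherits(spec, "tone_spec"))
  if (spec$kind != "instrument") stop("spec$kind must be 'instrument'")
  reg <- instrument_registry()
  row <- reg[reg$timbre == spec$timbre_id, ]
  if (nrow(row) != 1L) stop("unknown timbre id: ", spec$timbre_id)
  rate <- spec$rate_hz
  if (spec$f0_hz >= rate / 4) stop("f0 too high for sampling rate")
  n <- round(spec$duration_ms / 1000 * rate)
  t <- (seq_len(n) - 1) / rate
  tilt <- row$tilt_db_oct + (spec$brightness + 12)   # brightness offset vs default
  fmax <- min(5000, 0.45 * rate)
  kmax <- max(1L, floor(fmax / spec$f0_hz))
  # vibrato: ~0.4% frequency excursion at 5.5 Hz for bowed strings
  phase_t <- if (row$vibrato) {
    t + (0.004 / (2 * pi * 5.5)) * sin(2 * pi * 5.5 * t)
  } else t
  harm <- numeric(n)
  for (k in seq_len(kmax)) {
    fk <- k * spec$f0_hz * sqrt(1 + row$inharmonicity * k^2)
    if (fk >= fmax) break
    amp <- 10^(tilt * log2(k) / 20)
    if (k %% 2 == 0) amp <- amp * row$even_atten
    # bowed strings carry the vibrato phase track; inharmonicity only applies
    # to the struck/plucked strings, which have no vibrato
    harm <- harm + amp * sin(2 * pi * fk * phase_t)
  }
  out <- with_seed(spec$seed, {
    noise <- .shaped_noise(n, rate, function(f) {
      10^(tilt * log2(pmax(f, spec$f0_hz) / spec$f0_hz) / 20)
    }, fmax)
    .mix_at_hnr(harm, noise, spec$target_hnr_db)
  })
  # attack / decay amplitude envelope applied to the full mixture so the
  # harmonic-to-noise power ratio is constant over time
  env <- rep(1, n)
  atk <- row$attack_ms / 1000
  in_atk <- t < atk
  env[in_atk] <- 0.5 * (1 - cos(pi * t[in_atk] / atk))
  if (!is.na(row$decay_tau_ms)) {
    tau <- row$decay_tau_ms / 1000
    env <- env * exp(-pmax(t - atk, 0) / tau)
  }
  waveform(out * env, rate)
}

#' Synthesize a tone from its spec
#' @param spec A `tone_spec`.
#' @return A `waveform`.
#' @export
synth_tone <- function(spec) {
  if (spec$kind == "vowel") synth_vowel(spec) else synth_instrument(spec)
}

#' Default stimulus-bank configuration
#'
#' The first experiment's conditions: two categories of 16 sounds (4 vowels x
#' 4 singers; 16 instruments) at the 12 equal-tempered pitches A3..G#4,
#' 128-ms duration, RMS-equalized, 5-ms raised-cosine onset and offset ramps.
#' Per-timbre target HNRs are drawn once from the category distributions
#' N(24.1, 5.5) dB for voices and N(23.5, 3.5) dB for instruments.
#'
#' @param duration_ms Stimulus duration (128 for the one-back experiment,
#'   250 for chimera donors).
#' @param rate_hz Sampling rate.
#' @param rms Common RMS amplitude.
#' @param seed Seed for the per-timbre HNR draws and the per-stimulus noise.
#' @return A configuration list.
#' @export
bank_config <- function(duration_ms = 128, rate_hz = 44100, rms = 0.05,
                        seed = 1L) {
  vowels <- c("a", "e", "i", "o")
  singers <- names(.singer_scale)
  voice_timbres <- as.vector(outer(vowels, singers, paste, sep = "_"))
  list(
    categories = c("voice", "instrument"),
    voice_timbres = voice_timbres,
    instrument_timbres = instrument_registry()$timbre,
    pitches = names(pitch_grid()),
    duration_ms = duration_ms,
    rate_hz = rate_hz,
    rms = rms,
    ramp_ms = 5,
    hnr_mean_db = c(voice = 24.1, instrument = 23.5),
    hnr_sd_db = c(voice = 5.5, instrument = 3.5),
    seed = as.integer(seed)
  )
}

#' Read a stimulus-bank configuration from a YAML file
#'
#' Recognized keys mirror the arguments and fields of [bank_config()]; absent
#' keys take the defaults.
#'
#' @param path YAML file path.
#' @return A configuration list.
#' @export
bank_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- bank_config()
  for (k in intersect(names(y), names(cfg))) cfg[[k]] <- y[[k]]
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Manifest of the stimulus bank (no synthesis)
#'
#' Enumerates every (category, timbre, pitch) combination of a configuration
#' with its identifier, target HNR and fundamental frequency. Useful when only
#' the combinatorics are needed (e.g. building trial sequences).
#'
#' @param config A [bank_config()] list.
#' @return A data.frame with one row per stimulus.
#' @export
bank_manifest <- function(config = bank_config()) {
  if (length(config$voice_timbres) == 0 || length(config$instrument_timbres) == 0) {
    stop("category timbre lists must be non-empty")
  }
  timbres <- c(config$voice_timbres, config$instrument_timbres)
  categories <- rep(c("voice", "instrument"),
                    c(length(config$voice_timbres), length(config$instrument_timbres)))
  hnr_by_timbre <- with_seed(config$seed, {
    stats::rnorm(length(timbres),
                 mean = config$hnr_mean_db[categories],
                 sd = config$hnr_sd_db[categories])
  })
  hnr_by_timbre <- pmin(pmax(hnr_by_timbre, 5), 40)
  grid <- expand.grid(pitch = config$pitches, idx = seq_along(timbres),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- data.frame(
    id = paste(categories[grid$idx], timbres[grid$idx], grid$pitch, sep = "_"),
    category = categories[grid$idx],
    timbre = timbres[grid$idx],
    pitch = grid$pitch,
    f0_hz = note_to_hz(grid$pitch),
    target_hnr_db = hnr_by_timbre[grid$idx],
    stringsAsFactors = FALSE
  )
  out[order(out$category, out$timbre, out$f0_hz), , drop = FALSE]
}

#' Build the full stimulus bank
#'
#' Synthesizes every stimulus in the manifest, applies 5-ms raised-cosine
#' onset and offset ramps and equalizes all waveforms to the common RMS.
#'
#' @param config A [bank_config()] list.
#' @return A list of class `stimulus_bank`; each element has the manifest row
#'   fields plus `spec` and `wave`.
#' @export
build_stimulus_bank <- function(config = bank_config()) {
  man <- bank_manifest(config)
  entries <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    row <- man[i, ]
    kind <- if (row$category == "voice") "vowel" else "instrument"
    seed_i <- (config$seed * 100003 + i * 7919) %% 2147483647
    spec <- tone_spec(kind, row$timbre, row$f0_hz,
                      duration_ms = config$duration_ms,
                      target_hnr_db = row$target_hnr_db,
                      seed = seed_i, rate_hz = config$rate_hz)
    w <- synth_tone(spec)
    w <- apply_onset_ramp(w, config$ramp_ms)
    w <- apply_offset_ramp(w, config$duration_ms, config$ramp_ms)
    w <- rms_normalize(w, config$rms)
    entries[[i]] <- list(id = row$id, category = row$category,
                         timbre = row$timbre, pitch = row$pitch,
                         f0_hz = row$f0_hz, spec = spec, wave = w)
  }
  structure(entries, class = "stimulus_bank", manifest = man, config = config)
}

#' Write a stimulus bank to WAV files
#'
#' Filenames encode category, timbre and pitch (`<id>.wav`).
#'
#' @param bank A `stimulus_bank`.
#' @param dir Output directory (created if needed).
#' @param format WAV sample format, see [write_wav()].
#' @return The written file paths, invisibly.
#' @export
write_bank_wavs <- function(bank, dir, format = "pcm16") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(bank, function(e) {
    p <- file.path(dir, paste0(e$id, ".wav"))
    write_wav(e$wave, p, format)
    p
  }, character(1))
  invisible(paths)
}
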