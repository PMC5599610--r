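#' Per-band RMS levels of a band decomposition
#'
#' The "auditory spectrum" used for chimera construction: the RMS of each
#' band signal over the full stimulus duration.
#'
#' @param bands A `band_decomposition`.
#' @return Numeric vector of per-channel RMS levels.
#' @export
band_levels <- function(bands) {
  stopifnot(inherits(bands, "band_decomposition"))
  sqrt(rowMeans(bands$bands^2))
}

#' Rescaled chimera bands (pre-summation)
#'
#' Each band of the temporal donor is rescaled so its RMS equals the spectral
#' donor's corresponding band RMS. Bands whose spectral-donor level lies more
#' than `floor_db` below the maximum band level are left silent, as are bands
#' where the temporal donor itself is below the floor (so that near-silent
#' numerical noise is never amplified).
#'
#' @param temporal_donor,spectral_donor `waveform`s of equal duration and rate.
#' @param config A [fb_config()].
#' @param floor_db Level floor below the maximum band (default 60 dB).
#' @return A `band_decomposition` carrying the rescaled bands, with attribute
#'   `target_levels` (the spectral donor's band levels, zeroed below floor).
#' @export
chimera_bands <- function(temporal_donor, spectral_donor, config = fb_config(),
                          floor_db = 60) {
  stopifnot(inherits(temporal_donor, "waveform"),
            inherits(spectral_donor, "waveform"))
  if (temporal_donor$rate_hz != spectral_donor$rate_hz) {
    stop("donor sampling rates differ")
  }
  if (length(temporal_donor$samples) != length(spectral_donor$samples)) {
    stop("donor durations differ")
  }
  bt <- gammatone_filterbank(temporal_donor, config)
  bs <- gammatone_filterbank(spectral_donor, config)
  lt <- band_levels(bt)
  ls <- band_levels(bs)
  floor_lin <- max(ls) * 10^(-floor_db / 20)
  floor_t <- max(lt) * 10^(-floor_db / 20)
  out <- bt$bands
  target <- ls
  for (k in seq_along(lt)) {
    if (ls[k] < floor_lin || lt[k] < floor_t) {
      out[k, ] <- 0
      target[k] <- 0
    } else {
      out[k, ] <- out[k, ] * (ls[k] / lt[k])
    }
  }
  structure(list(bands = out, cf_hz = bt$cf_hz, rate_hz = bt$rate_hz),
            class = "band_decomposition", target_levels = target)
}

#' Build an auditory chimera
#'
#' Produces a sound with the temporal structure (frequency-dependent
#' envelopes) of `temporal_donor` and the auditory spectrum (per-band levels)
#' of `spectral_donor`: the temporal donor's gammatone bands are rescaled to
#' the spectral donor's band levels and summed. The result is RMS-normalized
#' and offset-ramped like the natural stimuli.
#'
#' @inheritParams chimera_bands
#' @param rms Output RMS (default 0.05, the bank default).
#' @param ramp_ms Raised-cosine offset ramp (default 5 ms).
#' @return A `waveform`.
#' @export
make_chimera <- function(temporal_donor, spectral_donor, config = fb_config(),
                         floor_db = 60, rms = 0.05, ramp_ms = 5) {
  cb <- chimera_bands(temporal_donor, spectral_donor, config, floor_db)
  w <- waveform(colSums(cb$bands), cb$rate_hz)
  w <- apply_offset_ramp(w, 1000 * duration_s(w), ramp_ms)
  rms_normalize(w, rms)
}

#' Synthesize the four chimera donors at each pitch
#'
#' The donors of the factorial chimera set: the vowels /a/ and /i/ and
#' violin-like and cello-like tones, truncated at `duration_ms` (250 ms by
#' default), at each of the 12 pitches A3..G#4.
#'
#' @param duration_ms Donor duration (default 250).
#' @param rate_hz Sampling rate.
#' @param rms Common RMS.
#' @param seed Synthesis seed.
#' @param pitches Note names (default the full 12-pitch grid).
#' @return A list indexed by pitch name; each element is a named list of four
#'   `waveform`s (`a`, `i`, `violin`, `cello`) with a `category` attribute.
#' @export
build_chimera_donors <- function(duration_ms = 250, rate_hz = 44100,
                                 rms = 0.05, seed = 1L,
                                 pitches = names(pitch_grid())) {
  donor_ids <- c(a = "voice", i = "voice", violin = "instrument",
                 cello = "instrument")
  out <- list()
  i <- 0L
  for (p in pitches) {
    f0 <- note_to_hz(p)
    waves <- list()
    for (d in names(donor_ids)) {
      i <- i + 1L
      kind <- if (donor_ids[[d]] == "voice") "vowel" else "instrument"
      spec <- tone_spec(kind, d, f0, duration_ms = duration_ms,
                        target_hnr_db = 24,
                        seed = (seed * 99991 + i * 104729) %% 2147483647,
                        rate_hz = rate_hz)
      w <- synth_tone(spec)
      w <- apply_onset_ramp(w, 5)
      w <- apply_offset_ramp(w, duration_ms, 5)
      waves[[d]] <- rms_normalize(w, rms)
    }
    attr(waves, "category") <- donor_ids
    out[[p]] <- waves
  }
  out
}

#' Generate the full factorial chimera stimulus set
#'
#' Crosses the four donors pairwise at each pitch, including self-pairs, so
#' all four cells of the 2 x 2 design (Temporal structure x auditory Spectrum,
#' each Voice or Instrument) pass through the same filterbank path: 16
#' stimuli per pitch, 192 in total for 12 pitches.
#'
#' @param donors Output of [build_chimera_donors()]: per pitch, exactly the
#'   four named donors `a`, `i`, `violin`, `cello`.
#' @param config A [fb_config()].
#' @param rms Output RMS.
#' @return A `chimera_set`: list of records with fields `id`, `pitch`,
#'   `temporal_id`, `spectral_id`, `T_label`, `S_label`, `condition`, `wave`.
#' @export
generate_chimera_set <- function(donors, config = fb_config(), rms = 0.05) {
  required <- c("a", "i", "violin", "cello")
  out <- list()
  for (p in names(donors)) {
    dl <- donors[[p]]
    if (!all(required %in% names(dl))) {
      stop("missing donor at pitch ", p, ": need ",
           paste(required, collapse = ", "))
    }
    cat_of <- attr(dl, "category")
    if (is.null(cat_of)) {
      cat_of <- c(a = "voice", i = "voice", violin = "instrument",
                  cello = "instrument")
    }
    for (t_id in required) {
      for (s_id in required) {
        w <- make_chimera(dl[[t_id]], dl[[s_id]], config, rms = rms)
        T_label <- if (cat_of[[t_id]] == "voice") "Voice" else "Instrument"
        S_label <- if (cat_of[[s_id]] == "voice") "Voice" else "Instrument"
        out[[length(out) + 1L]] <- list(
          id = sprintf("chim_%s_T-%s_S-%s", p, t_id, s_id),
          pitch = p, temporal_id = t_id, spectral_id = s_id,
          T_label = T_label, S_label = S_label,
          condition = condition_label(T_label, S_label),
          wave = w)
      }
    }
  }
  structure(out, class = "chimera_set")
}

#' Condition label for a (Temporal, Spectrum) cell
#'
#' `Voice` when both factors are Voice, `Instrument` when both are
#' Instrument; the mixed cells are chimeras named for which feature set they
#' inherit from the voice.
#'
#' @param T_label,S_label `"Voice"` or `"Instrument"`.
#' @return Condition string.
#' @export
condition_label <- function(T_label, S_label) {
  if (T_label == "Voice" && S_label == "Voice") "Voice"
  else if (T_label == "Instrument" && S_label == "Instrument") "Instrument"
  else if (S_label == "Voice") "Chimera_SpectrumVoice"
  else "Chimera_TemporalVoice"
}

#' Label table of a chimera set
#' @param set A `chimera_set`.
#' @return A data.frame with one row per stimulus (no waveforms).
#' @export
chimera_labels <- function(set) {
  do.call(rbind, lapply(set, function(e) {
    data.frame(id = e$id, pitch = e$pitch, temporal_id = e$temporal_id,
               spectral_id = e$spectral_id, T_label = e$T_label,
               S_label = e$S_label, condition = e$condition,
               stringsAsFactors = FALSE)
  }))
}

#' Write a chimera set as WAV files plus a label table
#'
#' Batch interface: emits one WAV per stimulus and a TSV with the factorial
#' labels.
#'
#' @param set A `chimera_set`.
#' @param dir Output directory.
#' @param format WAV format, see [write_wav()].
#' @return Path of the label table, invisibly.
#' @export
write_chimera_batch <- function(set, dir, format = "pcm16") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (e in set) write_wav(e$wave, file.path(dir, paste0(e$id, ".wav")), format)
  tab <- chimera_labels(set)
  path <- file.path(dir, "chimera_labels.tsv")
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
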