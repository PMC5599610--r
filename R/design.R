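# Onset and block arithmetic shared by both experiments: trials at a fixed
# SOA with an extra pause inserted after every `trials_per_block` trials.
.sequence_onsets <- function(n_trials, soa_s, pause_s, trials_per_block) {
  i <- seq_len(n_trials) - 1L
  n_pauses <- i %/% trials_per_block
  list(onset_s = i * soa_s + n_pauses * pause_s,
       block = as.integer(n_pauses + 1L))
}

#' Build the one-back event-related trial sequence (Experiment 1 design)
#'
#' Each of the 384 bank stimuli appears on two base trials (768 trials),
#' shuffled with `seed`; one in twenty base trials (floor(768/20) = 38) is
#' selected for an immediate one-back repetition, inserted directly after its
#' original, giving 806 trials in total. Trials run at a 2-s SOA; each trial
#' denotes six identical 128-ms presentations (768 ms of sound). Twenty-second
#' pauses occur every 290 s, forming six blocks.
#'
#' @param bank A `stimulus_bank` or its manifest data.frame (columns `id`,
#'   `category`); must contain 2 categories x 16 sounds x 12 pitches.
#' @param seed Shuffle seed.
#' @param soa_s,pause_s,pause_every_s Timing parameters (defaults 2, 20, 290).
#' @return A `trial_sequence` data.frame with columns `onset_s`, `condition`,
#'   `stimulus_id`, `is_repeat`, `block`, and attributes `soa_s`, `pause_s`,
#'   `pause_every_s`, `n_blocks`, `sound_ms` (768), `reps_per_trial` (6).
#' @export
build_expt1_sequence <- function(bank, seed = 1L, soa_s = 2, pause_s = 20,
                                 pause_every_s = 290) {
  man <- if (inherits(bank, "stimulus_bank")) attr(bank, "manifest")
         else as.data.frame(bank)
  if (nrow(man) != 384L || length(unique(man$category)) != 2L) {
    stop("bank must contain 2 categories x 16 sounds x 12 pitches = 384 stimuli")
  }
  base <- man[rep(seq_len(nrow(man)), each = 2L), c("id", "category")]
  seq_df <- with_seed(seed, {
    ord <- sample.int(nrow(base))
    shuffled <- base[ord, , drop = FALSE]
    n_rep <- floor(nrow(base) / 20)          # one in twenty trials
    rep_at <- sort(sample.int(nrow(base), n_rep))
    out <- data.frame(
      stimulus_id = character(0), condition = character(0),
      is_repeat = logical(0), stringsAsFactors = FALSE)
    rows <- vector("list", nrow(base))
    for (j in seq_len(nrow(base))) {
      rows[[j]] <- data.frame(stimulus_id = shuffled$id[j],
                              condition = shuffled$category[j],
                              is_repeat = FALSE, stringsAsFactors = FALSE)
      if (j %in% rep_at) {
        rows[[j]] <- rbind(rows[[j]],
                           data.frame(stimulus_id = shuffled$id[j],
                                      condition = shuffled$category[j],
                                      is_repeat = TRUE, stringsAsFactors = FALSE))
      }
    }
    do.call(rbind, rows)
  })
  trials_per_block <- round(pause_every_s / soa_s)
  tim <- .sequence_onsets(nrow(seq_df), soa_s, pause_s, trials_per_block)
  out <- data.frame(onset_s = tim$onset_s, condition = seq_df$condition,
                    stimulus_id = seq_df$stimulus_id,
                    is_repeat = seq_df$is_repeat, block = tim$block,
                    stringsAsFactors = FALSE)
  structure(out, class = c("trial_sequence", "data.frame"),
            soa_s = soa_s, pause_s = pause_s, pause_every_s = pause_every_s,
            n_blocks = max(tim$block), sound_ms = 6 * 128, reps_per_trial = 6L)
}

#' Build the categorization trial sequence (Experiment 2 design)
#'
#' The 192 factorial chimera-set stimuli are each presented twice (384
#' trials) in seeded pseudo-random order at a 2-s SOA; on each trial the
#' 250-ms stimulus repeats four times (1 s of sound). Twenty-second pauses
#' occur every 296 s, forming three blocks. Conditions follow the 2 x 2
#' (Temporal structure, Spectrum) factorial.
#'
#' @param labels A `chimera_set` or its [chimera_labels()] data.frame
#'   (columns `id`, `condition`, `T_label`, `S_label`); must have 192 rows.
#' @param seed Shuffle seed.
#' @param soa_s,pause_s,pause_every_s Timing parameters (defaults 2, 20, 296).
#' @return A `trial_sequence` with the same columns as
#'   [build_expt1_sequence()] plus `T_label` and `S_label`; attribute
#'   `sound_ms` is 1000 and `reps_per_trial` 4.
#' @export
build_expt2_sequence <- function(labels, seed = 1L, soa_s = 2, pause_s = 20,
                                 pause_every_s = 296) {
  lab <- if (inherits(labels, "chimera_set")) chimera_labels(labels)
         else as.data.frame(labels)
  if (nrow(lab) != 192L) stop("chimera set must contain 192 labelled stimuli")
  base <- lab[rep(seq_len(nrow(lab)), each = 2L), , drop = FALSE]
  shuffled <- with_seed(seed, base[sample.int(nrow(base)), , drop = FALSE])
  trials_per_block <- round(pause_every_s / soa_s)
  tim <- .sequence_onsets(nrow(shuffled), soa_s, pause_s, trials_per_block)
  out <- data.frame(onset_s = tim$onset_s, condition = shuffled$condition,
                    stimulus_id = shuffled$id, is_repeat = FALSE,
                    block = tim$block, T_label = shuffled$T_label,
                    S_label = shuffled$S_label, stringsAsFactors = FALSE)
  structure(out, class = c("trial_sequence", "data.frame"),
            soa_s = soa_s, pause_s = pause_s, pause_every_s = pause_every_s,
            n_blocks = max(tim$block), sound_ms = 4 * 250, reps_per_trial = 4L)
}

#' @export
print.trial_sequence <- function(x, ...) {
  cat(sprintf("<trial_sequence: %d trials (%d base + %d repeats), %d blocks, SOA %g s, %g ms sound/trial>\n",
              nrow(x), sum(!x$is_repeat), sum(x$is_repeat),
              attr(x, "n_blocks"), attr(x, "soa_s"), attr(x, "sound_ms")))
  invisible(as.data.frame(x))
}

#' Write a trial sequence as a BIDS-flavoured events TSV
#'
#' Columns: onset, duration, trial_type, stimulus_id, is_repeat, block.
#' Duration is the per-trial sound duration (mini-block of repetitions).
#'
#' @param seq A `trial_sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(seq, path) {
  df <- data.frame(onset = seq$onset_s,
                   duration = attr(seq, "sound_ms") / 1000,
                   trial_type = seq$condition,
                   stimulus_id = seq$stimulus_id,
                   is_repeat = tolower(as.character(seq$is_repeat)),
                   block = seq$block)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Attribute button presses to trials
#'
#' Each press is associated with the trial whose onset lies in the preceding
#' 100-2100 ms (inclusive window \[t-2100, t-100\] ms). When two trials
#' qualify (exactly at the window edges) the press is assigned to the more
#' recent trial; presses with no qualifying trial are left unmatched.
#'
#' @param seq A `trial_sequence`.
#' @param presses Data.frame with columns `time_s` and `button` (button may
#'   be any label, e.g. `"voice"`/`"instrument"` or `"repeat"`).
#' @param window_s Attribution window relative to the press (default
#'   `c(0.1, 2.1)` seconds before the press).
#' @return A data.frame: one row per press with `time_s`, `button`,
#'   `trial` (index into `seq`, NA if unmatched).
#' @export
attribute_responses <- function(seq, presses, window_s = c(0.1, 2.1)) {
  onsets <- seq$onset_s
  trial <- vapply(presses$time_s, function(t) {
    # small tolerance so exact window-edge presses are not lost to float error
    ok <- which(onsets >= t - window_s[2] - 1e-9 &
                  onsets <= t - window_s[1] + 1e-9)
    if (length(ok) == 0L) NA_integer_ else max(ok)   # tie: more recent trial
  }, integer(1))
  data.frame(time_s = presses$time_s, button = presses$button, trial = trial,
             stringsAsFactors = FALSE)
}

#' Score the one-back task
#'
#' Hits are repeat trials that received at least one attributed press; false
#' alarms are presses attributed to non-repeat trials.
#'
#' @param seq An Experiment-1 style `trial_sequence` (with repeat trials).
#' @param presses Press data.frame (`time_s`, `button`), or the output of
#'   [attribute_responses()].
#' @return A list with `hit_rate`, `fa_rate`, `n_repeats`, `n_nonrepeats`,
#'   `n_unmatched` presses.
#' @export
score_one_back <- function(seq, presses) {
  attr_df <- if ("trial" %in% names(presses)) presses
             else attribute_responses(seq, presses)
  responded <- rep(FALSE, nrow(seq))
  responded[attr_df$trial[!is.na(attr_df$trial)]] <- TRUE
  is_rep <- seq$is_repeat
  list(hit_rate = if (any(is_rep)) mean(responded[is_rep]) else NA_real_,
       fa_rate = mean(responded[!is_rep]),
       n_repeats = sum(is_rep), n_nonrepeats = sum(!is_rep),
       n_unmatched = sum(is.na(attr_df$trial)))
}

#' Tally voice categorizations per condition
#'
#' For each condition, the proportion of countable trials categorized as
#' "voice": trials where both or neither button was pressed are excluded from
#' the denominator. If a participant's responses on the pure conditions
#' indicate systematic button reversal (voice rate below 50% for pure Voice
#' AND above 50% for pure Instrument), their labels are flipped before
#' tallying.
#'
#' @param seq An Experiment-2 style `trial_sequence`.
#' @param presses Press data.frame with `button` in `{"voice","instrument"}`.
#' @param pure_conditions Names of the pure cells used for reversal detection
#'   (default `c("Voice", "Instrument")`).
#' @return A list with `prop_voice` (named per condition), `n_counted`,
#'   `excluded_fraction`, `reversed`.
#' @export
tally_categorization <- function(seq, presses,
                                 pure_conditions = c("Voice", "Instrument")) {
  attr_df <- attribute_responses(seq, presses)
  attr_df <- attr_df[!is.na(attr_df$trial), , drop = FALSE]
  n_trials <- nrow(seq)
  voice_p <- tapply(attr_df$button == "voice", attr_df$trial, any)
  instr_p <- tapply(attr_df$button == "instrument", attr_df$trial, any)
  got <- as.integer(names(voice_p))
  pressed_voice <- pressed_instr <- rep(FALSE, n_trials)
  pressed_voice[got] <- voice_p
  pressed_instr[got] <- instr_p
  countable <- xor(pressed_voice, pressed_instr)
  voted_voice <- pressed_voice & countable
  tally <- function(vv) {
    conds <- sort(unique(seq$condition))
    sapply(conds, function(cc) {
      sel <- countable & seq$condition == cc
      if (!any(sel)) stop("condition with zero countable trials: ", cc)
      mean(vv[sel])
    })
  }
  prop <- tally(voted_voice)
  reversed <- FALSE
  if (all(pure_conditions %in% names(prop)) &&
      prop[pure_conditions[1]] < 0.5 && prop[pure_conditions[2]] > 0.5) {
    reversed <- TRUE
    prop <- tally(!voted_voice & countable)
  }
  list(prop_voice = prop, n_counted = sum(countable),
       excluded_fraction = 1 - mean(countable), reversed = reversed)
}

#' Simulate a one-back responder
#'
#' Presses after repeat trials with probability `hit_p` and after non-repeat
#' trials with probability `fa_p`, at a reaction time drawn uniformly from
#' `rt_s`.
#'
#' @param seq A `trial_sequence`.
#' @param hit_p,fa_p Response probabilities.
#' @param rt_s Reaction-time range in seconds (default 0.3-1.2).
#' @param seed RNG seed.
#' @return A press data.frame (`time_s`, `button`).
#' @export
simulate_one_back_responder <- function(seq, hit_p = 0.9, fa_p = 0.02,
                                        rt_s = c(0.3, 1.2), seed = 1L) {
  with_seed(seed, {
    p <- ifelse(seq$is_repeat, hit_p, fa_p)
    press <- stats::runif(nrow(seq)) < p
    data.frame(time_s = seq$onset_s[press] +
                 stats::runif(sum(press), rt_s[1], rt_s[2]),
               button = "repeat", stringsAsFactors = FALSE)
  })
}

#' Default condition-wise voice-response probabilities
#'
#' The observed categorization pattern: pure voices almost always "voice",
#' chimeras with the voice spectrum mostly "voice" (59%), intact instruments
#' and chimeras with only the vocal temporal structure rarely (8% and 4%).
#' Both-button and no-button lapses occur on 0.3% and 1% of trials.
#'
#' @return A list with `p_voice` (named per condition), `p_both`, `p_neither`.
#' @export
categorization_probs <- function() {
  list(p_voice = c(Voice = 0.95, Chimera_SpectrumVoice = 0.59,
                   Instrument = 0.08, Chimera_TemporalVoice = 0.04),
       p_both = 0.003, p_neither = 0.01)
}

#' Simulate a categorization responder
#'
#' @param seq An Experiment-2 style `trial_sequence`.
#' @param probs Response model, see [categorization_probs()].
#' @param rt_s Reaction-time range (default 0.3-1.2 s).
#' @param seed RNG seed.
#' @param reversed If TRUE the responder uses the buttons with opposite
#'   senses.
#' @return A press data.frame (`time_s`, `button`).
#' @export
simulate_categorization_responder <- function(seq, probs = categorization_probs(),
                                              rt_s = c(0.3, 1.2), seed = 1L,
                                              reversed = FALSE) {
  with_seed(seed, {
    rows <- list()
    for (j in seq_len(nrow(seq))) {
      u <- stats::runif(1)
      rt <- stats::runif(1, rt_s[1], rt_s[2])
      t_press <- seq$onset_s[j] + rt
      if (u < probs$p_neither) next
      both <- u < probs$p_neither + probs$p_both
      p_v <- probs$p_voice[[seq$condition[j]]]
      voice <- stats::runif(1) < p_v
      if (reversed) voice <- !voice
      if (both) {
        rows[[length(rows) + 1L]] <- data.frame(
          time_s = c(t_press, t_press + 0.05),
          button = c("voice", "instrument"), stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          time_s = t_press,
          button = if (voice) "voice" else "instrument",
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}
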