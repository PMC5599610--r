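man <- bank_manifest()
seq1 <- build_expt1_sequence(man, seed = 31)
lab2 <- voicechimera:::.factorial_label_table()
seq2 <- build_expt2_sequence(lab2, seed = 31)

test_that("the one-back sequence has 768 base, 38 repeat, 806 total trials", {
  expect_equal(sum(!seq1$is_repeat), 768L)
  expect_equal(sum(seq1$is_repeat), 38L)     # floor(768 / 20)
  expect_equal(nrow(seq1), 806L)
  expect_equal(attr(seq1, "sound_ms"), 768)  # 6 x 128 ms mini-block
  expect_equal(attr(seq1, "n_blocks"), 6L)
  # every stimulus appears exactly twice among base trials
  expect_true(all(table(seq1$stimulus_id[!seq1$is_repeat]) == 2))
  # each repeat directly follows its original with the same id
  ri <- which(seq1$is_repeat)
  expect_true(all(seq1$stimulus_id[ri] == seq1$stimulus_id[ri - 1]))
  expect_true(all(!seq1$is_repeat[ri - 1]))  # no repeat-of-a-repeat
  expect_error(build_expt1_sequence(man[1:100, ], seed = 1), "384")
})

test_that("the categorization sequence has 384 balanced factorial trials", {
  expect_equal(nrow(seq2), 384L)
  expect_true(all(table(seq2$condition) == 96))
  expect_equal(attr(seq2, "sound_ms"), 1000) # 4 x 250 ms
  expect_equal(attr(seq2, "n_blocks"), 3L)
  expect_true(all(table(seq2$stimulus_id) == 2))
  expect_error(build_expt2_sequence(lab2[1:100, ], seed = 1), "192")
})

test_that("onsets follow SOA plus 20 s per elapsed pause; seeds reproduce", {
  i <- seq_len(nrow(seq1)) - 1
  expect_equal(seq1$onset_s, i * 2 + 20 * (i %/% 145))
  j <- seq_len(nrow(seq2)) - 1
  expect_equal(seq2$onset_s, j * 2 + 20 * (j %/% 148))
  # same seed bit-identical; different seed permutes but preserves counts
  again <- build_expt1_sequence(man, seed = 31)
  expect_identical(seq1, again)
  other <- build_expt1_sequence(man, seed = 32)
  expect_false(identical(other$stimulus_id, seq1$stimulus_id))
  # base trials hold the same multiset of ids; repeat count is preserved
  expect_equal(sort(other$stimulus_id[!other$is_repeat]),
               sort(seq1$stimulus_id[!seq1$is_repeat]))
  expect_equal(nrow(other), 806L)
})

test_that("events export as BIDS-style TSV", {
  path <- tempfile(fileext = ".tsv")
  write_events_tsv(seq2, path)
  ev <- read.delim(path)
  expect_named(ev, c("onset", "duration", "trial_type", "stimulus_id",
                     "is_repeat", "block"))
  expect_equal(nrow(ev), 384L)
  expect_true(all(ev$duration == 1))
  unlink(path)
})

test_that("presses attribute to the trial in the preceding 100-2100 ms", {
  toy <- data.frame(onset_s = c(0, 2, 4), condition = "x",
                    stimulus_id = c("s1", "s2", "s3"), is_repeat = FALSE,
                    block = 1L)
  class(toy) <- c("trial_sequence", "data.frame")
  attr(toy, "soa_s") <- 2
  got <- attribute_responses(toy, data.frame(
    time_s = c(3.0, 2.05, 4.1, 0.05), button = "b"))
  expect_equal(got$trial[1], 2L)     # onset + 1.0 s: that trial
  expect_equal(got$trial[2], 1L)     # onset + 0.05 s: previous trial
  expect_equal(got$trial[3], 3L)     # eligible for trials 2 and 3: later wins
  expect_true(is.na(got$trial[4]))   # before any attributable window
})

test_that("one-back scoring separates perfect, silent and random responders", {
  perfect <- data.frame(time_s = seq1$onset_s[seq1$is_repeat] + 0.8,
                        button = "repeat")
  sc <- score_one_back(seq1, perfect)
  expect_equal(sc$hit_rate, 1)
  expect_equal(sc$fa_rate, 0)
  silent <- score_one_back(seq1, data.frame(time_s = numeric(0),
                                            button = character(0)))
  expect_equal(silent$hit_rate, 0)
  fa <- sapply(1:10, function(s) {
    presses <- simulate_one_back_responder(seq1, hit_p = 0.1, fa_p = 0.1,
                                           seed = s)
    score_one_back(seq1, presses)$fa_rate
  })
  expect_equal(mean(fa), 0.1, tolerance = 0.25)   # simulation mean near fa_p
})

test_that("categorization tallies exclude both/neither trials and flag reversal", {
  presses <- simulate_categorization_responder(seq2, seed = 41)
  tl <- tally_categorization(seq2, presses)
  expect_false(tl$reversed)
  p <- tl$prop_voice
  # ordering of the observed pattern: Voice > spectrum-voice chimera > rest
  expect_gt(p[["Voice"]], p[["Chimera_SpectrumVoice"]])
  expect_gt(p[["Chimera_SpectrumVoice"]], p[["Instrument"]])
  expect_gt(p[["Instrument"]], p[["Chimera_TemporalVoice"]])
  expect_lt(tl$excluded_fraction, 0.05)
  # a reversed responder is detected and flipped back
  rev_presses <- simulate_categorization_responder(seq2, seed = 41,
                                                   reversed = TRUE)
  tl_rev <- tally_categorization(seq2, rev_presses)
  expect_true(tl_rev$reversed)
  expect_gt(tl_rev$prop_voice[["Voice"]], 0.5)
  expect_lt(tl_rev$prop_voice[["Instrument"]], 0.5)
})

test_that("both-button trials leave the denominator", {
  toy <- data.frame(onset_s = c(0, 2, 4, 6), condition = "Voice",
                    stimulus_id = paste0("s", 1:4), is_repeat = FALSE,
                    block = 1L)
  class(toy) <- c("trial_sequence", "data.frame")
  attr(toy, "soa_s") <- 2
  presses <- data.frame(
    time_s = c(0.5, 2.5, 2.6, 4.5),
    button = c("voice", "voice", "instrument", "voice"))
  tl <- tally_categorization(toy, presses, pure_conditions = c("none", "none"))
  expect_equal(tl$n_counted, 2L)              # trial 2 double-press excluded
  expect_equal(unname(tl$prop_voice["Voice"]), 1)
  expect_equal(tl$excluded_fraction, 0.5)
})
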