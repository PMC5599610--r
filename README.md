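# voicechimera

Stimulus engineering and simulation tools for studying **voice selectivity in
auditory cortex with acoustically matched controls**. The package is aimed at
auditory neuroscientists and psychoacousticians who want to (a) build voice
and instrument tone banks matched in pitch, duration, intensity and
harmonic-to-noise ratio (HNR), (b) construct *auditory chimeras* that carry
the temporal structure of one sound and the auditory spectrum of another,
(c) verify acoustic matching with explicit statistics, and (d) rehearse the
full event-related fMRI analysis chain — design, ROI BOLD simulation, GLM,
group statistics — with parameter recovery as the test surface.

## What it computes

**Auditory chimeras.** Both donors are decomposed by a 4th-order gammatone
filterbank with ERB-spaced center frequencies (zero-phase magnitude response
`|H(f)| = [1 + ((f − f_c)/b)²]⁻²`, `b = 1.019·ERB(f_c)`). Each band *k* of
the temporal donor is rescaled so its RMS equals the spectral donor's band
RMS, and the bands are summed:

    chimera(t) = Σ_k  x_k(t) · L_k(spectral) / L_k(temporal)

with near-silent bands left silent. The chimera inherits the spectral
donor's auditory spectrum and the temporal donor's frequency-dependent
envelopes. The factorial set crosses 4 donors (/a/, /i/, violin, cello) at
each of 12 pitches (A3–G#4): 16 stimuli per pitch, 192 total, 48 per cell of
the 2 × 2 (Temporal structure × Spectrum) design.

**Acoustic descriptors.** Per stimulus: f0 (autocorrelation period), HNR
(cross-correlation method, `10·log10(r/(1−r))` dB at the pitch-period lag,
capped at +60 dB), spectral centroid (level-weighted mean channel frequency
of the auditory spectrum), and dominant temporal rate (Hz) / spectral scale
(cycles/octave) — energy centroids of the 2-D modulation spectrum of the
auditory spectrogram over 1–32 Hz and 0.25–8 cyc/oct windows.

**Matching statistics.** One-way ANOVAs per descriptor between categories,
a match report, and a greedy matched-subset selector.

**Designs and analysis.** One-back (768 base + 38 repeat = 806 trials, six
blocks) and categorization (384 trials, three blocks) sequences with BIDS
style event TSVs; response attribution in a 100–2100 ms window; one-back and
categorization scoring. Canonical double-gamma HRF, design matrices with
serially orthogonalized parametric modulators (pitch, HNR, dominant scale,
dominant rate, centroid), AR(1) ROI BOLD simulation, OLS GLM, paired group
contrasts (df = n−1), 2 × 2 repeated-measures ANOVA, and one-way
repeated-measures ANOVA with Greenhouse–Geisser correction
(`ε = tr(S_c)²/((k−1)·ΣS_c²)`).

## Worked example

```r
library(voicechimera)

voice <- synth_vowel(tone_spec("vowel", "a", 220, duration_ms = 250,
                               target_hnr_db = 24, seed = 1))
cello <- synth_instrument(tone_spec("instrument", "cello", 220,
                                    duration_ms = 250, target_hnr_db = 24,
                                    seed = 2))
voice <- rms_normalize(apply_offset_ramp(voice, 250), 0.05)
cello <- rms_normalize(apply_offset_ramp(cello, 250), 0.05)

acoustic_profile(voice)
#> f0 = 220.0 Hz, HNR = 23.9 dB, centroid = 486 Hz,
#> dominant rate = 16.7 Hz, dominant scale = 1.14 cyc/oct

# cello temporal structure + voice auditory spectrum
ch <- make_chimera(cello, voice)
spec <- function(w) auditory_spectrum(auditory_front_end(w))$level
cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
round(c(voice = cosine(spec(ch), spec(voice)),
        cello = cosine(spec(ch), spec(cello))), 4)
#>  voice  cello
#> 0.9993 0.9906

build_expt1_sequence(bank_manifest(), seed = 1)
#> <trial_sequence: 806 trials (768 base + 38 repeats), 6 blocks, SOA 2 s, 768 ms sound/trial>

recover_voice_effect(n_sims = 200, seed = 1)
#> voice-effect recovery (200 sims, n = 22, d = 0.80):
#>   detection rate (effect ROI): 0.930
#>   type-I rate (null ROI):      0.050
#>   mean contrast: 0.391 (effect), -0.005 (null)
```

The profile says the synthetic /a/ landed on pitch (220 Hz) and on its target
harmonicity (23.9 vs 24 dB); the low centroid reflects the vowel's
first-formant-dominated spectrum. The chimera's auditory spectrum is closer
to the voice donor (cosine similarity 0.999) than to the cello that supplied
its temporal structure. The recovery report shows the group analysis detects
an injected voice effect of conventional size (d = 0.8, n = 22) in 93% of
simulated groups while keeping the false-positive rate of the null ROI at
the nominal 5%.

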