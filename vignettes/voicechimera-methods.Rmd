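---
title: "Voice-selectivity stimulus engineering and simulated ROI analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voice-selectivity stimulus engineering and simulated ROI analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Voice-selective regions of auditory cortex (the temporal voice areas, TVAs)
respond more to vocal than to nonvocal sounds. A persistent worry is that this
selectivity could reduce to low-level acoustic confounds: vocal sounds tend to
be more harmonic, brighter, or more richly modulated than typical control
sounds. The experimental strategy this package implements is to *engineer the
control sounds*: build voice and instrument stimulus sets matched in pitch,
duration, intensity and harmonic-to-noise ratio (HNR); verify the matching
with explicit statistics; and then construct *auditory chimeras* that
transplant the per-band auditory spectrum of one sound onto the temporal
structure of another, so that each chimera carries only a subset of the vocal
features. A region that responds to the voice but not to either chimera type
cannot be driven by the spectral profile or the temporal envelope alone.

`voicechimera` implements that full chain as tested, seedable code operating
on synthetic stimuli: tone-bank synthesis, an auditory-model front end,
chimera construction, acoustic descriptors, matching statistics, the two
event-related trial designs with behavioral scoring, and a simulated
region-of-interest (ROI) GLM analysis whose test surface is parameter
recovery.

# Stimulus synthesis

The synthetic bank stands in for recorded sung vowels and instrument notes.
Its defaults are the study conditions:

* two categories of 16 sounds each — 4 vowels (/a/, /e/, /i/, /o/) crossed
  with 4 "singers" (vocal-tract scale factors 0.95–1.18, two male-like and
  two female-like), and 16 instruments (oboe through cello);
* 12 equal-tempered pitches spanning one octave, A3 (220 Hz) to G#4;
* 128-ms duration for the one-back experiment, 250 ms for chimera donors;
* all stimuli RMS-equalized and faded out with a 5-ms raised-cosine offset
  ramp; a symmetric onset ramp is applied as well to avoid onset clicks, and
  is documented as a package extension;
* per-timbre target HNRs drawn once per bank from N(24.1, 5.5) dB for voices
  and N(23.5, 3.5) dB for instruments — the category
  distributions of the matched recorded stimulus sets this bank emulates —
  and clipped to [5, 40] dB.

Vowels are additive harmonic sources with a spectral-tilt parameter
(`brightness`, dB/octave, default −12) shaped by three parallel second-order
formant resonances per vowel (classic adult formant frequencies), plus
formant-shaped Gaussian aspiration noise. Instruments use per-timbre harmonic
profiles (tilt, even-harmonic attenuation, slight inharmonicity for
struck/plucked strings), attack/decay envelopes, and 5.5-Hz vibrato for the
bowed strings. In both cases harmonics and noise are band-limited to 5 kHz
and the noise gain is solved analytically from the in-band harmonic/noise
power ratio, so the realized HNR tracks the target; the amplitude envelope is
applied to the *mixture*, keeping the ratio constant over time. Synthesis is
deterministic given the spec seed. The sample rate defaults to 44.1 kHz and
is configurable.

What the generator does *not* emulate: singer identity beyond a formant scale
factor, perceptually convincing instrument timbre, room acoustics, recording
noise, or intonation drift. Passing tests therefore show that the *pipeline*
behaves correctly under controlled conditions, not that its descriptors would
numerically match measurements on recorded singing and playing.

# Auditory front end

The filterbank is a 4th-order gammatone bank with ERB-spaced center
frequencies (Glasberg–Moore ERB formula), by default 64 channels spanning
80–8000 Hz. It is implemented in the frequency domain by applying the
analytic gammatone magnitude response
$|H(f)| = [1 + ((f - f_c)/b)^2]^{-2}$, $b = 1.019\,\mathrm{ERB}(f_c)$, with
*zero phase*. Zero-phase filtering keeps the band signals time-aligned, so
summing rescaled bands (chimera resynthesis) is coherent and a self-chimera
reconstructs its input (waveform correlation ≈ 1). Signals are zero-padded
past the longest filter ringing before the FFT to avoid circular wrap.

Envelopes are computed per band by half-wave rectification followed by a
4th-order Butterworth low-pass at 70 Hz applied forward–backward (zero
phase), then decimation to a 200-Hz frame rate. Small negative excursions
introduced by the low-pass are clamped to zero, keeping the auditory
spectrogram nonnegative. The time-averaged envelope per channel is the
"auditory spectrum" used both for chimera levels and for the spectral
centroid.

Channel count and frequency bounds are configuration, with the
64-channel/80–8000-Hz default documented above. The unit and acceptance
tests that rebuild the full factorial set run a 32-channel, 100–4000-Hz bank
at 22.05 kHz — the same code path at a size that keeps the whole suite fast.

# Chimeras

A chimera takes the gammatone bands of the *temporal donor* and rescales each
band so its RMS over the full stimulus duration equals the corresponding band
RMS of the *spectral donor*; the rescaled bands are summed, RMS-normalized
and offset-ramped like natural stimuli. Band levels are equalized over the
whole duration, not frame-by-frame: the simplest construction consistent
with a level-transplant description, and the documented choice here. Bands whose spectral-donor level is more than 60 dB below the
maximum band (configurable) are left silent rather than amplified out of
numerical noise; the same floor is applied to the temporal donor so that a
near-silent band is never boosted by a huge ratio.

The factorial set crosses four donors per pitch (/a/, /i/, violin, cello) in
all ordered pairs *including self-pairs*, so the pure Voice and pure
Instrument conditions pass through the identical filterbank path and share
any resynthesis artifacts with the chimera conditions: 16 stimuli per pitch,
192 in total, 48 per cell of the 2 × 2 (Temporal structure × Spectrum)
design.

# Acoustic descriptors

Five descriptors per stimulus, in the order used as parametric modulators:
pitch (f0), HNR, dominant scale, dominant rate, spectral centroid.

* **f0** — autocorrelation period estimation over a 100–600 Hz search range;
  the smallest lag within 1% of the global maximum is taken (octave-error
  guard) and refined by parabolic interpolation. Inputs whose peak normalized
  correlation is below 0.5 raise an "unvoiced" error.
* **HNR** — cross-correlation method: in 40-ms frames with a 10-ms hop, the
  peak normalized autocorrelation *r* over the pitch-lag range gives a
  per-frame HNR of $10\log_{10}(r/(1-r))$ dB. Frames with *r* > 0.3 count as
  voiced and are averaged; when no frame reaches threshold (noise), the mean
  over all frames is returned, which is how white noise comes out below 0 dB
  rather than erroring. The estimate is capped at +60 dB. Parabolic
  interpolation of the correlation peak matters here: without it, the
  half-sample lag quantization bounds measurable HNR to ~35 dB at 220 Hz.
  The frame length, hop, search range and threshold are the package's own
  conventions; the estimator is validated against constructed harmonic+noise
  mixtures, which it recovers within ±2 dB from 0 to 40 dB.
* **Spectral centroid** — level-weighted mean of channel center frequencies
  on the linear Hz axis (to match reporting in Hz), computed from the
  auditory spectrum. Gain-invariant, strictly increasing in spectral tilt.
* **Dominant rate and scale** — the envelope matrix is interpolated onto a
  uniform log2-frequency grid, compressed with $\log(1 + \mathrm{env}/\varepsilon)$,
  mean-subtracted, and 2-D Fourier transformed over (time, log2-frequency);
  positive and negative temporal rates are folded by magnitude (the source
  description does not indicate direction-selective rates). Dominant rate
  and scale are the energy-weighted centroids over integration windows of
  1–32 Hz (DC excluded) and 0.25–8 cycles/octave; both windows are
  configuration with these defaults. The compression constant defaults to
  $\varepsilon = 4\max(\mathrm{env})$: strong enough to stabilize near-silent
  cells, weak enough that the harmonic distortion it introduces into a
  sinusoidal envelope shifts the rate centroid of a 100% AM tone by well
  under 1 Hz (with $\varepsilon = \max(\mathrm{env})$ the shift exceeds 1 Hz
  at 12–16 Hz modulation).

# Matching statistics

`match_report()` runs one between-category one-way ANOVA per descriptor and
flags descriptors significant at α = 0.05 as unmatched (the conventional
criterion level; configurable).
`select_matched_subset()` implements a greedy selection standing in for how
matched sets are chosen from a larger pool: while the target descriptor
differs significantly, drop the single item most deviant from the *other*
category's mean (ties broken by a seeded draw). The heuristic is a simple,
documented choice for a selection step usually known only by its outcome;
matching is global rather than per pitch.
Item values are never altered, only membership, and pitch coverage is
unaffected because items are timbres.

# Trial designs and behavioral scoring

*One-back design*: each of the 384 bank stimuli appears on two base trials
(768 trials, seeded uniform shuffle with no further ordering constraints);
one in twenty base trials
(⌊768/20⌋ = 38) is repeated immediately after its original, and repeats are
drawn without replacement from base trials only (no repeat-of-a-repeat),
giving 806 trials. Each trial denotes six identical 128-ms presentations
(768 ms of sound) at a 2-s SOA; 20-s pauses every 290 s partition the run
into six blocks. *Categorization design*: the 192 factorial stimuli twice
each (384 trials), four 250-ms presentations per trial (1 s of sound), 20-s
pauses every 296 s, three blocks.

Button presses attribute to the trial whose onset falls 100–2100 ms before
the press. At the window edges a press can qualify for two trials; it is
assigned to the more recent one, on the grounds that reaction times under
2 s dominate. Categorization tallies count, per condition, voice-presses
over countable trials, excluding trials where both or neither button was
pressed. A participant whose pure-condition responses indicate systematic
button reversal (voice rate < 50% for pure Voice *and* > 50% for pure
Instrument) has their labels flipped before tallying; the detection rule is
the package's own convention.

The simulated categorization responder presses "voice" with probability
0.95 / 0.59 / 0.08 / 0.04 for the Voice / spectrum-voice chimera /
Instrument / temporal-voice chimera conditions — the behavioral pattern the
pipeline is designed to emulate, with 0.95 for the pure voice as the
package's realistic choice — with both-button and no-button lapses at 0.3% and 1%.

# Simulated ROI GLM

The canonical HRF is the standard double-gamma (response gamma shape 6,
undershoot shape 16, unit dispersions, undershoot ratio 1/6, 32-s support,
unit peak). Condition event trains are built on a 0.1-s microtime grid,
convolved, and sampled at the 2-s TR. Parametric modulators are mean-centered
per-event feature values, convolved, then *serially orthogonalized* — each
against the intercept, the condition columns and all earlier modulators, in
the stated order (pitch, HNR, dominant scale, dominant rate, centroid); the
serial scheme is the conventional one. Drift modeling is an intercept only
(the simulated runs are short); a cosine drift set could be added as columns
without changing the fitting code.

Noise is Gaussian AR(1) with ρ = 0.2 by default (the standard
single-parameter approximation to BOLD autocorrelation), scaled to a
specified marginal SD.
Fitting is ordinary least squares with residual df = n − rank(X). Group
inference uses paired t tests on per-subject contrast values with
df = n − 1, the convention for within-subject condition comparisons in a
single group. The 2 × 2
repeated-measures ANOVA is computed via within-subject difference contrasts
(each effect's F(1, n−1) is the squared one-sample t of its contrast), and
the one-way repeated-measures ANOVA applies the Greenhouse–Geisser
correction with ε from the double-centered condition covariance,
ε = tr(S_c)² / ((k−1) ΣS_c²), clamped to [1/(k−1), 1].

`recover_voice_effect()` closes the loop: it simulates a group of subjects
on the factorial design in a "right-TVA-like" ROI (voice beta elevated by a
per-subject amount with between-subject effect size *d*) and a null ROI
(equal betas), runs design → simulate → fit → group contrast, and reports
detection and type-I rates. Behavioral tallies and the neural contrast are
computed by entirely separate code paths — the behavioral simulation never
feeds the GLM — mirroring the dissociation logic of the design.

# Numerical choices and degenerate inputs

* Zero-phase FFT filterbank; zero-padding past filter ringing.
* Raised-cosine ramps tolerate sub-sample overshoot of the requested end
  time from ms-to-sample rounding.
* All-zero waveforms error on RMS normalization, HNR and centroid rather
  than returning NaN; zero-variance paired differences are flagged as
  degenerate contrasts (t = 0, p = 1 when the mean difference is also zero).
* Response-window ties go to the later trial; window comparisons carry a
  1-ns tolerance so exact-edge presses are not lost to float error.
* GG ε falls back to its lower bound 1/(k−1) when the centered covariance is
  singular.
* Seeds: every stochastic function takes an explicit seed and restores the
  global RNG state on exit; identical seeds give bit-identical output.

# Problem sizes used by the test suite

The unit and acceptance tests synthesize audio at 22.05 kHz with a
32-channel filterbank for whole-set checks (all 192 chimeras, all 96
heterogeneous donor pairings) and at 44.1 kHz with the 64-channel default
for single-stimulus checks; error-rate calibration uses 1000 simulated
groups of 22 subjects, and power checks 200 groups. These sizes are the
package's own choices for a suite that a developer can run routinely.

# Known limitations

* The instrument models are schematic; they provide controllable acoustics,
  not perceptual realism.
* The chimera resynthesis exchanges whole-duration band levels only; no
  iterative spectro-temporal projection variant is provided.
* The modulation analysis uses folded rate magnitudes; direction-selective
  (signed-rate) analyses are out of scope.
* The ROI simulation is a single time series per ROI; voxelwise inference,
  smoothing and anatomical registration are out of scope.
* Group statistics measured on real scanner data depend on that data and
  are not desk-reproducible; the package's claims are about correctness and
  calibration of the analysis chain, which is what the tests compute.
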