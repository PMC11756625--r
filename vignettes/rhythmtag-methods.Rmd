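---
title: "Measuring neural synchronization to nested rhythmic periodicities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring neural synchronization to nested rhythmic periodicities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A rhythmic auditory sequence built from 300 ms events carries a hierarchy of
periodicities: the isochronous beat at 1/0.3 s = 10/3 Hz (printed as
3.33 Hz), groupings of two beats (duple meter, 5/3 ≈ 1.67 Hz) and groupings
of three beats (triple meter, 10/9 ≈ 1.11 Hz). The six-event pattern used
here — tone, rest, tone, tone, tone, rest — is metrically ambiguous: it
contains acoustic evidence for both the duple and triple readings, plus a
subharmonic at 5/9 ≈ 0.56 Hz and superharmonics at 2.22 and 2.78 Hz.

`rhythmtag` measures how strongly multichannel EEG oscillations synchronize
to each of these periodicities ("frequency tagging" in the phase domain),
and how that synchronization depends on a per-subject maturational
covariate, gestational age (GA) at the time of recording, in preterm
neonates between roughly 28 and 36 weeks GA. Because neonatal clinical EEG
cannot be redistributed, the package includes a first-class synthetic
cohort generator that reproduces the statistical structure the analysis
assumes, so every stage is testable end to end.

# The synchronization index

For each electrode and target frequency, the EEG is narrow-band filtered
(zero-phase FIR, 0.2 Hz bandwidth) around the target, the instantaneous
phase `phi_EEG(t, i)` is obtained from the Hilbert analytic signal, and it
is compared against the phase `phi_sin(t, i)` of a reference cosine whose
peaks are aligned with the event onsets. The complex synchronization index
is

    SI = 1/(I N) * sum_i sum_t exp( j |phi_EEG(t,i) - phi_sin(t,i)| )

over `I` trials and `N` retained samples per trial, with the phase
difference wrapped to (-pi, pi] before the absolute value. |SI| measures
coupling strength and Arg(SI) the preferred phase.

Two variants are implemented, because the absolute value inside the
exponent changes the chance level qualitatively and the intended reading
cannot be resolved from the printed equation alone:

* `variant = "absolute"` — the printed form. Angles are restricted to
  [0, pi], so for independent phases |SI| converges to
  |E exp(j|d|)| = 2/pi ≈ 0.6366, not 0. This is the default for coupling
  *strength* and is what the surrogate null is built for.
* `variant = "signed"` — the conventional phase-locking value,
  `mean exp(j d)`, chance magnitude ~ sqrt(pi/(4 N I)) → 0. Its angle is
  symmetric about zero and is used as the *preferred phase* for the
  circular statistics.

Neither variant is privileged by the package: both are exposed, both are
unit-tested against their analytic chance levels, and the pipeline reports
strength from the absolute variant and phase from the signed variant.

# Surrogate inference

The null hypothesis — no stimulus-brain alignment — is simulated by
recomputing the SI between the intact EEG phases and a shuffled reference,
1000 times. The default shuffle shifts the underlying reference sinusoid in
time by an independent uniform random amount per trial. For a pure sinusoid
a time shift is exactly a constant phase offset, so the marginal phase
distribution is preserved while the alignment is destroyed; a within-trial
sample permutation is available as `scheme = "permute"` (it additionally
destroys the smooth phase progression).

Electrode-level p-values use the complementary-error-function method: the
surrogate distribution is summarized by its mean and standard deviation and
the observed group-mean |SI| is referred to the upper Gaussian tail.
Empirical rank p-values are reported alongside as a diagnostic; the
Gaussian approximation is justified because the group-level statistic
averages over subjects, trials, and (effectively) many independent phase
stretches. p-values are corrected across electrodes by Benjamini-Hochberg
FDR at q = 0.05.

Sensor clusters follow the neighbor rule: a significant electrode is kept
when at least 3 of its montage neighbors are significant too, and connected
components (under the montage adjacency) larger than 3 electrodes form
clusters. No cluster-mass permutation is performed; the cluster-level
p-value reported is the minimum FDR-adjusted p within the cluster. This is
a labelling convention, not an inferential guarantee, and the output says
so.

## Computational note

All filtering is performed in the frequency domain: applying a
Hamming-window FIR forward and backward equals multiplying the spectrum by
the squared magnitude response, which is exactly zero-phase; reflection
padding of one filter length absorbs edge transients. Surrogate |SI| values
for the absolute variant are computed from a 512-bin histogram of the
per-trial phase differences plus a circulant |sin| kernel (the real part
and the signed variant have exact closed forms under time shifting).
Binning error is bounded by the bin width (~0.012 rad) squared and is
unit-tested to be below 2e-3 — far below the Monte-Carlo noise of a
1000-surrogate null.

# The synthetic preterm cohort

`simulate_subject()` produces multichannel recordings as

    data = sum_f a_f(GA) * w_e * cos(2 pi f t + lag_f)   (during trials)
         + 1/f^alpha noise + white noise                  (everywhere)

with `w_e` a frontocentral Gaussian spatial profile (width 0.8 rad around a
point 30 degrees anterior of the vertex; weights under 0.05 are exactly
zero). The montage is a synthetic geodesic layout (Fibonacci lattice on a
spherical cap) standing in for the proprietary 64/124-channel nets, with
adjacency by angular distance and a flagged outer ring.

The default effect structure encodes the developmental hypothesis the
pipeline is designed to detect, so that parameter-recovery tests can target
it directly:

* beat coupling present at all ages, increasing with GA:
  `1.5 + 0.35 (GA - 28)` microvolts;
* duple/triple coupling zero before 33 weeks GA, then
  `0.8 + 1.0 (GA - 33)` microvolts;
* preferred phase ~0 (0.2 rad jitter) for subjects at/after 33 weeks,
  uniform on the circle for younger subjects (phase concentration emerges
  with age);
* noise: 1/f^1 with 20 uV standard deviation plus 5 uV white noise.

These amplitudes were fixed from a signal-to-noise calculation rather than
from the analysis output: with a 0.2 Hz analysis bandwidth, the in-band 1/f
noise amplitude near the target frequencies is 2.5-4.5 uV, so couplings of
1-4 uV put single-subject coupling strengths in the same moderate range the
study's figures display, rather than at ceiling. The profile width matters
for cluster detection: an effect narrower than the inter-electrode spacing
can never satisfy the 3-significant-neighbors rule at 64-channel
resolution, so the profile spans several electrodes, matching the broad
frontocentral clusters in the study.

Gestational ages are stratified (half the cohort below 33 weeks, half at or
above), so a 46-subject cohort reproduces the 23/23 median split. Each
subject's recording is reproducible from a seed derived deterministically
from the cohort seed.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: neonatal sleep-stage alternation, cardiac/ocular
artifacts (the artifact hook defaults to a simple ±500 uV trial rejector;
the study used a dedicated artifact pipeline), volume conduction from a
head model, and non-sinusoidal evoked responses. The recovery tests
demonstrate that the *analysis* is correct and calibrated, not that the
biological effect exists.

# Problem sizes

Generator and pipeline defaults follow the acquisition protocol (1000 Hz
digitization filtered to 0.5-15 Hz and resampled to 512 Hz; 54 trials of
36 s per subject; 1000 surrogates). The package's own test and
demonstration scale — the `"desk"` profile — keeps the identical chain and
effect structure at 256 Hz simulated / 128 Hz analyzed with 6 trials per
subject, which runs a complete 46-subject cohort, surrogates included, in
about three minutes on one core. All acceptance-style checks in the test
suite use the desk profile; the only quantities that depend on the profile
are statistical power (more trials narrow the SI sampling distribution) and
runtimes, not the logic under test.

# Preprocessing chain and numerical choices

* Band-pass 0.5-15 Hz, two-pass Hamming FIR, order = 3 cycles of the low
  cutoff (`3 rate / 0.5` taps).
* Downsampling by trigonometric (FFT) resampling — exact for the
  band-limited signal the band-pass guarantees, and it preserves trial
  onsets that fall on whole-second boundaries exactly.
* 124-channel recordings are spatially downsampled to the 64-channel
  layout by inverse-distance weighting over the 4 nearest electrodes
  (constant-preserving; an exactly coincident electrode is copied).
* Outer-ring exclusion, then average re-reference (a projection;
  idempotent). The order matters and follows the acquisition description:
  ring channels are dropped before the average is formed.
* Epochs are half-open windows [onset, onset + 36 s); 2 s are trimmed from
  each trial edge after phase extraction.
* The narrow-band filter order is 3 rate / bandwidth taps, giving a
  one-sided transition of about one bandwidth. Trials are filtered as a
  continuous recording (they are contiguous), which avoids introducing
  within-trial filter edges; the simulated recording carries 5 s of
  padding before the first and after the last trial so that recording-edge
  transients stay outside the analyzed span.

# Group-level statistics

* GA correlations: |SI| is z-scored across subjects per electrode
  (sample sd), averaged over the region of interest (the detected
  full-cohort cluster per frequency; the frontocentral profile electrodes
  when no cluster exists), and Spearman-correlated with GA (midranks,
  two-tailed t approximation). Normality screening uses a Monte-Carlo
  Lilliefors test (10,000 seeded draws of the KS statistic with estimated
  moments; the null table is cached per sample size).
* The 3x2 mixed ANOVA (frequency within, age group between) runs on raw
  |SI| averaged over the electrodes shared by the three clusters.
  Per-frequency z-scores would force the frequency main effect to zero by
  construction, which is why raw coupling strength is used here while
  z-scores feed the correlations. Effect sizes are partial eta squared.
* Phase analyses use the signed-variant SI angle summed over the
  frontocentral beat-cluster electrodes: Rayleigh tests per age group
  (Zar's small-sample p approximation) and a circular-linear correlation
  of phase with GA (chi-squared p on n Rc^2). The frontocentral
  restriction avoids mixing in far electrodes, which acquire a weak
  anti-phase copy of the coupled component through the average reference.
* Band-power controls: per-trial DFT power averaged over trials and bins.
  Two band presets coexist deliberately — 1-1.7 Hz for the GA correlation
  and 1-3.4 Hz for the group comparison — because the two analyses are
  described with different bands in the study's methods; neither is
  guessed to be "the" band.
* AIC-based Bayes factors: BF_effect/null = exp((AIC_null -
  AIC_effect)/2), with BF <= 0.33 read as support for the null. Both
  orientations are returned and labelled, since reciprocal confusion is
  the main failure mode of this convention.

# Open design points, resolved

* **Rest acoustics**: rests are pure silence; real instruments have reverb
  tails, which would only blur the envelope's harmonic structure, not move
  peak locations.
* **Tone envelopes**: default tones decay exponentially (tau = 130 ms)
  under 10 ms raised-cosine ramps, emulating percussive timbres. A
  perfectly rectangular 300 ms envelope has a spectral null exactly at
  1/0.3 s — a sustained-tone stimulus would carry *no* acoustic energy at
  the beat frequency, so percussive decay is not cosmetic. Any envelope
  with beat-frequency energy also carries weak harmonics above it (3.89,
  4.44 Hz, about a fifth of the beat peak); `metric_peaks()` therefore
  identifies the beat as the dominant peak above 3 Hz rather than the
  fastest local maximum.
* **Peak threshold**: local maxima must exceed 5x the median in-range
  amplitude, 2% of the in-range maximum, and 1% of the envelope DC level;
  the floors exist because for noiseless synthetic audio the median
  amplitude is numerically zero (so a bare median rule would flag
  numerical ripple, even for an unmodulated carrier).
* **Trial counts**: the number of artifact-free trials per subject is not
  fixed by the protocol description; it is a configuration parameter
  (54 by default, 6 in the desk profile).
* **Whether Spearman p-values are one- or two-tailed**: two-tailed.
* **Average reference scope**: computed after outer-ring exclusion.

# Known limitations

* The Gaussian (erfc) p-value is an approximation to the surrogate
  distribution; the empirical-rank p is reported alongside and the
  calibration test bounds the realized false-discovery fraction.
* Cluster-level p-values are a reporting convention (minimum adjusted p),
  not a cluster-mass permutation test.
* The EDF writer/reader covers the continuous, uniform-rate subset of the
  format that this package produces, not arbitrary EDF files.
* With a single 0.2 Hz-wide band per target frequency, targets closer than
  about 0.3 Hz would leak into each other; the stimulus frequencies and
  controls used here are spaced at least 0.28 Hz apart, where the
  two-pass stopband attenuation makes leakage negligible.
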