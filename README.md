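# rhythmtag

Frequency-tagging analysis of neural synchronization to nested rhythmic
periodicities in neonatal EEG — from stimulus construction through
phase-locking measurement, surrogate-based inference, sensor-cluster
detection, and group-level developmental statistics — together with a
synthetic preterm-cohort generator that stands in for non-shareable
clinical recordings.

## The science in brief

A rhythmic sequence of 300 ms events (pattern: tone, rest, tone, tone,
tone, rest; cycle 1.8 s, repeated 20 times per 36 s trial) carries acoustic
energy at a hierarchy of periodicities: the beat (10/3 ≈ 3.33 Hz), duple
meter (5/3 ≈ 1.67 Hz), triple meter (10/9 ≈ 1.11 Hz), plus a subharmonic
(0.56 Hz) and superharmonics (2.22, 2.78 Hz). Neural synchronization to a
target frequency *f* is quantified by the complex synchronization index
between the instantaneous phase of the narrow-band (0.2 Hz) filtered EEG
and the phase of a reference cosine peak-aligned with event onsets:

    SI = 1/(I·N) Σᵢ Σₜ exp( j·|φ_EEG(t,i) − φ_sin(t,i)| )

|SI| is coupling strength (chance level 2/π for this absolute-difference
form; a signed variant with chance level → 0 provides the preferred
phase), and significance comes from 1000 surrogates in which the reference
sinusoid is randomly time-shifted per trial, with erfc (Gaussian-tail)
p-values, Benjamini–Hochberg correction across electrodes, and
FieldTrip-style sensor clusters (≥3 significant neighbors).

Group-level analyses relate coupling to gestational age (GA): Spearman
correlations of z-scored |SI| with GA, a 3×2 mixed ANOVA (frequency ×
age group split at 33 weeks GA), Rayleigh tests and a circular–linear
correlation for the preferred phase, AIC-based Bayes factors, and spectral
band-power controls.

## Worked example

```r
library(rhythmtag)

# the stimulus and its envelope spectrum
g  <- event_grid()                       # TRTTTR on a 300 ms grid
w  <- synthesize_trial(g, rate_hz = 8000)
sp <- envelope_spectrum(w)
round(metric_peaks(sp), 2)
#> subharmonic  triple  duple super1 super2 beat
#>        0.56    1.11   1.67   2.22   2.78 3.33

# a complete synthetic-cohort study replica (desk scale, ~3 min)
res <- run_pipeline(pipeline_config(seed = 1))
print(res)
#> Rhythm synchronization analysis: 46 subjects, 51 electrodes, seed 1 (desk profile)
#> Significant sensor clusters (count):
#>   beat       3.33 Hz  full: 1  younger: 2  older: 1
#>   duple      1.67 Hz  full: 1  younger: 0  older: 1
#>   triple     1.11 Hz  full: 0  younger: 0  older: 1
#>   control1   1.39 Hz  full: 0  younger: 0  older: 0
#>   control2   2.50 Hz  full: 0  younger: 0  older: 0
#>   control3   3.06 Hz  full: 0  younger: 0  older: 0
#> Spearman correlation of z-scored |SI| with gestational age:
#>   beat      rho = 0.96, p = 6.8e-25
#>   duple     rho = 0.80, p = 2.73e-11
#>   triple    rho = 0.76, p = 1.14e-09
#> ...
#> Rayleigh (beat phase): older z = 22.44, p = 6.45e-16; younger p = 0.455

report(res, "results/")                  # CSV/JSON artifact bundle
plot(res, type = "topo")                 # scalp maps with cluster overlays
```

Reading the output: both age groups synchronize to the beat, but only the
older (≥33 weeks GA) group shows significant clusters at the duple and
triple meter frequencies; coupling strength increases with GA at all three
stimulus-related frequencies; nothing is significant at the three control
frequencies absent from the stimulus; and the preferred coupling phase is
concentrated near zero only in the older group. This is the developmental
pattern the synthetic generator encodes and the pipeline is designed to
detect.

## Package layout

- `R/stimulus.R` — event grid, audio synthesis, envelope spectrum
- `R/montage.R`, `R/cohort.R` — synthetic geodesic montages and the
  preterm-cohort generator
- `R/preprocess.R` — zero-phase band-pass, resampling, spatial
  downsampling, re-referencing, epoching, artifact hook
- `R/phase.R` — reference sinusoids, narrow-band phase, the complex SI
- `R/inference.R` — surrogate nulls, erfc p-values, BH-FDR, clusters
- `R/groupstats.R` — correlation/circular/ANOVA/Bayes-factor/band-power
  statistics
- `R/pipeline.R` — `run_pipeline()`, `report()`, plotting
- `R/io.R` — WAV and minimal EDF I/O, result writers
- `inst/scripts/rhythmtag-cli.R` — thin command-line wrapper
  (`stimulus`, `simulate`, `run` subcommands)
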