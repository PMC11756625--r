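Package: rhythmtag
Title: Frequency-Tagged Neural Synchronization to Auditory Rhythms in Neonatal EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for frequency-tagging analyses of neural entrainment to
    nested rhythmic periodicities (beat and duple/triple meter) in neonatal
    EEG. Implements construction of a metrically ambiguous six-event rhythm
    and its envelope spectrum, a synthetic preterm-cohort generator with
    gestational-age-dependent stimulus coupling, a zero-phase FIR
    preprocessing chain, the complex synchronization index between
    narrow-band EEG phase and stimulus-aligned reference sinusoids,
    surrogate-based significance with erfc p-values, Benjamini-Hochberg
    correction and sensor-cluster detection, and group-level statistics
    (Spearman and circular-linear correlations with gestational age, the
    Rayleigh test, a 3x2 mixed ANOVA, AIC-based Bayes factors, and spectral
    band power controls), plus an end-to-end pipeline orchestrator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    nortest,
    optparse
Config/testthat/edition: 3
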