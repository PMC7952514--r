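Package: microstatr
Title: Resting-State EEG Microstate Segmentation and Group Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for resting-state EEG microstate analysis:
    synthetic multichannel EEG generation with known microstate structure,
    the standard preprocessing chain (notch, band-pass, resampling,
    epoching, artifact rejection, average reference), global field power
    peak extraction, polarity-invariant modified k-means clustering with
    two-level (subject/group/global) template derivation, backfitting,
    temporal microstate parameters (duration, occurrence, coverage),
    directed transition probabilities, and the group-statistics layer
    (mixed-design ANOVA with simple effects, one-way ANOVA with Bonferroni
    post hoc tests, chi-square tests, and ANOVA reconstructed from printed
    summary statistics). Includes minimal EDF and BrainVision readers and
    an internal array container for intermediates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
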