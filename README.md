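# microstatr

Resting-state EEG **microstate** analysis in R: a tested implementation of
the full pipeline used in clinical group-comparison studies of
schizophrenia and bipolar disorder — from raw multichannel EEG to
per-subject microstate parameters and the group-level statistics computed
on them — together with a synthetic-data generator with known ground truth
so every stage is verifiable without access to clinical recordings.

## Who this is for

Researchers who want a transparent, scriptable, fully reproducible version
of the standard microstate workflow (EEGLAB/Cartool-style) with explicit
contracts and ground-truth validation, and methodologists studying how
preprocessing and labeling choices propagate into microstate statistics.

## The method

EEG topographies alternate between quasi-stable states (~50–120 ms),
conventionally four classes A–D. The pipeline:

1. **Preprocess** (in order): 48–52 Hz zero-phase FIR notch → 0.1–40 Hz
   band-pass → resample to 250 Hz → 2 s epochs → reject epochs with
   any-channel peak-to-peak > 150 µV → average reference → 2–20 Hz
   band-pass.
2. **Cluster**: global field power `GFP_t = sd over channels of x_t`;
   strict GFP peaks are clustered by the polarity-invariant **modified
   k-means** — assign maps by maximal squared spatial correlation, update
   each template as the principal eigenvector of the cluster's
   GFP²-weighted outer-product sum, keep the best of 100 restarts by
   `GEV = Σ GFP²r² / Σ GFP²` — at subject, group, and global level.
3. **Backfit** the global A–D templates to every sample
   (polarity-invariant argmax) and compute per class: duration (s),
   occurrence (s⁻¹), coverage, and the 12 directed run-level transition
   probabilities (within epochs only; `coverage = occurrence × duration`
   holds exactly).
4. **Group statistics**: mixed-design ANOVA (class within, group between,
   with Greenhouse–Geisser correction), per-class simple effects and
   pooled-variance pairwise t tests with Bonferroni adjustment,
   per-transition one-way ANOVAs with Bonferroni post hocs, Pearson
   chi-square for categorical demographics, and one-way ANOVA
   reconstructed from printed summary statistics
   (`SSB = Σ n_g(m_g − m̄)²`, `SSW = Σ (n_g − 1)sd_g²`).

## Worked example

```r
library(microstatr)

cfg <- study_config(
  groups = c("SCH", "BD", "HC"), subjects_per_group = 5, seed = 42,
  out_dir = "results/study",
  simulation = simulation_config(n_channels = 16, fs = 500, duration = 60,
                                 seed = 1),
  clustering = clustering_config(n_restarts = 30))
res <- run_study(cfg, verbose = TRUE)

res$templates$global
#> <template_set> 4 maps x 16 channels, level=global, GEV=0.968
#>   labels: A B C D

aggregate(cbind(duration_s, occurrence_per_s, coverage) ~ class,
          data = res$parameters, FUN = median)
#>   class duration_s occurrence_per_s  coverage
#> 1     A 0.07103448         3.383333 0.2393333
#> 2     B 0.06370093         3.583333 0.2315333
#> 3     C 0.08572770         3.550000 0.3042000
#> 4     D 0.06772193         3.300000 0.2262667
```

The global template set explains 96.8% of the GFP²-weighted topographic
variance of the pooled peak maps; per-class median durations (64–86 ms)
and occurrences (3.3–3.6 s⁻¹) fall in the ranges reported for resting
adults. Because all
three simulated groups share one generating process here, the mixed-design
ANOVA shows a strong class main effect and no group or interaction effect;
`res$stats` holds the full tables and
`results/study/statistics_report.txt` a readable summary. The same run
writes `parameters.csv`, `transitions.csv`, `global_templates.csv`, and a
provenance log (config hash + seed); rerunning with the same seed
reproduces every table byte for byte.

The numbered scripts under `analysis/` walk the same path stepwise:
`01_simulate.R` (one subject, persisted as EDF/BrainVision/internal
container with ground-truth sidecars), `02_pipeline_study.R` (the study
above), `03_recovery_benchmark.R` (estimates vs. generator truth),
`04_demographics_tables.R` (published demographic table reproduced from
printed summaries).

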