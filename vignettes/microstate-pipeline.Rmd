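---
title: "Resting-state EEG microstate analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resting-state EEG microstate analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Resting-state EEG alternates between brief (roughly 50–120 ms) periods in
which the scalp potential topography stays quasi-stable. These
*microstates* are conventionally reduced to four classes labeled A–D. The
quantities of scientific interest are, per subject and class, the mean
**duration** (s) of contiguous dwell periods, the **occurrence** (s⁻¹,
appearances per second), the **coverage** (fraction of total time), and
the run-level directed **transition probabilities** (12 of them for four
classes, since self-transitions are structurally absent).

The analysis model treats the measured topography at time $t$ as

$$x_t = a_t \, s_t \, T_{L_t} + \varepsilon_t,$$

where $T_k$ is the class-$k$ template map (zero mean across channels, unit
norm), $L_t$ the active class, $a_t \ge 0$ the global field power (GFP)
envelope, $s_t \in \{-1, +1\}$ the field polarity, and $\varepsilon_t$
sensor noise. Because cortical fields reverse polarity within an
oscillatory cycle, all fitting is *polarity-invariant*: a map and its
negation are the same state.

### Estimation pipeline

1. **Preprocessing** mirrors a standard clinical chain, in this exact
   order: 48–52 Hz zero-phase FIR band-stop (line interference), 0.1–40 Hz
   zero-phase band-pass, anti-aliased resampling to 250 Hz, segmentation
   into 2 s epochs, automated rejection of epochs whose any-channel
   peak-to-peak amplitude exceeds 150 µV, average referencing, and a final
   2–20 Hz band-pass applied per epoch.
2. **GFP peaks.** GFP is the spatial standard deviation across channels at
   each sample; strict local maxima (computed within epochs, never at
   epoch edges) mark moments of maximal topographic signal-to-noise. Only
   these peak maps enter clustering.
3. **Modified k-means.** Maps are assigned to the class with the highest
   squared spatial correlation (polarity ignored); each class template is
   updated as the principal eigenvector of the GFP²-weighted outer-product
   sum of its members, which makes the global explained variance
   $\mathrm{GEV} = \sum_t \mathrm{GFP}_t^2 r_t^2 / \sum_t \mathrm{GFP}_t^2$
   non-decreasing across iterations (asserted at run time). One hundred
   random restarts are run and the best GEV kept.
4. **Two-level templates.** Clustering runs per subject first; the pooled
   subject templates are clustered again per group and once across all
   subjects. The global set — labeled A–D by exhaustive permutation
   matching against packaged canonical prototypes — is the set backfitted
   to every sample.
5. **Backfitting and parameters.** Every sample is labeled with the class
   of the highest polarity-invariant correlation (ties to the lowest
   index). Runs are maximal constant-label stretches, never bridged across
   epoch boundaries; edge-truncated runs count, which makes
   $\mathrm{coverage}_k = \mathrm{occurrence}_k \times \mathrm{duration}_k$
   an exact identity. Transition probabilities are run-level conditional
   frequencies counted within epochs; rows with no outgoing transitions
   are reported as missing, never zero-filled.
6. **Group statistics.** A mixed-design (split-plot) ANOVA with class as
   the within-subject factor and diagnostic group as the between-subject
   factor, reported both uncorrected and with Greenhouse–Geisser-corrected
   degrees of freedom; per-class simple effects with pooled-variance
   pairwise t tests under Bonferroni adjustment; per-transition one-way
   ANOVAs with the same post hoc scheme; Pearson chi-square (no continuity
   correction) for categorical demographics; and a one-way ANOVA
   reconstructed from printed means/SDs/sample sizes
   ($SS_B = \sum_g n_g(\bar x_g - \bar x)^2$,
   $SS_W = \sum_g (n_g - 1) s_g^2$) for published summary tables.

## The synthetic-data generator

No clinical recordings accompany this package, so every downstream stage
is validated against a generator with known ground truth. Its defaults
define the study conditions: 64 channels on a unit-disk layout, 5,000 Hz
native sampling, 180 s per subject, four classes, a 50 Hz line component
(5 µV, quasi-common-mode), 12 µV signal RMS, and white sensor noise at a
signal-to-noise ratio of 2. Mean dwell times default to 75/65/90/70 ms
with a mildly non-uniform transition matrix, chosen so the measured
durations fall in the 0.05–0.10 s band and occurrences near 3–4.5 s⁻¹
reported for resting adults.

Two design points deserve explanation because the open literature rarely
spells them out:

**Switching is locked to the field-power oscillation.** The generator
first draws a band-limited 12–18 Hz carrier; the GFP envelope is its
rectified modulus plus a floor, and run boundaries sit on the carrier's
full-cycle grid, so states switch at GFP troughs — which is also where
empirical microstate boundaries concentrate. This choice is not cosmetic.
The 2 Hz high-pass in the analysis chain subtracts a ~0.5 s local average
from each channel; if runs carried nonzero signed area (as they do when
polarity is constant within a run and the envelope has a DC component),
that subtraction injects a mixture of *neighboring* runs' topographies
into every sample and corrupts low-amplitude samples wholesale. Whole-
cycle runs have near-zero signed area, making the high-pass essentially
transparent. Polarity alternates at every envelope trough (the
oscillation) and additionally flips at random per run.

A sequence generator with the plain memoryless law (geometric run lengths
with minimum one sample, gamma optional) is retained and tested on its
own contracts; the study wrapper uses the cycle-locked variant because
sub-cycle runs are unresolvable in principle after band-limiting.

**What the generator does not emulate:** spatially correlated (1/f,
muscle, ocular) noise, electrode drift and pops, inter-subject template
variability, non-stationary dwell statistics, and volume-conduction
structure from real source geometry. Passing recovery tests therefore
demonstrates correctness of the estimators under the stated model, not
robustness to every artifact of clinical data. GEV on synthetic data
(~90–98%) is accordingly higher than the ~75% typical of patient
recordings.

## Label smoothing at the study level

`backfit()` applies no temporal smoothing by default: each sample is
labeled independently, which follows the plainest reading of the
procedure being reproduced. That estimator is, however, provably unstable
exactly at GFP troughs: there the topographic signal passes through zero
while filtered residues and noise do not, so isolated one- or two-sample
label flips appear at oscillation rate. They barely affect coverage or
transitions but roughly double the run count, biasing durations downward
by ~40% and occurrences upward correspondingly — at *any* sensor SNR,
including noiseless data. Every mature microstate toolchain addresses
this with temporal regularization. The study configuration therefore
enables the package's smoothing option with a 7-sample (28 ms at 250 Hz)
within-epoch majority vote: long enough to absorb trough flips, and
shorter than any physiologically reported microstate duration, so it
cannot manufacture spurious states. With it, duration and occurrence
recover to within a few percent of generator truth; without it the
reader can reproduce the fragmentation by setting
`study_config(smooth_window = 1)`.

## Numerical choices

* **Filters.** All filtering is zero-phase. The band-stop is a
  linear-phase FIR (equiripple design attempted first; windowed design
  used where the exchange algorithm cannot converge at the required
  order) applied by delay-compensated FFT convolution with reflected
  edges; attenuation at 50 Hz exceeds 40 dB with passband ripple below
  1 dB. Band-passes are Butterworth sections (order 2 high-pass, order 4
  low-pass) applied forward–backward through C-level recursions, with
  reflection padding sized to ~3 time constants of the lowest corner
  frequency. Resampling uses an FIR anti-alias low-pass (cutoff 0.8 of
  the target Nyquist) followed by integer decimation aligned to sample 1.
* **Clustering.** Peak maps are normalized (zero mean, unit norm) before
  clustering; GEV weights keep the original GFP. Restart seeds are k
  distinct maps; empty clusters are re-seeded from the worst-fit map so k
  stays fixed. Convergence is a relative GEV gain below 1e-6 or 100
  iterations; ties in assignment break to the first class. GEV is clamped
  to [0, 1] against rounding at the noiseless boundary.
* **Degenerate inputs.** Flat (zero-variance) samples inherit the
  previous label (class 1 at an epoch start) and are counted; classes
  never observed get duration `NA`, occurrence and coverage 0; transition
  rows without outgoing transitions are `NA` with the row index recorded.
* **Determinism.** Every stochastic routine takes an explicit seed and
  restores the caller's RNG state; rerunning a study with the same
  configuration reproduces all output tables byte for byte.

## Problem sizes used in validation

Unit and property tests run a reduced geometry (16 channels, 500 Hz,
10–30 s) that exercises every stage including decimation; the recovery
study runs the full native conditions (10 subjects, 64 channels,
5,000 Hz, 180 s). Statistical calibration (type-I error of the
transition and mixed-model tests) uses label-sequence-level replicates —
the statistics consume parameter tables, so synthesizing waveforms for
those replicates would add cost without adding evidence.

## Known limitations

* The canonical A–D prototypes are synthetic conventions on an idealized
  layout; with real montages the labeling step should be given empirical
  prototypes.
* The mixed ANOVA implements the standard univariate split-plot
  decomposition; it does not handle missing cells (it stops with the
  offending subject named) or unbalanced within-subject designs.
* The EDF and BrainVision readers cover the continuous, uniformly sampled
  subset of those formats that this workflow needs; they are not general
  viewers (no annotations, no variable record layouts).
* Durations include epoch-edge-truncated runs, which biases them slightly
  downward relative to an unsegmented recording; the identity
  coverage = occurrence × duration is exact under this convention, and
  truth comparisons apply the same convention to both sides.
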