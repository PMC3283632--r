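---
title: "Methods: cross-platform circadian transcriptome comparison"
author: "crossclock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-platform circadian transcriptome comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossclock)
```

## The problem

Liver transcriptomes profiled at different developmental stages are often
measured on different microarray platforms, in separate hybridization
batches, with different circadian sampling grids. `crossclock` implements a
pipeline for asking two questions of such data:

1. **Which transcripts are enriched in one stage relative to the other?**
   Absolute intensities are not comparable across platforms, so the
   comparison works on *relative* abundance after a global rescaling.
2. **Do transcripts that cycle in both stages peak at the same circadian
   time?** Rhythmicity is detected nonparametrically per series and peak
   phases are compared on the circle.

Everything runs end-to-end on synthetic data with planted ground truth, so
each stage's statistical behaviour is testable without downloading any
repository data.

## Cross-platform enrichment model

For each series the per-probe *daily average* is the arithmetic mean over
all time points, computed on the **linear** intensity scale: log2 input is
exponentiated first. Fold language ("10-fold enriched") is linear-scale
language, which fixes this choice; correlations and scatterplots use the
log2 scale, the conventional display scale for microarray intensities.
(Averaging log2 values instead would estimate the geometric mean and
systematically shrink large fold differences; the linear mean is the
default and the only implemented path.)

The two platforms interrogate overlapping but unequal probe sets, so the
comparison is restricted to the intersection (in first-series order).
Because the common set represents the bulk of the transcriptome, the two
series are assumed to have equal *overall* averages: each side's probe
averages are multiplied by `factor = target / overall`, where `overall` is
the mean of that side's probe-set averages over the common set. The target
is the geometric mean of the two overall averages — an arbitrary choice,
because the target cancels exactly in every ratio
`(a_i / mean(a)) / (b_i / mean(b))`; this cancellation is property-tested,
as is full invariance of ratios, ranks, thresholds and calls under
rescaling either series by any positive constant.

Enrichment calls use a fold threshold with an **inclusive** boundary
(`ratio >= threshold` is `up_in_a`, `ratio <= 1/threshold` is `up_in_b`),
default 10. Rather than being a tuning constant, the threshold can be
derived empirically from a *replicate* comparison of the same tissue:
`deriveEmpiricalThreshold()` takes the largest symmetric fold
`max(r, 1/r)` observed between replicates, optionally after discarding a
stated number of extreme probes (`outlierAllowance`, default 0). With
several stage-A series, a probe is "commonly enriched" only if it passes
the criterion in **every** comparison — the intersection rule, which
controls platform- and batch-specific artifacts at the price of
sensitivity.

The RT-PCR helper `deltaCtToFold()` converts threshold-cycle differences
to folds as `(1 + E)^(-dCt)`; at the ideal efficiency `E = 1` one cycle is
one doubling.

## Rhythmicity scan

Rhythm detection is a rank-based scan against cosine reference waveforms
of fixed 24 h period (a fixed period keeps the best-fit lag interpretable
as a peak time). For sample times `t` (measured from the first sample) and
each lag `L` on the grid `{0, lagStep, ..., 24 - lagStep}`, the template is
`cos(2*pi*(t - L)/24)`; templates whose *sampled* values coincide (coarse
grids alias the cosine) are deduplicated, so a 4-hourly two-day series has
6 distinct templates, an hourly one-day series 24. Sampled template values
are rounded to 9 decimals so mathematically equal values compare equal in
floating point.

The test statistic is Kendall's S between the data and a template:
concordant minus discordant pairs, with tied pairs contributing zero.
Under the null (exchangeable data against a fixed template), sorting
samples by template value partitions them into ordered tie groups; only
cross-group pairs contribute, so `S = 2U - M` with `M` the number of
cross-group pairs and `U` a Jonckheere–Terpstra-type count. `U` is the
independent sum of the Mann–Whitney counts of each group against all
earlier groups, each distributed as a Gaussian-binomial coefficient, so
the exact null pmf is obtained by convolution in `O(M * groups)` time —
no permutation enumeration, and it scales comfortably to 48-sample series.
The test suite proves this distribution identical to full enumeration over
`n!` orderings for all `n <= 7` across random tie patterns.

Per probe, the best template is the one with the smallest one-sided exact
p (ties resolved toward the smaller lag; troughs are covered by lags
shifted 12 h), and the reported p-value applies a group Bonferroni factor
equal to the number of distinct templates. This is conservative by the
union bound, which the null-calibration test confirms empirically (10,000
pure-noise probes; the fraction with reported `p < 0.1` stays below
nominal). Constant probes are defined to have `p = 1` at lag 0.
Benjamini–Hochberg q-values (via `stats::p.adjust`) are attached across
probes.

**Data ties.** The exact null conditions on the template's tie pattern and
assumes untied data. Ties in the data only shrink `|S|` (tied pairs count
zero), so applying the same null is conservative; it also keeps the
degenerate noiseless-cosine case well defined (quantized or aliased data
values are tied, yet the scan still reports the minimal attainable exact p
at the matching lag). The scan therefore defaults to the exact route and
flags tied probes in `data_ties`; `tieMethod = "montecarlo"` instead
estimates their p by random permutations (add-one estimator), for users
who prefer an unconditioned answer on heavily quantized data.

Suggested significance rules follow common practice for the two sampling
designs: raw `p < 0.1` for short 12-point series (where BH across ~20k
probes at 6 lags is very strict) and BH `q < 0.1` for dense 48-point
series; both are configuration options, not constants.

## Phases and circular statistics

A best-fit lag counts hours after the series' first sample, so the peak
phase in circadian time is `(start CT + lag) mod 24` — a series starting
at CT18 with lag 8 peaks at CT2. Degrees are exactly `15 * hours`.
`commonRhythmic()` intersects the probes passing each series' rule and
pairs their phases.

Phase agreement is quantified two ways, because they disagree in an
instructive way:

* **Linear** Pearson correlation of phases treated as numbers in
  `[0, 24)`. Not rotation-invariant: phase pairs straddling the midnight
  boundary are split apart. The test suite pins a deterministic example —
  identical phase sets offset by 12 h have circular correlation exactly 1
  but linear correlation −0.5.
* **Circular–circular** correlation, the Fisher–Lee T-linear association
  coefficient
  `rho = sum_{i<j} sin(a_i - a_j) sin(b_i - b_j) / sqrt(sum sin^2 * sum sin^2)`,
  computed through its O(n) closed form in component sums and verified
  against the O(n²) defining double sum to 1e-12. It is invariant under
  independent rotations of either margin. Commercial circular-statistics
  packages differ in which coefficient they implement
  (Fisher–Lee vs Jammalamadaka–SenGupta); Fisher–Lee was chosen here for
  its rotation-invariance class and simple exact small-sample behaviour,
  without claiming numerical fidelity to any particular program.
  Significance uses the normal approximation to the jackknifed statistic
  (pseudo-value mean over its standard error); degenerate margins (all
  angles equal) are refused with an error naming the offending side.

Signed phase differences are wrapped to `(-12, 12]`, with exact antiphase
mapping to +12 by convention so the result is deterministic.

## The synthetic-data generator

`syntheticConfig()` defaults encode the study design the package targets:
two replicate "fetal-style" series on platform a (12 points, 4 h apart,
starting CT2), one dense "adult-style" reference on platform b (48 hourly
points, starting CT18), 2000 probes per platform sharing 1500. Planted
structure, all on common probes: 50 + 50 probes enriched at 4.5 log2-fold
(≈ 23-fold), 100 cosine rhythms of amplitude 2 log2 units with uniform
phases, a +1 log2 global offset on the platform-b series (so the scaling
step is exercised non-trivially), and i.i.d. Gaussian noise of SD 0.25
log2 units — a realistic replicate scatter for summarized microarray
intensities; noise is multiplicative on the linear scale, matching
microarray error convention. Platform-private probes get independent
baselines so the intersection step does real work. All randomness flows
from one integer seed; identical seeds give bit-identical series.

What the generator does **not** emulate: probe-level (pre-summarization)
intensities, GC-content or intensity-dependent biases, heteroskedastic
noise, correlated probes, or asymmetric waveforms. Passing tests therefore
demonstrate the pipeline's statistical correctness under its stated model,
not robustness to every artifact of real arrays.

## Numerical and design notes

* TSV output prints 15 significant digits; write→read round trips
  reproduce values to full double precision, and repeated writes are
  byte-identical.
* Ratio ranks break ties by probe id, making rank plots deterministic.
* `splitDays()` returns the samples in the first and last 24 h windows;
  windows may overlap for series between 24 h and 48 h long, and a series
  whose duration does not exceed one window (the two windows would be
  identical) is an error.
* The pipeline derives one RNG substream per stage from the config seed,
  so stages can be rerun independently; logs (with stage timings) go to
  standard error, results only to files.
* Problem sizes in the shipped tests and acceptance script — 10,000 null
  probes, 200 planted rhythms, 20 simulation seeds for enrichment
  recovery, exhaustive permutation checks to `n = 7` — were chosen as the
  smallest sizes at which the binomial/Monte-Carlo error bars are tight
  enough to be meaningful.

## Working with real repository data

The real accessions this design mirrors are downloadable as GEO Series
Matrix files and read with `readGEOSeriesMatrix(path, startCt, resolution)`
(the deposits label samples by order, not circadian time, so the start CT
must be supplied — e.g. CT2 for the fetal series, CT18 for the adult
reference). From there the pipeline is identical: intersect (~22.6k common
probe sets for the 430A vs 430 2.0 chip pair), average, scale, call at
10-fold, scan each series at its own resolution, and correlate phases with
fetal-style `p < 0.1` against adult-style `q < 0.1`. Expect a positive
log-scale correlation with heavy-tailed rank plots; exact published values
depend on the deposit's normalization vintage and are not desk-scale
reproducible, so they are not asserted anywhere in this package.

## Limitations

* Only the symmetric cosine reference family is implemented; asymmetric
  waveform variants and period scanning (e.g. 20–28 h) are out of scope.
* Amplitude is not estimated beyond the rank statistic itself.
* The enrichment threshold model assumes a replicate pair is available to
  calibrate technical scatter; without one, 10-fold is a conservative
  default, not a statement about your platform.
* The Monte-Carlo tie fallback is quadratic per permutation and intended
  for short series.
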