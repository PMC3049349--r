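---
title: "Global randomization statistics for ERP scalp field data"
author: "topotest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Global randomization statistics for ERP scalp field data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topotest)
```

## The problem

Multichannel event-related EEG/MEG experiments ask whether experimental
conditions or groups differ in their active brain sources. Because the
forward projection from sources to sensors is linear and additive, a
*difference* of scalp fields is itself the scalp field of the sources
that differed — so the question can be answered on the scalp, without an
inverse model, by testing whether the overall strength of mean scalp
field differences exceeds what label shuffling alone produces. This
package implements that program: global, assumption-free randomization
statistics on the full sensor array, with familywise control across
time and companion tools (topographic consistency test, MDS displays, a
ground-truth synthetic generator).

## The model and its statistics

A *scalp field map* is the vector $v_1, \dots, v_n$ of measurements
across all $n$ sensors at one time point, expressed against the average
reference ($\sum_j v_j = 0$). Map strength is the Global Field Power,
the spatial RMS about the mean:

$$\mathrm{GFP}(v) = \sqrt{\tfrac{1}{n}\sum_{j=1}^{n} (v_j - \bar v)^2}.$$

GFP is independent of the recording reference and of sensor choice,
which is what makes the statistics below unbiased by montage decisions.

**TANOVA.** For an effect with marginal cell mean maps $\bar v_{ij}$
(cell $i = 1..c$, sensor $j$) and the unweighted grand mean
$\bar{\bar v}_j$ across cells, the global effect strength is

$$s = \sqrt{\tfrac{1}{n}\sum_{i=1}^{c}\sum_{j=1}^{n}
      (\bar v_{ij} - \bar{\bar v}_j)^2},$$

the generalized GFP of the differences among cell means. The null
distribution of $s$ is estimated by repeatedly shuffling the condition
and/or group labels (schemes below) and recomputing $s$; the p-value is
the fraction of shuffled values greater than or equal to the observed
one, with the observed value counted as one realization of the null:
$p = (1 + \#\{s^{*} \ge s\}) / (1 + n_{\mathrm{runs}})$. A
randomization p can therefore never be exactly zero, and the number of
distinguishable p levels is bounded by the number of runs (1000 runs
are recommended at $\alpha = .05$, 5000 at $\alpha = .01$).

**TANCOVA.** When a continuous, interval- or rank-scaled per-subject
predictor $b_i$ replaces group membership, the topography of the
linearly related sources is estimated by the covariance map
$\beta_j = \sum_i v_{ij}(b_i - \bar b)$, and the statistic is
$s = \mathrm{GFP}(\beta)$. The null permutes the values $b_i$ across
subjects. For interaction terms the covariance map is computed per
within-subject cell and the maps are centered across cells before the
strength is taken, mirroring the TANOVA interaction statistic.

**Normalization.** With `normalization = "l2"` (the default and the
recommended setting) every individual map is scaled to unit GFP before
averaging, so significant results reflect *topographic* (qualitative)
differences rather than global amplitude scaling. `"none"` tests raw
fields; `"dissimilarity"` is a legacy variant that normalizes the
condition/group grand-mean maps instead of the individual maps, and is
defined for TANOVA only.

## Designs and permutation schemes

Designs cover up to two within-subject factors (whose included
conditions must form a complete, balanced crossing) and one
between-subject factor, either categorical groups or a continuous
covariate; conditions and subjects can be excluded. `enumerateEffects()`
lists the testable effects in a fixed order — e.g. A, B, A×B, G, G×A,
G×B, G×A×B for two within factors and groups.

The shuffling scheme of each effect must be exchangeable under that
effect's null while preserving all non-tested structure. The schemes
used here are:

| effect | scheme |
|---|---|
| within main A | per subject, a random permutation of A-level labels, applied consistently across B levels |
| within A×B | per subject, a random permutation of all included condition labels |
| between G | one global permutation of group labels across used subjects |
| mixed G×A, G×A×B | the within scheme and a group permutation, simultaneously |
| covariate terms | permutation of the covariate values across subjects |

Interaction statistics are computed on *fully centered* cell means:
all lower-order marginal means are removed (double centering for
two-way, triple for three-way terms) before $s$ is taken. This choice
makes $s$ exactly zero on purely additive data — the defining property
of an interaction test — and is verified on generated additive
fixtures. Cell means and grand means are unweighted across cells, so
unbalanced groups do not bias the statistic toward the larger group.

One shuffle is drawn per randomization run and reused across all time
points of that run. The null thereby preserves the temporal
autocorrelation of the data, which is what makes the count and
duration statistics below valid; drawing fresh shuffles per time point
would destroy exactly the dependence those statistics measure.

## Inference across time

Time-point-wise testing at many latencies inflates false positives.
Both global corrections are derived from the *same* randomization runs
as the pointwise test:

* **Pseudo-P matrix.** Each run $r$ is ranked against all other runs at
  every time point: $p'(r,t) = (1 + \#\{r' \ne r: s_{r't} \ge
  s_{rt}\}) / n_\mathrm{runs}$. Each run thus becomes one full
  time-resolved analysis under the null.
* **Count test.** The observed number of sub-$\alpha$ time points is
  compared against the null counts $\#\{t: p'(r,t) < \alpha\}$,
  yielding one global p per effect. The count is integer-valued, so
  this p is discrete; its calibration is checked in the test suite on
  the randomized probability-integral transform (the standard
  uniformity check for discrete p-values) together with a direct bound
  on the tail $P(p \le \alpha)$.
* **Duration threshold.** Each run is summarized by its *maximal*
  contiguous sub-$\alpha$ stretch; the threshold is the shortest
  duration reached by at most an $\alpha$ fraction of the runs,
  reported as an achievable null run length (the smallest
  null-observed duration $d$ with $\#\{\text{maxrun} \ge d\} \le
  \alpha\, n_\mathrm{runs}$). Using the per-run maximum gives
  familywise control in the spirit of cluster-size statistics; an
  alternative reading that pools *all* null epochs rather than the
  per-run maximum would be anticonservative and is not used. Observed
  sub-$\alpha$ intervals at least as long as the threshold are
  reported as significant clusters; intervals are open at exactly
  $\alpha$ (a sample with $p = \alpha$ is not significant).

Windows are specified in milliseconds and converted through the
sampling rate as half-open sample intervals $[start, end)$.
`averagedWindowTanova()` averages each subject's and condition's maps
across an a-priori window and applies the identical pipeline to the
averaged maps; a window covering exactly one sample reproduces the
pointwise result under the same seed.

## Topographic consistency test

The TCT asks, per condition (and group) and time point, whether
subjects share a common topography at all. The statistic is the GFP of
the across-subject mean map — consistent fields add, inconsistent ones
cancel. The null shuffles each subject's sensor values within the map
(one permutation per subject per run, reused across time), which
destroys any common spatial arrangement while keeping each subject's
value distribution. The GFP trace of the raw mean map is reported
alongside, and consistent periods are marked with the same duration
machinery as the TANOVA. On signal-bearing data the test's p is
inversely related to the mean-map GFP, which the test suite verifies on
a pulsed-source fixture. The implementation follows the summary
formulation (shuffle-within-subject-across-sensors on the mean-map
GFP); reproducing any more elaborate variance decomposition of the
original consistency-test literature is out of scope and stated as
such.

## MDS display

For more than two cell means, mean maps are visualized by spatial PCA:
maps are centered across the map set (a requirement for a principal
axes decomposition; uncentered maps would make the first axis encode
the grand mean rather than the differences), the eigenstructure of the
between-map covariance is taken, and each map is projected onto the
first two spatial eigenvectors. Distances in the plane approximate the
dissimilarities of the maps; the eigenvector maps themselves show which
topographic contrast each axis encodes. Eigenvector signs are fixed by
making the largest-|loading| sensor positive, so figures are
reproducible; a rank-1 map set gets a zero second axis rather than an
error.

## The synthetic generator

`simulateErp()` emulates what makes scalp data scalp data: fields are
*additive* superpositions of sources, each source a fixed unit-GFP
topography times an amplitude time course, with gains that may depend
on design cell, group and covariate, a multiplicative per-subject gain
(SD 0.2 by default), and sensor noise that is spatially correlated
through a squared-exponential kernel over montage distance (the
forward projection blurs fields in space, so white sensor noise would
make tests unrealistically easy). The default scale — 12 subjects, a
2×2 within design, 40 time points, 16 sensors, noise SD 1 — is the toy
scale all calibration suites run at.

What the generator does *not* emulate: temporal autocorrelation of
ongoing EEG (noise is white in time), eye/muscle artifacts, realistic
head-model leadfields, or sensor-specific noise levels. Passing
calibration on these fixtures therefore demonstrates the correctness
of the statistical machinery under exchangeability, not robustness to
every property of recorded data; on real recordings the usual
preprocessing responsibilities remain with the user.

Fixture choices used by the test suite, chosen once as study
conditions:

* The null fixture adds a background source common to all cells, so
  exchangeability is tested in the presence of shared signal, not just
  pure noise.
* The power fixture injects a condition-difference source active
  around samples 15–25 with a spatially distributed (tangential-dipole)
  topography, white sensor noise, and amplitude 0.25 noise SD. The
  amplitude was fixed so that the comparison arm — sensor-wise paired
  t-tests with Bonferroni correction over all 640 (time, sensor)
  cells — sits clearly below 50% detection; in that regime the
  duration-masked TANOVA detects the effect in well over 90% of
  datasets, which is precisely the regime the global statistics are
  for. A spatially distributed source and whole-array pooling is where
  the advantage comes from; a single-sensor spike would favor the
  mass-univariate test instead.
* The TANCOVA recovery fixture links a source's amplitude linearly to
  a standardized covariate (slope 3), where the covariance map's
  spatial correlation with the true topography exceeds 0.9.

## Numerical and design choices

* **Restored formulas.** GFP and the effect strength are implemented
  as root-mean-squares (the square and outer root are occasionally
  lost typographically in print); the covariance-map strength uses the
  spatial *mean* of $\beta$ so that it is exactly $\mathrm{GFP}(\beta)$.
* **Tie rule.** "$\ge$" throughout (pointwise p, pseudo-P, count
  test): the conservative reading, consistent across all three.
* **Add-one correction.** Observed data count as one realization of
  the null; p-values live in $(0, 1]$.
* **Predictor centering.** $b_i$ is mean-centered, so $\beta$ is a
  covariance (not raw cross-product) map and TANCOVA is invariant to
  covariate offsets.
* **Seeds.** One user seed; per-effect substreams are derived
  deterministically from the effect id, so a single effect rerun in
  isolation reproduces its p-values bit for bit.
* **Degenerate inputs.** Flat maps fail L2 normalization with an
  error naming subject, condition and sample; single-sensor data
  cannot be average-referenced; empty design cells, groups with fewer
  than 2 used subjects, and covariates with fewer than 3 distinct
  values are rejected before any computation.
* **Problem sizes.** The suites run at the toy scale: 200 null
  datasets at 500 runs for calibration and familywise checks, 100
  datasets for the power comparison, 10 000 runs against the
  exhaustive 2⁵-relabeling oracle. The acceptance script uses 150 null
  datasets and otherwise the same sizes.

## Known limitations

* Microstate statistics, univariate GFP statistics, frequency-domain
  analyses and source modelling are out of scope.
* At most two within factors and one between factor; no missing cells.
* The permutation schemes for mixed (group × within) interactions are
  a documented, property-tested reconstruction: they are exchangeable
  under the respective null and preserve non-tested effects, but other
  implementations of this methodology may shuffle differently in ways
  their published descriptions do not pin down.
* Session containers are versioned and self-describing but
  deliberately not bit-compatible with any external tool's format.

## A minimal session

```{r example, eval = FALSE}
spec <- erpSimSpec(seed = 14, sources = list(
  simSource(),
  simSource(center = 20, width = 2.1, amplitude = 0.4,
            cellGain = matrix(c(1, 1, -1, -1), 2, 2, byrow = TRUE))))
sim <- simulateErp(spec)
wd <- simWithinDesign(spec)
res <- runTanova(sim$dataset, wd,
                 options = randomizationOptions(nRuns = 1000,
                                                seed = 99))
res
gi <- globalInference(res)
globalTable(gi)
plotEffect(sim$dataset, res, "A", wd, global = gi)
```
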