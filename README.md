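# topotest

Global randomization statistics for multichannel event-related EEG/MEG
scalp field data.

## What it is for

ERP researchers comparing conditions and/or groups face two
entangled multiple-testing problems — many sensors, many time points —
and every conventional shortcut (picking electrodes of interest,
fitting an inverse model, averaging a-priori windows) injects model
assumptions that bias the statistics. `topotest` takes the opposite
route: at each time point it reduces the whole sensor array to one
physiologically meaningful number, the global strength of the
differences among condition/group mean maps, and tests it with
assumption-free randomization statistics. Because scalp fields are
additive, a significant difference of scalp fields is direct evidence
for a difference in active sources — no source localization required.

The package provides:

* **TANOVA** (topographic ANOVA): for up to two within-subject factors
  and one between-subject factor, the statistic per effect and time
  point is

  `s = sqrt( sum_i sum_j ( v̄_ij − v̿_j )² / n )`

  the generalized Global Field Power (GFP = spatial RMS about the
  spatial mean) of the deviations of the cell mean maps `v̄_ij` from
  their grand mean. The null is built by shuffling condition labels
  within subjects and/or group labels across subjects;
  `p = (1 + #{s* ≥ s}) / (1 + nRuns)`.
* **TANCOVA**: a continuous per-subject predictor `b` replaces groups;
  the statistic is the GFP of the covariance map
  `β_j = Σ_i v_ij (b_i − b̄)`, the estimated topography of the
  predictor-related sources.
* **Global inference over time**: count-of-significant-time-points
  test and duration thresholds derived from the same randomization
  runs (per-run pseudo-P values), controlling familywise error across
  the epoch.
* **Topographic consistency test (TCT)**: does any common topography
  exist across subjects at a given latency?
* **MDS displays**: condition mean maps projected onto their first two
  spatial eigenvectors.
* **L2 normalization** to separate topographic (qualitative) from
  amplitude (quantitative) effects.
* A **synthetic ERP generator** with known ground truth, the Ragu-style
  **plain-ASCII importer** (time × sensor matrices, subject/condition
  filename tags), a versioned **session container**, tab-delimited
  exports, and a small **CLI** (`inst/scripts/topotest-cli.R`).

## Worked example

Simulate a 12-subject 2×2 experiment (factors A and B) with a
condition-difference source active around samples 15–25 (60–100 ms at
250 Hz), then test all effects:

```r
library(topotest)

spec <- erpSimSpec(seed = 14, sources = list(
  simSource(),                                  # background activity
  simSource(center = 20, width = 2.1, amplitude = 0.4,
            cellGain = matrix(c(1, 1, -1, -1), 2, 2, byrow = TRUE))))
sim <- simulateErp(spec)
wd  <- simWithinDesign(spec)
res <- runTanova(sim$dataset, wd,
                 options = randomizationOptions(nRuns = 1000, seed = 99))
res
#> TANOVA (time-point-wise)
#>   3 effects x 40 time points; 1000 runs; normalization: l2
#>   A          min p = 0.001998 (8 of 40 samples < 0.05)
#>   B          min p = 0.02198 (1 of 40 samples < 0.05)
#>   AxB        min p = 0.03197 (2 of 40 samples < 0.05)
```

The injected main effect of A is strongly significant over 8 samples;
the two null effects graze the 5% line at isolated samples, which is
exactly what pointwise testing at 40 latencies produces by chance. The
global statistics separate the two situations:

```r
gi <- globalInference(res)
globalTable(gi)
#>   effect      countP thresholdSamples thresholdMs nClusters
#> 1      A 0.004995005                3          12         1
#> 2      B 0.889110889                3          12         0
#> 3    AxB 0.586413586                3          12         0
significantClusters(gi, "A")
#>   start end length startMs endMs
#> 1    17  23      7      64    88
```

Only effect A survives: its count of significant samples has a global
p of .005, and its 7-sample run (64–88 ms) exceeds the 3-sample
(12 ms) duration threshold estimated from the randomization null. The
isolated blips of B and A×B do not. `plotEffect(sim$dataset, res, "A",
wd, global = gi)` draws the p-trace with the cluster highlighted, the
cell mean maps at the most significant latency, and their MDS
projection; `topographicConsistencyTest()` and `plotTct()` mark the
latencies at which subjects share a topography at all.

Data import for real recordings follows the one-file-per-subject-and-
condition ASCII convention:

```r
ds <- importDataset("mydata/", searchMask = "S*_C1.asc",
                    conditionTags = c("C1", "C2", "F1", "F2"),
                    samplingRate = 250)
```

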