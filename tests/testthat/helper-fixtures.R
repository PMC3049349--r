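# Shared fixtures: all data are generated in code at test time.

# the standard 2 x 2 within design used by the toy-scale datasets
wd22 <- function() withinDesign(list(A = c(1, 1, 2, 2),
                                     B = c(1, 2, 1, 2)))

# pure-noise null fixture at the toy scale (12 subjects, 2 x 2, 40
# time points, 16 sensors): one background source common to all cells
# plus spatially correlated sensor noise -> H0 holds for every effect
h0Spec <- function(seed, ...) erpSimSpec(seed = seed, ...)

h0Dataset <- function(seed, ...) simulateErp(h0Spec(seed, ...))$dataset

# unit-GFP tangential-dipole topography on the circular montage:
# spatially distributed (low peak-to-RMS), the regime where global
# statistics outperform sensor-wise tests
dipoleTopo <- function(nch) {
  v <- cos(2 * pi * (seq_len(nch) - 1L) / nch)
  v <- v - mean(v)
  v / sqrt(mean(v^2))
}

# power fixture: condition-difference source (main effect of A) active
# around samples 15-25, white sensor noise (SD 1), amplitude in noise
# SD units
powerSpec <- function(seed, amplitude = 0.25) {
  erpSimSpec(seed = seed, noiseCorrLength = 0, sources = list(
    simSource(),
    simSource(topography = dipoleTopo(16), center = 20, width = 2.1,
              amplitude = amplitude,
              cellGain = matrix(c(1, 1, -1, -1), 2, 2,
                                byrow = TRUE))))
}

# covariate-linked source for TANCOVA recovery
covSpec <- function(seed, slope = 3) {
  erpSimSpec(seed = seed, covariate = TRUE, sources = list(
    simSource(),
    simSource(center = 20, width = 2.1, amplitude = 0,
              covariateSlope = slope)))
}

# additive-only dataset: pure main effects of A and B, no interaction,
# no noise
additiveDataset <- function(seed = 1, ns = 6, nt = 8, nch = 10) {
  set.seed(seed)
  mkMap <- function() { v <- rnorm(nch); v - mean(v) }
  mapA <- mkMap(); mapB <- mkMap(); base <- mkMap()
  x <- array(0, c(ns, 4L, nt, nch))
  aLev <- c(1, 1, 2, 2); bLev <- c(1, 2, 1, 2)
  for (s in seq_len(ns))
    for (k in 1:4)
      for (t in seq_len(nt))
        x[s, k, t, ] <- base + (aLev[k] - 1.5) * mapA +
          (bLev[k] - 1.5) * mapB + rnorm(1) * 0  # deterministic
  erpDataset(x, samplingRate = 250, reference = "average")
}

quietTanova <- function(...) suppressWarnings(runTanova(...))
quietTancova <- function(...) suppressWarnings(runTancova(...))
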