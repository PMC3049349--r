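test_that("the pointwise p rule counts the observed value as one realization", {
  expect_equal(pointwiseP(10, rep(1, 999)), 1 / 1000)
  expect_equal(pointwiseP(5, rep(5, 99)), 1)          # >= rule
  # observed at the median of a 9-value null: 5 of 9 are >=
  expect_equal(pointwiseP(5, 1:9), 6 / 10)
  expect_error(pointwiseP(1, numeric(0)), "empty")
})

test_that("same seed gives bit-identical results; seeds differ otherwise", {
  ds <- h0Dataset(31)
  wd <- wd22()
  o <- randomizationOptions(nRuns = 60, seed = 5)
  r1 <- quietTanova(ds, wd, options = o)
  r2 <- quietTanova(ds, wd, options = o)
  expect_identical(r1@p, r2@p)
  expect_identical(r1@null, r2@null)
  r3 <- quietTanova(ds, wd,
                    options = randomizationOptions(nRuns = 60,
                                                   seed = 6))
  expect_false(identical(r1@p, r3@p))
  # per-effect substreams: restricting to one effect reproduces it
  r4 <- quietTanova(ds, wd, options = o, effects = "B")
  expect_identical(pValues(r4, "B"), pValues(r1, "B"))
})

test_that("engine strengths equal the direct cell-mean statistic for all schemes", {
  sim <- simulateErp(erpSimSpec(nSubjects = 8, nGroups = 2,
                                nTime = 5, nSensors = 10, seed = 17))
  ds <- sim$dataset
  wd <- wd22()
  bd <- betweenDesign(sim$truth$groups, "categorical")
  res <- quietTanova(ds, wd, bd,
                     randomizationOptions(nRuns = 5, seed = 1,
                                          normalization = "none"))
  for (eff in effectIds(res)) {
    sdir <- vapply(1:5, function(t)
      effectStrength(cellMeans(ds, wd, bd, eff, t)), numeric(1))
    expect_equal(observedStrength(res, eff), sdir, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("L2 analysis ignores per-map rescaling; raw s is equivariant", {
  sim <- simulateErp(erpSimSpec(nSubjects = 6, nTime = 5,
                                nSensors = 8, seed = 23))
  ds <- sim$dataset
  wd <- wd22()
  x <- erpData(ds)
  set.seed(99)
  fac <- array(runif(prod(dim(x)[1:3]), 0.5, 2), dim(x)[1:3])
  xs <- x * as.vector(fac)            # per-map positive rescaling
  ds2 <- erpDataset(xs, samplingRate = samplingRate(ds))
  o <- randomizationOptions(nRuns = 80, seed = 3)
  expect_equal(quietTanova(ds, wd, options = o)@p,
               quietTanova(ds2, wd, options = o)@p)
  # unnormalized: scaling the data scales s linearly
  oN <- randomizationOptions(nRuns = 5, seed = 3,
                             normalization = "none")
  s1 <- quietTanova(ds, wd, options = oN)@observed
  s2 <- quietTanova(erpDataset(3 * x), wd, options = oN)@observed
  expect_equal(s2, 3 * s1)
})

test_that("dissimilarity normalization runs and differs from L2", {
  ds <- h0Dataset(37)
  wd <- wd22()
  rD <- quietTanova(ds, wd, options = randomizationOptions(
    nRuns = 40, seed = 2, normalization = "dissimilarity"))
  rL <- quietTanova(ds, wd, options = randomizationOptions(
    nRuns = 40, seed = 2, normalization = "l2"))
  expect_true(all(rD@p > 0 & rD@p <= 1))
  expect_false(identical(rD@observed, rL@observed))
})

test_that("a single-sample window reproduces the pointwise result", {
  ds <- h0Dataset(41)
  wd <- wd22()
  o <- randomizationOptions(nRuns = 100, seed = 9)
  full <- quietTanova(ds, wd, options = o)
  tms <- timePoints(ds)
  k <- 18L
  dt <- 1000 / samplingRate(ds)
  win <- quietTanova(ds, wd, options = o) # guard against state leaks
  avg <- suppressWarnings(averagedWindowTanova(
    ds, wd, options = o, window = c(tms[k], tms[k] + dt / 2)))
  expect_equal(avg@p[, 1], full@p[, k])
  expect_equal(avg@observed[, 1], full@observed[, k])
})

test_that("window averaging cancels a polarity-reversing effect", {
  # difference topography flips sign mid-window: pointwise detects,
  # the window average does not
  topo <- dipoleTopo(16)
  tc <- c(rep(0, 10), rep(1, 10), rep(-1, 10), rep(0, 10))
  spec <- erpSimSpec(seed = 51, noiseSd = 0.3, sources = list(
    simSource(),
    simSource(topography = topo, timecourse = tc, amplitude = 0.8,
              cellGain = matrix(c(1, 1, -1, -1), 2, 2,
                                byrow = TRUE))))
  ds <- simulateErp(spec)$dataset
  wd <- wd22()
  o <- randomizationOptions(nRuns = 200, seed = 4)
  tms <- timePoints(ds)
  pw <- quietTanova(ds, wd, options = o, effects = "A")
  expect_lt(min(pValues(pw, "A")[11:30]), 0.01)
  avg <- suppressWarnings(averagedWindowTanova(
    ds, wd, options = o, window = c(tms[11], tms[30] + 1),
    effects = "A"))
  expect_gt(pValues(avg, "A"), 0.2)
  expect_error(averagedWindowTanova(ds, wd, options = o,
                                    window = c(-500, -400)),
               "empty window")
})

test_that("TANCOVA rejects degenerate covariates and detects a linked source", {
  sim <- simulateErp(covSpec(61))
  ds <- sim$dataset
  wd <- wd22()
  constant <- betweenDesign(c(rep(1, 11), 2), "continuous")
  expect_error(quietTancova(ds, wd, constant,
                            randomizationOptions(nRuns = 10, seed = 1)),
               "3 distinct")
  expect_error(quietTanova(ds, wd,
                           betweenDesign(rnorm(12), "continuous"),
                           randomizationOptions(nRuns = 10, seed = 1)),
               "runTancova")
  bd <- betweenDesign(sim$truth$covariate, "continuous")
  res <- quietTancova(ds, wd, bd,
                      randomizationOptions(nRuns = 300, seed = 8))
  # source is active around samples 15-25 and linked to the covariate
  expect_lt(min(pValues(res, "Cov")[15:25]), 0.01)
})

test_that("run-count recommendation is surfaced as a warning", {
  ds <- h0Dataset(71, nSubjects = 4, nTime = 3, nSensors = 6)
  expect_warning(runTanova(ds, wd22(),
                           options = randomizationOptions(nRuns = 50,
                                                          seed = 1)),
                 "1000")
})

test_that("Monte-Carlo p agrees with the exhaustive sign-flip oracle", {
  set.seed(77)
  ns <- 5; nch <- 8
  x <- array(rnorm(ns * 2 * 1 * nch), c(ns, 2, 1, nch))
  ds <- applyAverageReference(erpDataset(x, samplingRate = 250))
  wd1 <- withinDesign(list(A = c(1, 2)))
  # oracle: plain-R statistic over all 2^5 swap patterns
  sstat <- function(xx) {
    m1 <- colMeans(xx[, 1, 1, ]); m2 <- colMeans(xx[, 2, 1, ])
    g <- (m1 + m2) / 2
    sqrt((sum((m1 - g)^2) + sum((m2 - g)^2)) / nch)
  }
  obs <- sstat(erpData(ds))
  vals <- vapply(0:31, function(bits) {
    xx <- erpData(ds)
    for (s in 1:ns)
      if (bitwAnd(bits, bitwShiftL(1L, s - 1L)) > 0)
        xx[s, , 1, ] <- xx[s, 2:1, 1, ]
    sstat(xx)
  }, numeric(1))
  pExact <- mean(vals >= obs - 1e-12)
  nRuns <- 4000
  res <- quietTanova(ds, wd1, options = randomizationOptions(
    nRuns = nRuns, seed = 19, normalization = "none"))
  se <- sqrt(pExact * (1 - pExact) / nRuns)
  expect_lt(abs(pValues(res, "A") - pExact), 3 * se + 2 / nRuns)
})
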