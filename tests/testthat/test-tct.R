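test_that("flat data give statistic 0 and p = 1", {
  x <- array(0, c(3, 1, 4, 6))
  ds <- erpDataset(x, reference = "average")
  tct <- topographicConsistencyTest(
    ds, randomizationOptions(nRuns = 30, seed = 1,
                             normalization = "none"))
  expect_true(all(tctGfp(tct) == 0))
  expect_true(all(tctPValues(tct) == 1))
})

test_that("a shared topography is detected at the p floor", {
  # all subjects: one topography scaled by positive weights, no noise
  spec <- erpSimSpec(nSubjects = 8, factorLevels = 1, nTime = 12,
                     nSensors = 12, noiseSd = 0, subjectSd = 0.3,
                     seed = 3,
                     sources = list(simSource(center = 6, width = 8)))
  ds <- simulateErp(spec)$dataset
  tct <- topographicConsistencyTest(
    ds, randomizationOptions(nRuns = 199, seed = 5))
  expect_true(all(tctPValues(tct) <= 0.05))
  solo <- erpDataset(erpData(ds)[1, , , , drop = FALSE])
  expect_error(topographicConsistencyTest(solo), ">= 2 subjects")
})

test_that("the TCT statistic is invariant to common permutations and offsets", {
  ds <- h0Dataset(91, nSubjects = 6, nTime = 8, nSensors = 10,
                  noiseCorrLength = 0)
  o <- randomizationOptions(nRuns = 60, seed = 7,
                            normalization = "none")
  t1 <- topographicConsistencyTest(ds, o)
  # one common sensor permutation applied to ALL subjects
  perm <- c(3, 1, 2, 10, 4, 6, 5, 9, 8, 7)
  ds2 <- erpDataset(erpData(ds)[, , , perm],
                    samplingRate = samplingRate(ds),
                    conditionLabels = conditionLabels(ds))
  t2 <- topographicConsistencyTest(ds2, o)
  # the statistic (GFP of the mean map) is permutation-invariant; the
  # null realizations compose with the permutation, so p agrees in
  # distribution but not sample-by-sample
  expect_equal(t2@gfpMean, t1@gfpMean)
  expect_lt(max(abs(t2@p - t1@p)), 0.25)
  # re-referencing: adding a per-map constant changes nothing
  x <- erpData(ds)
  off <- array(rnorm(prod(dim(x)[1:3])), dim(x)[1:3])
  ds3 <- erpDataset(x + as.vector(off),
                    samplingRate = samplingRate(ds),
                    conditionLabels = conditionLabels(ds))
  t3 <- topographicConsistencyTest(ds3, o)
  expect_equal(t3@p, t1@p, tolerance = 1e-12)
})

test_that("consistency p is inversely related to the GFP of the ERP", {
  # source amplitude waxes and wanes -> where the mean-map GFP is
  # high, the consistency p must be low
  spec <- erpSimSpec(nSubjects = 12, factorLevels = 1, nTime = 40,
                     nSensors = 16, noiseSd = 1, seed = 11,
                     sources = list(simSource(center = 20, width = 5,
                                              amplitude = 1.2)))
  ds <- simulateErp(spec)$dataset
  tct <- topographicConsistencyTest(
    ds, randomizationOptions(nRuns = 300, seed = 13))
  expect_lt(cor(tctGfp(tct, "A1"), tctPValues(tct, "A1")), -0.5)
  # and the active window is marked as consistent
  ci <- consistentIntervals(tct, "A1")
  expect_gt(nrow(ci), 0)
  expect_true(any(ci$start <= 25 & ci$end >= 15))
})

test_that("groups are tested as separate strata", {
  sim <- simulateErp(erpSimSpec(nSubjects = 8, factorLevels = 1,
                                nTime = 6, nSensors = 8, nGroups = 2,
                                seed = 15))
  bd <- betweenDesign(sim$truth$groups, "categorical",
                      groupLabels = c("good", "poor"))
  tct <- topographicConsistencyTest(
    sim$dataset, randomizationOptions(nRuns = 40, seed = 2),
    between = bd)
  expect_equal(tct@strata, c("good.A1", "poor.A1"))
})
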