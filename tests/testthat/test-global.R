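test_that("pseudo-P ranks each run against the others with the >= rule", {
  expect_equal(pseudoPMatrix(matrix(c(3, 1, 2), 3, 1)),
               matrix(c(1 / 3, 1, 2 / 3), 3, 1))
  # the run with the largest s gets the smallest pseudo-P
  set.seed(1)
  m <- matrix(rnorm(50), 10, 5)
  pp <- pseudoPMatrix(m)
  for (t in 1:5)
    expect_equal(which.min(pp[, t]), which.max(m[, t]))
  # ties: all runs equal -> pseudo-P = 1 everywhere
  expect_true(all(pseudoPMatrix(matrix(2, 6, 3)) == 1))
  # run order is irrelevant up to the same permutation
  o <- sample(10)
  expect_equal(pseudoPMatrix(m[o, ]), pp[o, ])
})

test_that("the count test compares the observed count to the null counts", {
  pseudo <- matrix(c(0.2, 0.6, 0.9,
                     0.01, 0.5, 0.8,
                     0.04, 0.02, 0.7), 3, 3, byrow = TRUE)
  # no observed significance -> k = 0, every null count >= 0 -> p = 1
  expect_equal(countSignificanceTest(c(0.5, 0.6, 0.7), pseudo, 0.05),
               1)
  # k = 2; null counts are 0, 1, 2 -> (1 + 1) / (1 + 3)
  expect_equal(countSignificanceTest(c(0.01, 0.02, 0.9), pseudo,
                                     0.05), 2 / 4)
  expect_error(countSignificanceTest(c(0.1, 0.2), pseudo, 0.05),
               "time axis")
})

test_that("the duration threshold is the (1 - alpha) null duration quantile", {
  # craft pseudo-P rows whose max sub-alpha run lengths are
  # 1, 1, 1, 1, 10 -> at alpha = .2 exactly one run (20%) reaches 10
  mk <- function(len, nt = 12) {
    p <- rep(0.9, nt); if (len > 0) p[seq_len(len)] <- 0.01; p
  }
  pseudo <- rbind(mk(1), mk(1), mk(1), mk(1), mk(10))
  expect_equal(durationThreshold(pseudo, 0.2), 10L)
  # alpha -> 1: a single sample suffices
  expect_equal(durationThreshold(pseudo, 1), 1L)
  # null with no significant stretches: any single sample is enough
  expect_equal(durationThreshold(matrix(0.9, 5, 6), 0.05), 1L)
  # monotone in alpha for a fixed null (quantile sense): the sub-alpha
  # pattern is unchanged between these alphas, the quantile moves
  pseudo2 <- rbind(mk(2), mk(2), mk(3), mk(5), mk(8))
  expect_gte(durationThreshold(pseudo2, 0.25),
             durationThreshold(pseudo2, 0.45))
})

test_that("the duration mask keeps only long-enough sub-alpha intervals", {
  cl <- applyDurationMask(rep(0.01, 5), 3, 0.05)
  expect_equal(nrow(cl), 1L)
  expect_equal(c(cl$start, cl$end), c(1L, 5L))
  expect_equal(nrow(applyDurationMask(c(0.9, 0.01, 0.01, 0.9), 3,
                                      0.05)), 0L)
  p <- c(0.01, 0.01, 0.01, 0.01, 0.5, 0.01, 0.01, 0.5)
  cl2 <- applyDurationMask(p, 3, 0.05)
  expect_equal(nrow(cl2), 1L)
  expect_equal(c(cl2$start, cl2$end), c(1L, 4L))
  # boundary samples at exactly alpha are not significant
  expect_equal(nrow(applyDurationMask(rep(0.05, 6), 2, 0.05)), 0L)
})

test_that("globalInference assembles per-effect tables in samples and ms", {
  ds <- h0Dataset(81)
  res <- quietTanova(ds, wd22(),
                     options = randomizationOptions(nRuns = 80,
                                                    seed = 13))
  gi <- globalInference(res)
  tab <- globalTable(gi)
  expect_equal(tab$effect, c("A", "B", "AxB"))
  expect_true(all(tab$countP > 0 & tab$countP <= 1))
  expect_true(all(tab$thresholdSamples >= 1))
  expect_equal(tab$thresholdMs,
               tab$thresholdSamples * 1000 / samplingRate(ds))
  cl <- significantClusters(gi, "A")
  expect_true(is.data.frame(cl))
})
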