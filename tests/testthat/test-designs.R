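test_that("within designs enforce orthogonality of two factors", {
  expect_silent(wd22())
  # excluding one condition of a 2 x 2 breaks the crossing
  expect_error(withinDesign(list(A = c(1, 1, 2, NA),
                                 B = c(1, 2, 1, NA))),
               "orthogonal")
  # a balanced post-hoc subset is fine: drop one level of B entirely
  expect_silent(withinDesign(list(A = c(1, NA, 2, NA),
                                  B = c(1, NA, 1, NA))))
  expect_error(withinDesign(list(A = c(1, 2), B = c(1, 2),
                                 C = c(1, 2))), "two")
  # a level on one factor only is rejected
  expect_error(withinDesign(list(A = c(1, 1, 2, 2),
                                 B = c(1, NA, 1, 2))))
})

test_that("between designs validate their mode", {
  expect_silent(betweenDesign(c(1, 1, 2, 2), "categorical"))
  bd <- betweenDesign(c(1, 1, NA, 2, 2), "categorical")
  expect_equal(useFlags(bd), c(TRUE, TRUE, FALSE, TRUE, TRUE))
  expect_error(betweenDesign(rep(3, 4), "continuous"), "distinct")
  expect_error(betweenDesign(numeric(0), "categorical"))
})

test_that("effect enumeration is deterministic and complete", {
  wd <- wd22()
  wd1 <- withinDesign(list(A = c(1, 2)))
  bdG <- betweenDesign(c(1, 1, 2, 2), "categorical")
  bdC <- betweenDesign(c(0.1, 0.5, 0.9, 1.3), "continuous",
                       name = "improvement")

  expect_equal(vapply(enumerateEffects(wd), function(e) e@id, ""),
               c("A", "B", "AxB"))
  expect_equal(length(enumerateEffects(wd1)), 1L)
  expect_equal(vapply(enumerateEffects(wd, bdG),
                      function(e) e@id, ""),
               c("A", "B", "AxB", "G", "GxA", "GxB", "GxAxB"))
  ids <- vapply(enumerateEffects(wd, bdC), function(e) e@id, "")
  expect_equal(ids, c("A", "B", "AxB", "Cov", "CovxA", "CovxB",
                      "CovxAxB"))
  labs <- vapply(enumerateEffects(wd, bdC), function(e) e@label, "")
  expect_true("improvement x A" %in% labs)
  expect_equal(length(enumerateEffects(NULL, NULL)), 0L)
  # pure function of the designs
  expect_identical(enumerateEffects(wd, bdG),
                   enumerateEffects(wd, bdG))
})

test_that("cell means marginalize, and interactions are fully centered", {
  sim <- simulateErp(erpSimSpec(nSubjects = 5, nTime = 6,
                                nSensors = 8, seed = 21))
  ds <- sim$dataset
  wd <- wd22()
  x <- erpData(ds)
  # main effect of A at t = 3: mean over subjects and B levels
  M <- cellMeans(ds, wd, NULL, "A", 3)
  expect_equal(nrow(M), 2L)
  expect_equal(M[1, ], colMeans(rbind(x[, 1, 3, ], x[, 2, 3, ])),
               ignore_attr = TRUE)
  expect_equal(M[2, ], colMeans(rbind(x[, 3, 3, ], x[, 4, 3, ])),
               ignore_attr = TRUE)

  # all conditions copies of one map -> identical cell means
  x2 <- x
  for (k in 2:4) x2[, k, , ] <- x2[, 1, , ]
  ds2 <- erpDataset(x2)
  M2 <- cellMeans(ds2, wd, NULL, "A", 2)
  expect_equal(M2[1, ], M2[2, ], ignore_attr = TRUE)

  # additive data: interaction cell means vanish after centering
  add <- additiveDataset(seed = 5)
  Mi <- cellMeans(add, wd, NULL, "AxB", 4)
  Mm <- cellMeans(add, wd, NULL, "A", 4)
  expect_lt(max(abs(Mi)), 1e-12 * max(1, max(abs(Mm))))
})

test_that("empty cells and undersized groups are caught", {
  sim <- simulateErp(erpSimSpec(nSubjects = 5, nTime = 4,
                                nSensors = 6, seed = 9))
  bd <- betweenDesign(c(1, 1, 1, 1, 2), "categorical")
  expect_error(
    quietTanova(sim$dataset, wd22(), bd,
                randomizationOptions(nRuns = 10, seed = 1)),
    ">= 2 used subjects")
})

test_that("shuffles permute labels only, with the right support", {
  wd1 <- withinDesign(list(A = c(1, 2)))
  eff <- enumerateEffects(wd1)[[1]]
  # 3 subjects, 2 levels: exactly 2^3 = 8 distinct relabelings,
  # identity among them
  set.seed(10)
  seen <- character(0)
  for (i in 1:300) {
    sh <- shuffleLabels(wd1, NULL, eff, nSubjects = 3)
    expect_true(all(apply(sh$cells, 1, sort) == c(1, 2)))  # labels move
    seen <- c(seen, paste(sh$cells, collapse = ""))
  }
  expect_equal(length(unique(seen)), 8L)
  expect_true(paste(matrix(c(1, 2), 3, 2, byrow = TRUE),
                    collapse = "") %in% seen)

  # a factor-scheme shuffle moves A labels jointly across B levels
  wd <- wd22()
  effA <- enumerateEffects(wd)[[1]]
  set.seed(11)
  for (i in 1:20) {
    sh <- shuffleLabels(wd, NULL, effA, nSubjects = 4)
    # columns are conditions (A1B1, A1B2, A2B1, A2B2): per subject the
    # first two entries agree, the last two agree, and together they
    # are a permutation of the two levels
    expect_true(all(sh$cells[, 1] == sh$cells[, 2]))
    expect_true(all(sh$cells[, 3] == sh$cells[, 4]))
    expect_true(all(sort(unique(c(sh$cells[1, ]))) == c(1, 2)))
  }

  # between effect: one global permutation of group labels
  bd <- betweenDesign(c(1, 1, 2, 2, 2), "categorical")
  effG <- enumerateEffects(wd, bd)[[4]]
  set.seed(12)
  for (i in 1:20) {
    sh <- shuffleLabels(wd, bd, effG, nSubjects = 5)
    expect_equal(sort(sh$groups), c(1, 1, 2, 2, 2))
    expect_identical(sh$cells, matrix(rep(1L, 20), 5))  # untouched
  }
})

test_that("shuffled cell means converge to the grand mean", {
  set.seed(13)
  ns <- 6; nch <- 8
  x <- array(rnorm(ns * 2 * 1 * nch), c(ns, 2, 1, nch))
  ds <- erpDataset(x)
  wd1 <- withinDesign(list(A = c(1, 2)))
  eff <- enumerateEffects(wd1)[[1]]
  nSh <- 600
  acc <- matrix(0, 2, nch)
  for (i in seq_len(nSh)) {
    sh <- shuffleLabels(wd1, NULL, eff, nSubjects = ns)
    for (cell in 1:2) {
      idx <- which(sh$cells == cell, arr.ind = TRUE)
      mm <- vapply(seq_len(nrow(idx)), function(j)
        x[idx[j, 1], idx[j, 2], 1, ], numeric(nch))
      acc[cell, ] <- acc[cell, ] + rowMeans(mm)
    }
  }
  grand <- apply(x[, , 1, ], 3, mean)
  avg <- acc / nSh
  # SE of a mean of shuffled cell means ~ sd / sqrt(nSh * ns)
  se <- sd(x) / sqrt(nSh * ns)
  expect_lt(max(abs(sweep(avg, 2, grand))), 3 * se * 3)
})
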