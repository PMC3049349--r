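test_that("GFP is the spatial RMS about the mean, reference-free and homogeneous", {
  expect_equal(gfp(c(5, 5, 5, 5)), 0)
  expect_equal(gfp(c(1, -1)), 1)          # sqrt((1 + 1) / 2)
  expect_error(gfp(3), "2 sensors")

  set.seed(1)
  for (i in 1:20) {
    m <- rnorm(sample(2:30, 1))
    k <- rnorm(1)
    expect_equal(gfp(m + 7), gfp(m))                 # reference shift
    expect_equal(gfp(k * m), abs(k) * gfp(m))        # homogeneity
  }
  expect_equal(gfp(rep(2.5, 9)), 0)                  # flat iff zero
})

test_that("L2 normalization yields unit GFP, preserves shape, idempotent", {
  expect_equal(normalizeMap(c(2, -2)), c(1, -1))
  m <- c(3, 1, -4, 0)
  expect_identical(normalizeMap(m, "none"), m)
  nm <- normalizeMap(m)
  expect_equal(gfp(nm), 1, tolerance = 1e-12)
  # direction preserved: proportional to the centered input
  expect_equal(cor(nm, m - mean(m)), 1)
  expect_equal(normalizeMap(nm), nm)
  expect_error(normalizeMap(c(4, 4, 4)), "flat map")
})

test_that("effect strength s matches the hand oracle and its invariances", {
  expect_equal(effectStrength(rbind(c(1, 0), c(1, 0))), 0)
  expect_equal(effectStrength(rbind(c(1, -1), c(-1, 1))), sqrt(2))
  expect_error(effectStrength(list(c(1, 2), c(1, 2, 3))),
               "mismatched")

  set.seed(2)
  cells <- matrix(rnorm(4 * 8), 4, 8)
  s0 <- effectStrength(cells)
  expect_equal(effectStrength(cells[c(3, 1, 4, 2), ]), s0)  # order
  common <- rnorm(8)
  shifted <- sweep(cells, 2, -common)
  expect_equal(effectStrength(shifted), s0)                 # common map
  # s grows continuously with a one-sensor perturbation of one cell
  # of an otherwise homogeneous set
  base <- matrix(rep(rnorm(8), each = 4), 4, 8)
  eps <- c(0, 0.1, 0.5, 1, 2)
  sv <- vapply(eps, function(e) {
    cc <- base; cc[1, 1] <- cc[1, 1] + e; effectStrength(cc)
  }, numeric(1))
  expect_equal(sv[1], 0)
  expect_true(all(diff(sv) > 0))
})

test_that("covariance maps are the centered cross-product and bilinear", {
  m <- c(2, -1, 0.5, -1.5)
  expect_equal(covarianceMap(rbind(m, -m), c(1, -1)), 2 * m)
  expect_equal(covarianceMap(rbind(m, m, m), rep(0, 3)), rep(0, 4))
  expect_error(covarianceMap(rbind(m, m), 1:3), "one predictor")

  set.seed(3)
  maps <- matrix(rnorm(6 * 5), 6, 5)
  b1 <- rnorm(6); b2 <- rnorm(6)
  expect_equal(covarianceMap(maps, b1 + b2, center = FALSE),
               covarianceMap(maps, b1, center = FALSE) +
                 covarianceMap(maps, b2, center = FALSE))
  expect_equal(covarianceMap(2 * maps, b1), 2 * covarianceMap(maps, b1))
  # centering: adding a constant to the predictor changes nothing
  expect_equal(covarianceMap(maps, b1 + 5), covarianceMap(maps, b1))
})

test_that("TANCOVA strength is the GFP of the covariance map", {
  set.seed(4)
  for (i in 1:10) {
    maps <- matrix(rnorm(8 * 12), 8, 12)
    b <- rnorm(8)
    beta <- covarianceMap(maps, b)
    expect_equal(tancovaStrength(beta), gfp(beta))
    # scaling the predictor by k scales the strength by |k|
    expect_equal(tancovaStrength(covarianceMap(maps, -3 * b)),
                 3 * tancovaStrength(beta))
  }
  expect_equal(tancovaStrength(rep(0, 5)), 0)
  expect_equal(tancovaStrength(c(1, -1)), 1)
})
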