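test_that("ROI summaries reduce masked finite voxels", {
  m3 <- array(1, dim = c(3, 3, 3))
  mask <- roi_mask(m3)
  const <- parameter_map("t2star", array(50, dim = dim(m3)),
                         array(TRUE, dim = dim(m3)), array(0, dim = dim(m3)))
  expect_equal(roi_summary(const, mask, "mean"), 50)

  vals <- array(NaN, dim = dim(m3)); vals[1:3] <- c(1, 2, 100)
  vm <- parameter_map("x", vals, array(TRUE, dim = dim(m3)), array(0, dim = dim(m3)))
  expect_equal(roi_summary(vm, mask, "median"), 2)
  expect_equal(roi_summary(vm, mask, "mean"), mean(c(1, 2, 100)))

  allnan <- parameter_map("x", array(NaN, dim = dim(m3)),
                          array(FALSE, dim = dim(m3)), array(0, dim = dim(m3)))
  expect_error(roi_summary(allnan, mask), "no finite voxels")

  # flagged-voxel exclusion
  ok <- array(TRUE, dim = dim(m3)); ok[3] <- FALSE
  vm2 <- parameter_map("x", vals, ok, array(0, dim = dim(m3)))
  expect_equal(roi_summary(vm2, mask, "mean", exclude_flagged = TRUE), 1.5)
})

test_that("normative regression matches the closed-form least squares", {
  # exact line carrying the published control slope
  ga <- c(22, 25, 28, 31, 34)
  v <- 160 - 3.004 * ga
  nm <- suppressWarnings(fit_normative(ga, v))  # exact fit warns in summary.lm
  expect_equal(nm$slope, -3.004, tolerance = 1e-12)
  expect_equal(nm$intercept, 160, tolerance = 1e-10)
  expect_equal(nm$r2, 1)

  flat <- suppressWarnings(fit_normative(ga, rep(7, 5)))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r2, 0)

  # closed-form normal equations as independent oracle
  set.seed(31)
  for (i in 1:25) {
    n <- sample(3:12, 1)
    x <- runif(n, 20, 38); y <- rnorm(n, 50, 10)
    if (length(unique(x)) < 2) next
    nm <- fit_normative(x, y)
    sl <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    ic <- mean(y) - sl * mean(x)
    rss <- sum((y - ic - sl * x)^2)
    expect_equal(nm$slope, sl, tolerance = 1e-10)
    expect_equal(nm$intercept, ic, tolerance = 1e-10)
    expect_equal(nm$residual_sd, sqrt(rss / (n - 2)), tolerance = 1e-10)
  }
  expect_error(fit_normative(c(28, 28, 28), c(1, 2, 3)), "identical")
  expect_error(fit_normative(c(28, 29), c(1, 2)), ">= 3")
})

test_that("z-scores measure deviation from the control trend in residual SDs", {
  set.seed(12)
  ga <- runif(40, 20, 38)
  v <- 160 - 3 * ga + rnorm(40, 0, 5)
  nm <- fit_normative(ga, v)
  on_line <- nm$intercept + nm$slope * 27
  expect_equal(zscore(on_line, 27, nm), 0)
  expect_equal(zscore(on_line + nm$residual_sd, 27, nm), 1)
  # control cohort scored against its own model: mean 0, SD = consistent value
  z <- zscore(v, ga, nm)
  expect_lt(abs(mean(z)), 1e-10)
  expect_equal(stats::sd(z), sqrt((40 - 2) / (40 - 1)), tolerance = 1e-6)
})

test_that("group z-score comparison behaves like a Welch t-test should", {
  expect_error(group_difference(1, c(0, 1)), ">= 2 subjects")
  same <- c(-1, 0, 1, 2)
  gt <- group_difference(same, same)
  expect_equal(gt$statistic, 0)
  expect_equal(gt$p, 1)

  set.seed(5)
  zc <- rnorm(60); zp <- rnorm(16, -3)
  gt2 <- group_difference(zp, zc)
  expect_lt(gt2$p, 0.005)
  # shift invariance: adding a constant to both groups changes nothing
  gt3 <- group_difference(zp + 4.2, zc + 4.2)
  expect_equal(gt3$p, gt2$p)
  expect_equal(gt3$statistic, gt2$statistic)

  # null calibration: p approximately uniform under label permutation
  set.seed(6)
  zall <- rnorm(76)
  ps <- replicate(200, {
    pick <- sample(76, 16)
    group_difference(zall[pick], zall[-pick])$p
  })
  expect_gt(mean(ps < 0.05), 0.01)
  expect_lt(mean(ps < 0.05), 0.12)
})

test_that("z-outcome regression recovers structure and respects nulls", {
  out <- c(25, 27, 29, 31, 33)
  z <- 0.5 * out - 14
  r <- suppressWarnings(z_outcome_regression(z, out, "ga_delivery"))
  expect_equal(r$r2, 1)
  expect_equal(r$slope, 0.5, tolerance = 1e-10)

  # missing outcomes are dropped with a message; too few remaining errors
  expect_message(suppressWarnings(
    z_outcome_regression(c(z, 1), c(out, NA), "ga_delivery")), "dropped")
  expect_error(z_outcome_regression(c(1, 2, NA), c(25, NA, 27), "x"), ">= 3")

  # independent z and outcome: p > 0.05 in at least 90% of repeats
  set.seed(14)
  hits <- replicate(100, {
    z <- rnorm(16); o <- runif(16, 24, 34)
    z_outcome_regression(z, o)$p > 0.05
  })
  expect_gte(mean(hits), 0.90)

  # built-in coupling: sign recovered in at least 95% of repeats
  set.seed(15)
  signs <- replicate(100, {
    o <- runif(16, 24, 34)
    z <- -10 + 0.4 * o + rnorm(16, 0, 0.5)
    sign(z_outcome_regression(z, o)$slope)
  })
  expect_gte(mean(signs > 0), 0.95)
})
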