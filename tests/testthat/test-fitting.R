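paper <- build_paper_scheme()
avg56 <- direction_average_signals(matrix(0, 1, 264), paper)$scheme
mege <- build_mege_scheme()

test_that("mono-exponential fit recovers noiseless decay exactly", {
  sig <- signal_mono(100, 50, mege)
  r <- fit_monoexp(sig, mege)
  expect_true(r$converged)
  expect_lt(abs(r$params$s0 / 100 - 1), 1e-6)
  expect_lt(abs(r$params$t2star / 50 - 1), 1e-6)
  expect_lt(r$rss, 1e-12)
})

test_that("non-decaying signal is clipped to the bound and flagged", {
  r <- fit_monoexp(rep(80, 5), mege)
  expect_false(r$converged)
  expect_equal(r$params$t2star, fit_config()$t2star_bounds[2], tolerance = 1e-4)
  expect_error(fit_monoexp(c(1, 2), acq_scheme(c(80, 80), c(0, 0))), "distinct TEs")
})

test_that("mono fit matches a dense grid-search oracle under Rician noise", {
  # grid oracle: exhaustive RSS minimisation over (s0, t2star)
  grid_fit <- function(sig) {
    s0g <- seq(80, 120, length.out = 81)
    t2g <- seq(30, 120, length.out = 181)
    rss <- outer(s0g, t2g, function(a, b) {
      vapply(seq_along(a), function(i)
        sum((a[i] * exp(-mege$te_ms / b[i]) - sig)^2), numeric(1))
    })
    w <- arrayInd(which.min(rss), dim(rss))
    c(s0g[w[1]], t2g[w[2]])
  }
  set.seed(9)
  est <- matrix(0, 60, 2); orc <- matrix(0, 60, 2)
  clean <- signal_mono(100, 60, mege)
  for (i in 1:60) {
    noisy <- add_rician_noise(clean, 2, seed = 100 + i)
    r <- fit_monoexp(noisy, mege)
    est[i, ] <- c(r$params$s0, r$params$t2star)
    orc[i, ] <- grid_fit(noisy)
  }
  expect_lt(abs(median(est[, 2]) / median(orc[, 2]) - 1), 0.02)
  expect_lt(abs(median(est[, 1]) / median(orc[, 1]) - 1), 0.02)
})

test_that("T2*-ADC fit recovers noiseless parameters on the averaged scheme", {
  truth <- eq1_params(1, 60, 1.8)
  sig <- signal_eq1(truth, avg56)
  r <- fit_t2s_adc(sig, avg56)
  expect_true(r$converged)
  expect_lt(abs(r$params$s0 - 1), 1e-6)
  expect_lt(abs(r$params$t2star / 60 - 1), 1e-6)
  expect_lt(abs(r$params$adc / 1.8 - 1), 1e-6)
})

test_that("axis-deficient schemes are refused with a named axis", {
  one_te <- acq_scheme(rep(78, 4), c(0, 100, 400, 800))
  expect_error(fit_t2s_adc(rep(1, 4), one_te), "TE axis")
  one_b <- acq_scheme(c(78, 114, 150, 186), rep(0, 4))
  expect_error(fit_t2s_adc(rep(1, 4), one_b), "b axis")
  two_b <- acq_scheme(c(78, 114, 78, 114), c(0, 0, 800, 800))
  expect_error(fit_t2s_ivim(rep(1, 4), two_b), "b axis")
})

test_that("T2*-ADC estimates converge to truth as noise vanishes", {
  truth <- eq1_params(100, 60, 1.8)
  clean <- signal_eq1(truth, avg56)
  errs <- vapply(c(2, 0.5, 0.05), function(sg) {
    est <- vapply(1:8, function(i) {
      r <- fit_t2s_adc(add_rician_noise(clean, sg, seed = i), avg56)
      c(r$params$t2star, r$params$adc)
    }, numeric(2))
    mean(abs(rowMeans(est) / c(60, 1.8) - 1))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 1e-3)
})

test_that("IVIM fit recovers noiseless two-compartment parameters", {
  truth <- eq2_params(1, 0.3, 120, 50, 50, 1.5)
  sig <- signal_eq2(truth, avg56)
  r <- fit_t2s_ivim(sig, avg56)
  expect_true(r$converged)
  for (nm in names(truth)) {
    expect_lt(abs(r$params[[nm]] / truth[[nm]] - 1), 1e-3)
  }
})

test_that("nested f=0 data yields a degenerate IVIM fit matching T2*-ADC", {
  sig <- signal_eq2(eq2_params(100, 0, 150, 55, 40, 1.6), avg56)
  r2 <- fit_t2s_ivim(sig, avg56)
  r1 <- fit_t2s_adc(sig, avg56)
  expect_lt(r2$params$f, 0.02)
  expect_lt(abs(r2$params$t2star_slow / r1$params$t2star - 1), 0.01)
  expect_lt(abs(r2$params$adc_slow / r1$params$adc - 1), 0.01)
})

test_that("compartment labels are ordered by diffusivity regardless of init", {
  # diffusivities inside the D*/ADC bounds overlap so that the label-swapped
  # parameter point is feasible too
  truth <- eq2_params(1, 0.35, 120, 50, 3.8, 3.2)
  sig <- signal_eq2(truth, avg56)
  straight <- fit_t2s_ivim(sig, avg56, fit_config(n_multistart = 1))
  swapped_init <- list(s0 = 1, f = 0.65, t2star_fast = 50, t2star_slow = 120,
                       dstar = 3.2, adc_slow = 3.8)
  # a start with exchanged labels must land on the same labeled solution
  swapped <- fit_t2s_ivim(sig, avg56,
                          fit_config(n_multistart = 1, init_override = swapped_init))
  for (nm in names(truth)) {
    expect_lt(abs(swapped$params[[nm]] / straight$params[[nm]] - 1), 1e-4)
  }
  expect_gt(swapped$params$dstar, swapped$params$adc_slow)
})

test_that("two-compartment RSS never exceeds single-compartment RSS", {
  # nesting: the T2*-ADC model is the f=0 submodel of T2*-IVIM
  truth <- eq2_params(100, 0.3, 110, 55, 35, 1.4)
  clean <- signal_eq2(truth, avg56)
  worse <- 0
  for (i in 1:100) {
    noisy <- add_rician_noise(clean, 2, seed = 2000 + i)
    r2 <- fit_t2s_ivim(noisy, avg56, fit_config(seed = i))
    r1 <- fit_t2s_adc(noisy, avg56, fit_config(seed = i))
    if (r2$rss > r1$rss + 1e-9) worse <- worse + 1
    expect_gte(r2$params$dstar, r2$params$adc_slow)
  }
  expect_equal(worse, 0)
})

test_that("noisy single-voxel IVIM recovery meets the accuracy budget", {
  truth <- eq2_params(100, 0.4, 120, 50, 40, 1.5)
  clean <- signal_eq2(truth, paper)
  est <- vapply(1:200, function(i) {
    a <- direction_average_signals(add_rician_noise(clean, 2, seed = 3000 + i), paper)
    unlist(fit_t2s_ivim(as.vector(a$signals), a$scheme, fit_config(seed = i))$params)
  }, numeric(6))
  relerr <- abs(est / unlist(truth) - 1)
  med <- apply(relerr, 1, median)
  expect_lt(med[["f"]], 0.10)
  expect_lt(med[["t2star_fast"]], 0.10)
  expect_lt(med[["t2star_slow"]], 0.10)
  expect_lt(med[["adc_slow"]], 0.10)
  expect_lt(med[["dstar"]], 0.25)  # pseudo-diffusivity is weakly identified
})

test_that("fits are scale-equivariant and seed-deterministic", {
  truth <- eq2_params(1, 0.3, 120, 50, 50, 1.5)
  sig <- signal_eq2(truth, avg56)
  a <- fit_t2s_ivim(sig, avg56, fit_config(seed = 5))
  b <- fit_t2s_ivim(sig * 37, avg56, fit_config(seed = 5))
  expect_equal(b$params$s0 / a$params$s0, 37, tolerance = 1e-6)
  for (nm in setdiff(names(truth), "s0")) {
    expect_equal(b$params[[nm]], a$params[[nm]], tolerance = 1e-6)
  }
  noisy <- add_rician_noise(sig, 0.02, seed = 1)
  r1 <- fit_t2s_ivim(noisy, avg56, fit_config(seed = 9))
  r2 <- fit_t2s_ivim(noisy, avg56, fit_config(seed = 9))
  expect_identical(r1$params, r2$params)
})

test_that("volume fitting respects the mask and is deterministic", {
  ph <- make_phantom(shape = c(16, 16, 16), n_lobules = 1,
                     scheme = avg56, sigma = 0.5, seed = 2)
  cfg <- fit_config(seed = 3, n_multistart = 2)
  maps <- fit_volume(ph$image, ph$mask, "t2s_adc", cfg)
  m <- unclass(ph$mask)
  expect_true(all(is.nan(maps$t2star$data[!m])))
  expect_true(all(is.finite(maps$t2star$data[m])))
  maps2 <- fit_volume(ph$image, ph$mask, "t2s_adc", cfg)
  expect_identical(maps$t2star$data, maps2$t2star$data)

  one <- array(0, dim = dim(m)); one[8, 8, 8] <- 1
  maps1 <- fit_volume(ph$image, roi_mask(one), "mono", fit_config())
  expect_equal(sum(is.finite(maps1$t2star$data)), 1L)
})
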