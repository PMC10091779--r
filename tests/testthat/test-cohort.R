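test_that("default cohort matches the study design", {
  spec <- cohort_spec(n_voxels = 2, models = "mono", seed = 10)
  expect_equal(spec$n_control, 60L)
  expect_equal(spec$n_pprom, 16L)
  co <- make_cohort(spec)
  expect_equal(sum(co$table$group == "control"), 60L)
  expect_equal(sum(co$table$group == "PPROM"), 16L)
  # PPROM deliver much earlier (group means near 29 vs 40 weeks)
  mns <- tapply(co$table$ga_delivery_weeks, co$table$group, mean)
  expect_lt(abs(mns[["PPROM"]] - 29), 2)
  expect_lt(abs(mns[["control"]] - 40), 1)
  expect_true(all(co$table$ga_delivery_weeks >= co$table$ga_scan_weeks))
  expect_true(all(is.na(co$table$rom_to_scan_days[co$table$group == "control"])))
  expect_true(all(co$table$rom_to_scan_days[co$table$group == "PPROM"] >= 0))
})

test_that("an out-of-range fraction trend is rejected with guidance", {
  expect_error(cohort_spec(ga_range_control = c(20, 38), models = "t2s_ivim"),
               "restrict the GA range")
  # the same range is fine when the diffusion data follow the one-compartment model
  expect_silent(cohort_spec(ga_range_control = c(20, 38), models = "t2s_adc"))
})

test_that("noise-free control values sit exactly on the trend line", {
  tr <- default_trends()
  tr$sd_between <- 0
  spec <- cohort_spec(n_control = 12, n_pprom = 0, trends = tr, n_voxels = 1,
                      models = "mono", seed = 6)
  co <- make_cohort(spec)
  ga <- co$table$ga_scan_weeks
  v <- vapply(co$subjects, function(s) s$true_values$mege_t2star, numeric(1))
  nm <- suppressWarnings(fit_normative(ga, v))  # exact fit warns in summary.lm
  expect_equal(nm$r2, 1, tolerance = 1e-12)
  expect_equal(nm$slope, -3.004, tolerance = 1e-9)
})

test_that("cohort generation is reproducible and the CSV round-trips", {
  spec <- cohort_spec(n_control = 4, n_pprom = 2, n_voxels = 3,
                      models = c("mono", "t2s_ivim"), seed = 77)
  a <- make_cohort(spec); b <- make_cohort(spec)
  expect_identical(a$table, b$table)
  expect_identical(a$subjects[[3]]$signals, b$subjects[[3]]$signals)

  path <- file.path(tempdir(), "cohort.csv")
  write_cohort_table(a$table, path)
  back <- read_cohort_table(path)
  expect_equal(back, a$table, tolerance = 1e-12)

  bad <- a$table; bad$group[1] <- "case"
  write_cohort_table(bad, path)
  expect_error(read_cohort_table(path), "control")
})

test_that("PPROM offset shifts T2* quantities by the requested z amount", {
  tr <- default_trends()
  tr$sd_between <- 0  # isolate the group offset
  spec <- cohort_spec(n_control = 5, n_pprom = 5, trends = tr, n_voxels = 1,
                      models = "mono", ga_range_pprom = c(24, 30), seed = 8,
                      pprom_offset = c(mege_t2star = -2))
  co <- make_cohort(spec)
  for (s in co$subjects) {
    # sd_between = 0 makes the offset (expressed in sd units) vanish too
    expect_equal(s$true_values$mege_t2star, 75 - 3.004 * (s$ga_scan - 28))
  }
  tr$sd_between[tr$quantity == "mege_t2star"] <- 4
  spec2 <- cohort_spec(n_control = 200, n_pprom = 200, trends = tr, n_voxels = 1,
                       models = "mono", ga_range_pprom = c(22, 32), seed = 9,
                       pprom_offset = c(mege_t2star = -1.5))
  co2 <- make_cohort(spec2)
  resid <- vapply(co2$subjects, function(s)
    s$true_values$mege_t2star - (75 - 3.004 * (s$ga_scan - 28)), numeric(1))
  grp <- co2$table$group
  shift <- mean(resid[grp == "PPROM"]) - mean(resid[grp == "control"])
  expect_equal(shift, -1.5 * 4, tolerance = 1.2)  # MC tolerance ~3 SE
})
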