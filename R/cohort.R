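#' Default control-cohort gestational-age trends
#'
#' One row per tracked ROI quantity: the linear slope over gestational age,
#' an anchor (value at a reference GA) pinning the intercept, and the
#' between-subject SD around the trend. Slopes are the published normative
#' control slopes for this acquisition; anchors are plausible mid-gestation
#' placental values chosen by this package (the normative table reports no
#' intercepts). T2* quantities in ms, diffusivities in 1e-3 mm2/s, the
#' perfusion fraction as a fraction in `[0, 1]`.
#'
#' @return data.frame with columns `quantity`, `slope` (units/week),
#'   `anchor_value`, `anchor_ga` (weeks), `sd_between`
#' @export
default_trends <- function() {
  data.frame(
    quantity = c("mege_t2star", "t2sadc_t2star", "t2sadc_adc",
                 "ivim_t2star_fast", "ivim_t2star_slow", "ivim_dstar",
                 "ivim_adc_slow", "ivim_f"),
    slope = c(-3.004, -2.615, -0.035, -4.791, -0.671, -0.764, -0.033, 0.05726),
    anchor_value = c(75, 75, 1.8, 120, 55, 40, 1.5, 0.50),
    anchor_ga = c(28, 28, 28, 28, 28, 28, 28, 27),
    sd_between = c(5, 5, 0.10, 5, 3, 5, 0.10, 0.05))
}

#' The ROI quantities tracked by the cohort statistics
#' @return character vector of quantity labels
#' @export
tracked_quantities <- function() default_trends()$quantity

trend_value <- function(trends, quantity, ga) {
  r <- trends[trends$quantity == quantity, ]
  if (nrow(r) != 1L) stop("no trend defined for quantity ", quantity)
  r$anchor_value + r$slope * (ga - r$anchor_ga)
}

#' Specification of a synthetic two-group cohort
#'
#' Emulates the study design: healthy controls whose ROI quantities follow
#' linear gestational-age trends, and a PPROM (preterm premature rupture of
#' membranes) group with down-shifted T2* values and earlier deliveries.
#'
#' @param n_control,n_pprom group sizes (defaults 60 and 16)
#' @param ga_range_control,ga_range_pprom GA-at-scan ranges, weeks, within
#'   `[20, 42]`
#' @param models which signal datasets to generate per subject: `"mono"`
#'   (multi-echo gradient-echo series) and/or exactly one of `"t2s_adc"` /
#'   `"t2s_ivim"` (the combined T2*-diffusion series and the model its
#'   signals are drawn from)
#' @param trends trend table as [default_trends()] (per-quantity slope,
#'   anchor, between-subject SD)
#' @param snr ratio of S0 to the Rician noise SD (default 50)
#' @param s0 common signal amplitude at (TEmin, b=0), a.u.
#' @param n_voxels ROI voxels simulated per subject (default 200)
#' @param pprom_offset named numeric: additive group shift per quantity in
#'   units of that quantity's `sd_between` (z-units); default -1.5 on all
#'   T2* quantities
#' @param delivery_mean_control,delivery_mean_pprom mean GA at delivery,
#'   weeks (defaults 40 and 29)
#' @param seed integer seed; the whole cohort generation is reproducible
#'   bit-for-bit given the spec
#' @return a list of class `cohort_spec`
#' @export
cohort_spec <- function(n_control = 60L, n_pprom = 16L,
                        ga_range_control = c(22, 32),
                        ga_range_pprom = c(23, 33),
                        models = c("mono", "t2s_ivim"),
                        trends = default_trends(),
                        snr = 50, s0 = 100, n_voxels = 200L,
                        pprom_offset = c(mege_t2star = -1.5,
                                         t2sadc_t2star = -1.5,
                                         ivim_t2star_fast = -1.5,
                                         ivim_t2star_slow = -1.5),
                        delivery_mean_control = 40,
                        delivery_mean_pprom = 29,
                        seed = 1L) {
  stopifnot(n_control >= 0, n_pprom >= 0, snr > 0, s0 > 0, n_voxels >= 1)
  for (r in list(ga_range_control, ga_range_pprom)) {
    if (!(length(r) == 2L && r[1] <= r[2] && r[1] >= 20 && r[2] <= 42)) {
      stop("GA ranges must lie within [20, 42] weeks")
    }
  }
  models <- match.arg(models, c("mono", "t2s_adc", "t2s_ivim"), several.ok = TRUE)
  if (all(c("t2s_adc", "t2s_ivim") %in% models)) {
    stop("choose one generator for the diffusion series: t2s_adc or t2s_ivim")
  }
  if ("t2s_ivim" %in% models) {
    ga_all <- range(ga_range_control, ga_range_pprom)
    fr <- trend_value(trends, "ivim_f", ga_all)
    if (any(fr < 0 | fr > 1)) {
      stop("the perfusion-fraction trend leaves [0, 1] within the GA range ",
           sprintf("(f = %.3f at %g wk, %.3f at %g wk); ", fr[1], ga_all[1],
                   fr[2], ga_all[2]),
           "restrict the GA range or change the f slope/anchor in `trends`")
    }
  }
  structure(list(n_control = as.integer(n_control), n_pprom = as.integer(n_pprom),
                 ga_range_control = ga_range_control,
                 ga_range_pprom = ga_range_pprom, models = models,
                 trends = trends, snr = snr, s0 = s0,
                 n_voxels = as.integer(n_voxels), pprom_offset = pprom_offset,
                 delivery_mean_control = delivery_mean_control,
                 delivery_mean_pprom = delivery_mean_pprom,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic two-group cohort
#'
#' For each subject, GA at scan is drawn uniformly in the group's range;
#' each tracked quantity's true ROI value is trend(GA) plus
#' Normal(0, sd_between); PPROM subjects additionally receive the group
#' offset (`pprom_offset`, in sd_between units). Voxel signals are generated
#' from the subject's true parameters — the multi-echo gradient-echo series
#' from the mono-exponential model over absolute TE, the diffusion series
#' from the chosen decay model on the full acquisition scheme — with Rician
#' noise of SD `s0 / snr`. Clinical covariates: GA at delivery is Normal
#' around the group mean (40 wk controls, 29 wk PPROM by default), truncated
#' above the scan; ROM-to-scan is uniform 0-21 days for PPROM and missing
#' for controls.
#'
#' @param spec a [cohort_spec()]
#' @return list of class `cohort`: `subjects` (list of per-subject records
#'   with `true_values`, `signals` per generated dataset and the clinical
#'   covariates), `table` (the cohort CSV as a data.frame), `schemes`, and
#'   the `spec`
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  schemes <- list()
  if ("mono" %in% spec$models) schemes$mono <- build_mege_scheme()
  dwi_model <- intersect(spec$models, c("t2s_adc", "t2s_ivim"))
  if (length(dwi_model)) schemes[[dwi_model]] <- build_paper_scheme()

  sigma <- spec$s0 / spec$snr
  groups <- c(rep("control", spec$n_control), rep("PPROM", spec$n_pprom))
  subjects <- vector("list", length(groups))

  for (i in seq_along(groups)) {
    grp <- groups[i]
    rng <- if (grp == "control") spec$ga_range_control else spec$ga_range_pprom
    ga <- stats::runif(1, rng[1], rng[2])

    tv <- list()
    for (q in spec$trends$quantity) {
      r <- spec$trends[spec$trends$quantity == q, ]
      v <- r$anchor_value + r$slope * (ga - r$anchor_ga) + stats::rnorm(1, 0, r$sd_between)
      if (grp == "PPROM" && q %in% names(spec$pprom_offset)) {
        v <- v + spec$pprom_offset[[q]] * r$sd_between
      }
      if (q == "ivim_f") v <- clamp(v, 0.02, 0.98)
      if (grepl("t2star", q)) v <- max(v, 6)
      if (q %in% c("t2sadc_adc", "ivim_adc_slow")) v <- max(v, 0.1)
      if (q == "ivim_dstar") v <- max(v, 4)
      tv[[q]] <- v
    }

    signals <- list()
    if ("mono" %in% spec$models) {
      clean <- signal_mono(spec$s0, tv$mege_t2star, schemes$mono)
      signals$mono <- add_rician_noise(
        matrix(clean, spec$n_voxels, nrow(schemes$mono), byrow = TRUE), sigma)
    }
    if (length(dwi_model)) {
      clean <- if (dwi_model == "t2s_adc") {
        signal_eq1(eq1_params(spec$s0, tv$t2sadc_t2star, tv$t2sadc_adc),
                   schemes[[dwi_model]])
      } else {
        signal_eq2(eq2_params(spec$s0, tv$ivim_f, tv$ivim_t2star_fast,
                              tv$ivim_t2star_slow, tv$ivim_dstar,
                              tv$ivim_adc_slow), schemes[[dwi_model]])
      }
      signals[[dwi_model]] <- add_rician_noise(
        matrix(clean, spec$n_voxels, nrow(schemes[[dwi_model]]), byrow = TRUE), sigma)
    }

    if (grp == "control") {
      ga_del <- clamp(stats::rnorm(1, spec$delivery_mean_control, 1.3), ga + 0.3, 42)
      rom <- NA_real_
    } else {
      ga_del <- clamp(stats::rnorm(1, spec$delivery_mean_pprom, 2.5), ga + 0.15, 37)
      rom <- stats::runif(1, 0, 21)
    }

    subjects[[i]] <- list(
      subject_id = sprintf("%s%03d", if (grp == "control") "C" else "P", i),
      group = grp, ga_scan = ga, ga_delivery = ga_del,
      rom_to_scan = rom, scan_to_delivery = (ga_del - ga) * 7,
      true_values = tv, signals = signals)
  }

  tab <- data.frame(
    subject_id = vapply(subjects, `[[`, "", "subject_id"),
    group = vapply(subjects, `[[`, "", "group"),
    ga_scan_weeks = vapply(subjects, `[[`, 0, "ga_scan"),
    ga_delivery_weeks = vapply(subjects, `[[`, 0, "ga_delivery"),
    rom_to_scan_days = vapply(subjects, `[[`, 0, "rom_to_scan"),
    scan_to_delivery_days = vapply(subjects, `[[`, 0, "scan_to_delivery"))

  structure(list(subjects = subjects, table = tab, schemes = schemes,
                 spec = spec), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d controls + %d PPROM, datasets: %s\n",
              sum(x$table$group == "control"), sum(x$table$group == "PPROM"),
              paste(names(x$schemes), collapse = ", ")))
  invisible(x)
}

#' Read/write the cohort covariate table
#'
#' CSV with columns exactly `subject_id, group, ga_scan_weeks,
#' ga_delivery_weeks, rom_to_scan_days, scan_to_delivery_days` ('.' decimal,
#' UTF-8). Missing ROM-to-scan (controls) is an empty field.
#'
#' @param path CSV path
#' @param table cohort data.frame as produced by [make_cohort()]
#' @return `read_cohort_table`: the data.frame; `write_cohort_table`:
#'   `path`, invisibly
#' @export
read_cohort_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "ga_scan_weeks", "ga_delivery_weeks",
            "rom_to_scan_days", "scan_to_delivery_days")
  if (!all(need %in% names(d))) {
    stop("cohort CSV must have columns ", paste(need, collapse = ", "))
  }
  if (!all(d$group %in% c("control", "PPROM"))) {
    stop("cohort group values must be 'control' or 'PPROM'")
  }
  d
}

#' @rdname read_cohort_table
#' @export
write_cohort_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}
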