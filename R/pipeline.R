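#' Fit all models across a synthetic cohort and summarise per subject
#'
#' Runs the voxelwise fits on every subject's generated signal sets — the
#' mono-exponential model on the multi-echo gradient-echo series, and the
#' T2*-ADC and/or T2*-IVIM models on the direction-averaged diffusion
#' series — then reduces each fitted quantity to one ROI summary value per
#' subject.
#'
#' @param cohort a [make_cohort()] result
#' @param fit_models subset of `c("mono", "t2s_adc", "t2s_ivim")` to fit;
#'   defaults to the mono model (if its series exists) plus both diffusion
#'   models (if a diffusion series exists). Note the diffusion series is
#'   fitted with whichever diffusion models are requested, regardless of
#'   which model generated it — mirroring how acquired data are analysed.
#' @param cfg a [fit_config()]
#' @param stat ROI summary statistic, `"mean"` (default) or `"median"`
#' @return data.frame with columns `subject_id`, `quantity`, `value`
#' @export
fit_cohort <- function(cohort, fit_models = NULL, cfg = fit_config(),
                       stat = c("mean", "median")) {
  stopifnot(inherits(cohort, "cohort"))
  stat <- match.arg(stat)
  have_mono <- "mono" %in% names(cohort$schemes)
  dwi_name <- setdiff(names(cohort$schemes), "mono")
  if (is.null(fit_models)) {
    fit_models <- c(if (have_mono) "mono",
                    if (length(dwi_name)) c("t2s_adc", "t2s_ivim"))
  }
  if ("mono" %in% fit_models && !have_mono) {
    stop("cohort has no gradient-echo series to fit the mono model on")
  }
  dwi_fits <- intersect(fit_models, c("t2s_adc", "t2s_ivim"))
  if (length(dwi_fits) && !length(dwi_name)) {
    stop("cohort has no diffusion series to fit ", paste(dwi_fits, collapse = "/"))
  }
  summ <- if (stat == "mean") mean else stats::median

  out <- list()
  for (i in seq_along(cohort$subjects)) {
    sub <- cohort$subjects[[i]]
    scfg <- cfg
    scfg$seed <- cfg$seed + 10000L * i
    add <- function(quantity, value) {
      out[[length(out) + 1L]] <<- data.frame(
        subject_id = sub$subject_id, quantity = quantity, value = value)
    }
    if ("mono" %in% fit_models) {
      f <- fit_signals(sub$signals$mono, cohort$schemes$mono, "mono", scfg)
      add("mege_t2star", summ(f$t2star))
    }
    if (length(dwi_fits)) {
      avg <- direction_average_signals(sub$signals[[dwi_name]],
                                       cohort$schemes[[dwi_name]])
      if ("t2s_adc" %in% dwi_fits) {
        f <- fit_signals(avg$signals, avg$scheme, "t2s_adc", scfg)
        add("t2sadc_t2star", summ(f$t2star))
        add("t2sadc_adc", summ(f$adc))
      }
      if ("t2s_ivim" %in% dwi_fits) {
        f <- fit_signals(avg$signals, avg$scheme, "t2s_ivim", scfg)
        add("ivim_t2star_fast", summ(f$t2star_fast))
        add("ivim_t2star_slow", summ(f$t2star_slow))
        add("ivim_dstar", summ(f$dstar))
        add("ivim_adc_slow", summ(f$adc_slow))
        add("ivim_f", summ(f$f))
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run the cohort statistics end to end
#'
#' From a cohort covariate table and per-subject ROI summaries: fits one
#' normative control regression per quantity, computes cross-sectional
#' z-scores for all subjects, compares the groups' z-scores (Welch t-test),
#' and regresses PPROM z-scores on the three clinical outcomes (gestation
#' at delivery, scan-to-delivery interval, ROM-to-scan interval). Raw p
#' values are reported with both conventional significance flags
#' (p < 0.05 and p < 0.005); no multiplicity correction is applied.
#'
#' @param table cohort covariate data.frame
#'   (see [read_cohort_table()] for the column contract)
#' @param summaries data.frame `subject_id, quantity, value` as from
#'   [fit_cohort()]
#' @param out_dir optional directory; when given, each result table is
#'   written as a CSV ('.' decimal, UTF-8) and, if ggplot2 is available and
#'   `plots = TRUE`, one scatter plot per quantity (value vs GA, controls
#'   and PPROM distinguished, control regression line) is saved as PNG
#' @param plots write per-quantity scatter plots (requires ggplot2)
#' @return list of data.frames: `normative`, `zscores`, `group_tests`,
#'   `outcome_regressions`
#' @export
run_cohort_pipeline <- function(table, summaries, out_dir = NULL, plots = FALSE) {
  missing_ids <- setdiff(unique(summaries$subject_id), table$subject_id)
  if (length(missing_ids)) {
    stop("subjects in summaries but absent from the cohort table: ",
         paste(missing_ids, collapse = ", "))
  }
  d <- merge(summaries, table, by = "subject_id")
  quantities <- intersect(tracked_quantities(), unique(d$quantity))

  norm_rows <- list(); z_rows <- list(); grp_rows <- list(); out_rows <- list()
  n_pprom <- sum(table$group == "PPROM")
  if (n_pprom == 0L) {
    warning("no PPROM subjects: group and outcome tables will be empty")
  }

  for (q in quantities) {
    dq <- d[d$quantity == q, ]
    ctl <- dq[dq$group == "control", ]
    nm <- fit_normative(ctl$ga_scan_weeks, ctl$value, quantity = q)
    norm_rows[[q]] <- data.frame(
      quantity = q, slope = nm$slope, intercept = nm$intercept,
      residual_sd = nm$residual_sd, r2 = nm$r2, p_slope = nm$p_slope,
      n_controls = nm$n_controls,
      sig_0.05 = nm$p_slope < 0.05, sig_0.005 = nm$p_slope < 0.005)
    z <- zscore(dq$value, dq$ga_scan_weeks, nm)
    z_rows[[q]] <- data.frame(subject_id = dq$subject_id, group = dq$group,
                              quantity = q, value = dq$value, z = z)
    pp <- dq$group == "PPROM"
    if (sum(pp) >= 2L) {
      gt <- group_difference(z[pp], z[!pp])
      grp_rows[[q]] <- data.frame(
        quantity = q, statistic = gt$statistic, p = gt$p,
        mean_z_pprom = gt$mean_pprom, mean_z_control = gt$mean_control,
        n_pprom = gt$n_pprom, n_control = gt$n_control,
        sig_0.05 = gt$p < 0.05, sig_0.005 = gt$p < 0.005)
    }
    if (sum(pp) >= 3L) {
      outcomes <- c(ga_delivery = "ga_delivery_weeks",
                    scan_to_delivery = "scan_to_delivery_days",
                    rom_to_scan = "rom_to_scan_days")
      for (o in names(outcomes)) {
        ov <- dq[[outcomes[[o]]]][pp]
        if (sum(is.finite(z[pp]) & is.finite(ov)) >= 3L) {
          zr <- z_outcome_regression(z[pp], ov, outcome_name = o)
          out_rows[[paste(q, o)]] <- data.frame(
            quantity = q, outcome = o, slope = zr$slope, p = zr$p,
            r2 = zr$r2, n = zr$n, n_dropped = zr$n_dropped,
            sig_0.05 = zr$p < 0.05, sig_0.005 = zr$p < 0.005)
        }
      }
    }
  }

  empty <- function(...) data.frame(...)[0, , drop = FALSE]
  res <- list(
    normative = do.call(rbind, c(norm_rows, list(make.row.names = FALSE))),
    zscores = do.call(rbind, c(z_rows, list(make.row.names = FALSE))),
    group_tests = if (length(grp_rows))
      do.call(rbind, c(grp_rows, list(make.row.names = FALSE)))
      else empty(quantity = character(), statistic = numeric(), p = numeric()),
    outcome_regressions = if (length(out_rows))
      do.call(rbind, c(out_rows, list(make.row.names = FALSE)))
      else empty(quantity = character(), outcome = character(), slope = numeric(),
                 p = numeric()))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(res)) {
      utils::write.csv(res[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE, na = "")
    }
    if (plots) plot_cohort_quantities(d, res$normative, out_dir)
  }
  res
}

# One scatter per quantity: value vs GA, control regression line overlaid
plot_cohort_quantities <- function(d, normative, out_dir) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    warning("ggplot2 not available; skipping plots")
    return(invisible(NULL))
  }
  for (q in normative$quantity) {
    dq <- d[d$quantity == q, ]
    nr <- normative[normative$quantity == q, ]
    p <- ggplot2::ggplot(dq, ggplot2::aes(x = ga_scan_weeks, y = value,
                                          colour = group, shape = group)) +
      ggplot2::geom_point(size = 2) +
      ggplot2::geom_abline(slope = nr$slope, intercept = nr$intercept,
                           colour = "darkgreen") +
      ggplot2::scale_colour_manual(values = c(control = "blue", PPROM = "red")) +
      ggplot2::scale_shape_manual(values = c(control = 15, PPROM = 16)) +
      ggplot2::labs(x = "Gestational age at scan (weeks)", y = q,
                    title = paste0(q, ": control trend ",
                                   sprintf("%.3g units/week", nr$slope))) +
      ggplot2::theme_minimal()
    ggplot2::ggsave(file.path(out_dir, paste0("scatter_", q, ".png")), p,
                    width = 6, height = 4, dpi = 120)
  }
  invisible(NULL)
}

#' Run the full simulate-fit-analyse demonstration
#'
#' Generates a small seeded two-group cohort (default 20 controls + 8 PPROM,
#' 100 voxels each), fits all three models, runs the cohort statistics, and
#' writes the full results tree (cohort CSV, per-subject ROI summaries,
#' statistics tables, provenance JSON) under `out_dir`. Deterministic: the
#' same seed reproduces the tree.
#'
#' @param out_dir output directory; must not already contain results unless
#'   `force = TRUE`
#' @param seed integer seed for the whole run
#' @param n_control,n_pprom,n_voxels cohort size knobs
#' @param force overwrite an existing non-empty `out_dir`
#' @return (invisibly) the [run_cohort_pipeline()] result list
#' @export
run_demo <- function(out_dir, seed = 7L, n_control = 20L, n_pprom = 8L,
                     n_voxels = 100L, force = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !force) {
    stop("output directory ", out_dir, " is not empty; use force = TRUE")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  spec <- cohort_spec(n_control = n_control, n_pprom = n_pprom,
                      n_voxels = n_voxels, models = c("mono", "t2s_ivim"),
                      seed = seed)
  cohort <- make_cohort(spec)
  write_cohort_table(cohort$table, file.path(out_dir, "cohort.csv"))
  cfg <- fit_config(seed = seed)
  summaries <- fit_cohort(cohort, cfg = cfg)
  utils::write.csv(summaries, file.path(out_dir, "roi_summaries.csv"),
                   row.names = FALSE)
  res <- run_cohort_pipeline(cohort$table, summaries,
                             out_dir = file.path(out_dir, "stats"))
  prov <- list(package = "t2sivim",
               version = as.character(utils::packageVersion("t2sivim")),
               seed = seed,
               spec = spec[setdiff(names(spec), "trends")],
               trends = spec$trends,
               fit_config = cfg[setdiff(names(cfg), "init_override")],
               timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}
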