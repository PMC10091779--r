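#' ROI summary of a parameter map
#'
#' Summarises the finite, in-mask voxels of a fitted map. The study summary
#' is the ROI mean; the median is offered for robustness. Voxels flagged by
#' the fit (bound hits, degenerate fits) are included by default and can be
#' excluded.
#'
#' @param map a [parameter_map()] (or a plain 3D array)
#' @param mask an [roi_mask()]
#' @param stat `"mean"` or `"median"`
#' @param exclude_flagged drop voxels with `fit_ok = FALSE` (only for
#'   `parameter_map` input)
#' @return scalar summary value
#' @export
roi_summary <- function(map, mask, stat = c("mean", "median"),
                        exclude_flagged = FALSE) {
  stat <- match.arg(stat)
  stopifnot(inherits(mask, "roi_mask"))
  m <- unclass(mask)
  if (inherits(map, "parameter_map")) {
    vals <- map$data[m]
    if (exclude_flagged) vals <- vals[map$fit_ok[m]]
  } else {
    vals <- unclass(map)[m]
  }
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0L) stop("no finite voxels in mask for ROI summary")
  if (stat == "mean") mean(vals) else stats::median(vals)
}

#' Fit a normative gestational-age regression on controls
#'
#' Ordinary least squares of an ROI quantity against gestational age at
#' scan over the control cohort, giving slope, intercept, the two-sided
#' slope p-value, R2, and the homoscedastic residual SD
#' `sqrt(RSS / (n - 2))` that scales the cross-sectional z-scores.
#'
#' @param ga numeric vector of gestational ages (weeks)
#' @param value numeric vector of ROI values, same length
#' @param quantity optional label carried into the result
#' @return list of class `normative_model`: `quantity`, `slope`,
#'   `intercept`, `residual_sd`, `r2`, `p_slope`, `n_controls`
#' @export
fit_normative <- function(ga, value, quantity = NA_character_) {
  ok <- is.finite(ga) & is.finite(value)
  ga <- ga[ok]; value <- value[ok]
  n <- length(ga)
  if (n < 3L) stop("normative regression needs >= 3 control subjects")
  if (length(unique(ga)) < 2L) stop("control gestational ages are all identical")
  fit <- stats::lm(value ~ ga)
  sm <- summary(fit)
  structure(list(quantity = quantity,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 residual_sd = sm$sigma,
                 r2 = sm$r.squared,
                 p_slope = unname(sm$coefficients[2, 4]),
                 n_controls = n),
            class = "normative_model")
}

#' @export
print.normative_model <- function(x, ...) {
  cat(sprintf("Normative model%s: value = %.4g %+.4g * GA (weeks), sd %.4g, R2 %.3f, p %.3g, n %d\n",
              if (is.na(x$quantity)) "" else paste0(" [", x$quantity, "]"),
              x$intercept, x$slope, x$residual_sd, x$r2, x$p_slope, x$n_controls))
  invisible(x)
}

#' Cross-sectional z-score against a normative model
#'
#' `z = (value - (intercept + slope * GA)) / residual_sd`: the deviation of
#' a subject from the control GA trend in units of the control residual SD
#' (the DeVore cross-sectional construction with a single homoscedastic SD).
#'
#' @param value observed ROI value(s)
#' @param ga gestational age(s) at scan, weeks
#' @param model a [fit_normative()] result
#' @return z-score(s)
#' @export
zscore <- function(value, ga, model) {
  stopifnot(inherits(model, "normative_model"))
  (value - (model$intercept + model$slope * ga)) / model$residual_sd
}

#' Group comparison of z-scores
#'
#' Two-sided Welch two-sample t-test between the PPROM and control z-score
#' distributions of one quantity.
#'
#' @param z_pprom,z_control numeric z-score vectors (each length >= 2)
#' @return list: `statistic`, `p`, `df`, group means and sizes
#' @export
group_difference <- function(z_pprom, z_control) {
  z_pprom <- z_pprom[is.finite(z_pprom)]
  z_control <- z_control[is.finite(z_control)]
  if (length(z_pprom) < 2L || length(z_control) < 2L) {
    stop("group comparison needs >= 2 subjects per group")
  }
  tt <- stats::t.test(z_pprom, z_control)
  list(statistic = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter),
       mean_pprom = mean(z_pprom), mean_control = mean(z_control),
       n_pprom = length(z_pprom), n_control = length(z_control))
}

#' Regress PPROM z-scores on a clinical outcome
#'
#' OLS of one quantity's z-scores on a clinical measure (gestation at
#' delivery, scan-to-delivery interval, or ROM-to-scan interval), computed
#' on PPROM subjects only. Subjects with a missing outcome are dropped with
#' a message.
#'
#' @param z numeric z-scores of the PPROM subjects
#' @param outcome numeric outcome values, same length
#' @param outcome_name label carried into the result
#' @return list: `slope`, `intercept`, `p`, `r2`, `n`, `n_dropped`
#' @export
z_outcome_regression <- function(z, outcome, outcome_name = NA_character_) {
  stopifnot(length(z) == length(outcome))
  ok <- is.finite(z) & is.finite(outcome)
  n_drop <- sum(!ok)
  if (n_drop > 0) message(n_drop, " subject(s) dropped for missing ", outcome_name)
  z <- z[ok]; outcome <- outcome[ok]
  if (length(z) < 3L) stop("outcome regression needs >= 3 subjects with data")
  fit <- stats::lm(z ~ outcome)
  sm <- summary(fit)
  list(outcome = outcome_name,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       p = unname(sm$coefficients[2, 4]),
       r2 = sm$r.squared, n = length(z), n_dropped = n_drop)
}
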