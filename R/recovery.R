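#' Slope-recovery experiment on a synthetic control cohort
#'
#' The package's core validation loop: simulate a control cohort whose ROI
#' quantity follows the generator's linear gestational-age trend, push every
#' subject's voxel signals through the voxelwise fit and ROI summary, refit
#' the normative regression, and compare the recovered slope with the
#' generating one. Because no imaging data accompany the published normative
#' table, this recovery — with the published slopes as ground truth — is how
#' the pipeline is validated end to end.
#'
#' @param quantity one or more of [tracked_quantities()], all belonging to
#'   the same signal model (the run is shared across them)
#' @param ga_range GA-at-scan range for the simulated controls, weeks
#' @param n_control number of control subjects
#' @param n_voxels ROI voxels per subject
#' @param snr S0-to-noise-SD ratio of the Rician noise
#' @param seed integer seed for the whole experiment
#' @param trends trend table (defaults to [default_trends()])
#' @param cfg a [fit_config()]; its seed is taken from `seed`
#' @param stat ROI summary statistic
#' @return data.frame with one row per quantity: `quantity`, `slope_true`
#'   (generator), `slope_recovered` (refit), `slope_error`, `r2`,
#'   `residual_sd`, `n_control`
#' @export
slope_recovery <- function(quantity, ga_range = c(20, 38), n_control = 60L,
                           n_voxels = 200L, snr = 50, seed = 1L,
                           trends = default_trends(), cfg = NULL,
                           stat = "mean") {
  model <- unique(vapply(quantity, function(q)
    switch(sub("_.*", "", q), mege = "mono", t2sadc = "t2s_adc",
           ivim = "t2s_ivim", stop("unknown quantity: ", q)), ""))
  if (length(model) != 1L) stop("all quantities must share one signal model")
  spec <- cohort_spec(n_control = n_control, n_pprom = 0L,
                      ga_range_control = ga_range, models = model,
                      trends = trends, snr = snr, n_voxels = n_voxels,
                      seed = seed)
  cohort <- make_cohort(spec)
  if (is.null(cfg)) cfg <- fit_config(seed = seed)
  summaries <- fit_cohort(cohort, fit_models = model, cfg = cfg, stat = stat)
  rows <- lapply(quantity, function(q) {
    sq <- summaries[summaries$quantity == q, ]
    ga <- cohort$table$ga_scan_weeks[match(sq$subject_id, cohort$table$subject_id)]
    nm <- fit_normative(ga, sq$value, quantity = q)
    truth <- trends$slope[trends$quantity == q]
    data.frame(quantity = q, slope_true = truth, slope_recovered = nm$slope,
               slope_error = nm$slope - truth, r2 = nm$r2,
               residual_sd = nm$residual_sd, n_control = n_control)
  })
  do.call(rbind, rows)
}
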