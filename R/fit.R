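#' Fitting configuration
#'
#' Bounds, initialization and multistart settings shared by all voxelwise
#' fits. Bounds follow placental-imaging convention: T2* quantities in
#' `[5, 500]` ms, tissue ADC in `[0.05, 4]` 1e-3 mm2/s, pseudo-diffusivity
#' D* in `[3, 500]` 1e-3 mm2/s (the D* and ADC ranges overlap on purpose;
#' compartment ordering `dstar > adc_slow` is enforced post hoc by label
#' swap, not by the bounds), f in `[0, 1]`, and S0 in
#' `(0, s0_max_factor * max(signal)]`.
#'
#' @param t2star_bounds,adc_bounds,dstar_bounds,f_bounds numeric length-2
#'   lower/upper bounds
#' @param s0_max_factor upper S0 bound as a multiple of the largest observed
#'   signal
#' @param n_multistart number of jittered restarts of the joint fit
#' @param jitter multiplicative jitter half-width on initial values
#' @param tolerance RSS below which further restarts are skipped
#' @param b_threshold b-value (s/mm2) above which the perfusion compartment
#'   is taken as fully attenuated during segmented initialization
#' @param seed integer seed driving the multistart jitter
#' @param init_override optional named list of start values replacing the
#'   data-driven initialization (used e.g. to probe label permutations)
#' @return a list of class `fit_config`
#' @export
fit_config <- function(t2star_bounds = c(5, 500),
                       adc_bounds = c(0.05, 4),
                       dstar_bounds = c(3, 500),
                       f_bounds = c(0, 1),
                       s0_max_factor = 10,
                       n_multistart = 5L,
                       jitter = 0.2,
                       tolerance = 1e-10,
                       b_threshold = 200,
                       seed = 1L,
                       init_override = NULL) {
  chk <- function(b, nm) if (!(length(b) == 2L && b[1] < b[2]))
    stop(nm, " bounds must be ordered low < high")
  chk(t2star_bounds, "t2star"); chk(adc_bounds, "adc")
  chk(dstar_bounds, "dstar"); chk(f_bounds, "f")
  structure(list(t2star_bounds = t2star_bounds, adc_bounds = adc_bounds,
                 dstar_bounds = dstar_bounds, f_bounds = f_bounds,
                 s0_max_factor = s0_max_factor,
                 n_multistart = as.integer(n_multistart), jitter = jitter,
                 tolerance = tolerance, b_threshold = b_threshold,
                 seed = as.integer(seed), init_override = init_override),
            class = "fit_config")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# log-linear slope/intercept of log(y) against x, robust to nonpositive y
loglin <- function(x, y) {
  ok <- is.finite(y) & y > 0
  if (sum(ok) < 2L || length(unique(x[ok])) < 2L) return(NULL)
  cf <- stats::lm.fit(cbind(1, x[ok]), log(y[ok]))$coefficients
  list(intercept = cf[[1]], slope = cf[[2]])
}

AT_BOUND_TOL <- 1e-6  # relative closeness to a bound that flags a fit

near_bound <- function(x, bounds) {
  span <- bounds[2] - bounds[1]
  (x - bounds[1]) < AT_BOUND_TOL * span || (bounds[2] - x) < AT_BOUND_TOL * span
}

# Bounded Levenberg-Marquardt wrapper returning par/rss/converged
lm_fit <- function(par0, fn, jac, lower, upper) {
  par0 <- clamp(par0, lower, upper)
  res <- tryCatch(
    minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                       fn = fn, jac = jac,
                       control = minpack.lm::nls.lm.control(
                         ftol = 1e-12, ptol = 1e-12, maxiter = 200)),
    error = function(e) NULL)
  if (is.null(res)) return(NULL)
  list(par = res$par, rss = sum(res$fvec^2), info = res$info)
}

#' Fit the mono-exponential T2* model
#'
#' Least-squares fit of `s0 * exp(-TE / t2star)` over absolute echo time
#' (so `s0` is proton density), initialized by log-linear regression and
#' refined by bounded Levenberg-Marquardt. A fit whose T2* lands on a bound
#' (e.g. a non-decaying signal pushed to the upper bound) is returned
#' clipped with `converged = FALSE`.
#'
#' @param signal numeric vector of magnitudes, one per scheme point
#' @param scheme `acq_scheme` (b = 0 throughout; only TEs are used)
#' @param cfg a [fit_config()]
#' @return list of class `fit_result`: `params` (s0, t2star), `rss`,
#'   `n_points`, `converged`, `init_used`
#' @export
fit_monoexp <- function(signal, scheme, cfg = fit_config()) {
  stopifnot(inherits(scheme, "acq_scheme"), length(signal) == nrow(scheme))
  te <- scheme$te_ms
  if (length(unique(te)) < 2L) stop("mono-exponential fit needs >= 2 distinct TEs")
  tb <- cfg$t2star_bounds
  s0b <- c(1e-12, cfg$s0_max_factor * max(signal, 1e-12))
  ll <- loglin(te, signal)
  if (is.null(ll) || ll$slope >= 0) {
    init <- c(s0 = max(signal, 1e-12), t2star = tb[2])
  } else {
    init <- c(s0 = clamp(exp(ll$intercept), s0b[1], s0b[2]),
              t2star = clamp(-1 / ll$slope, tb[1], tb[2]))
  }
  fn <- function(p) p[1] * exp(-te / p[2]) - signal
  jac <- function(p) {
    e <- exp(-te / p[2])
    cbind(e, p[1] * e * te / p[2]^2)
  }
  res <- lm_fit(init, fn, jac, lower = c(s0b[1], tb[1]), upper = c(s0b[2], tb[2]))
  if (is.null(res)) {
    return(fit_result(list(s0 = init[[1]], t2star = init[[2]]),
                      rss = sum(fn(init)^2), n_points = length(signal),
                      converged = FALSE, init_used = init))
  }
  flagged <- near_bound(res$par[2], tb)
  fit_result(list(s0 = res$par[[1]], t2star = res$par[[2]]), rss = res$rss,
             n_points = length(signal), converged = !flagged, init_used = init)
}

fit_result <- function(params, rss, n_points, converged, init_used,
                       degenerate = FALSE) {
  structure(list(params = params, rss = rss, n_points = n_points,
                 converged = converged, degenerate = degenerate,
                 init_used = init_used),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Fit over", x$n_points, "points; RSS", format(x$rss, digits = 4),
      if (!x$converged) "(flagged)" else "", "\n")
  print(unlist(x$params))
  invisible(x)
}

# shared precondition for the TE+b models
check_te_b <- function(scheme, min_b_levels) {
  if (length(unique(scheme$te_ms)) < 2L)
    stop("fit needs >= 2 distinct echo times (TE axis deficient)")
  if (length(unique(scheme$b_s_mm2)) < min_b_levels)
    stop("fit needs >= ", min_b_levels, " distinct b-values (b axis deficient)")
}

#' Fit the T2*-ADC model
#'
#' Bounded nonlinear least squares of the single-compartment joint decay
#' `S0 * exp(-(TE - TEmin)/T2*) * exp(-b * ADC)`. Initialization: T2* from a
#' log-linear fit over TE at the lowest b; ADC from a log-linear fit over b
#' at the lowest TE; S0 from the (TEmin, bmin) sample. Intended for
#' direction-averaged input.
#'
#' @inheritParams fit_monoexp
#' @return `fit_result` with params `s0`, `t2star`, `adc` (1e-3 mm2/s)
#' @export
fit_t2s_adc <- function(signal, scheme, cfg = fit_config()) {
  stopifnot(inherits(scheme, "acq_scheme"), length(signal) == nrow(scheme))
  check_te_b(scheme, 2L)
  fit_eq1_engine(signal, scheme, cfg)
}

# Eq.1 engine on an arbitrary subset (also used by the segmented IVIM init)
fit_eq1_engine <- function(signal, scheme, cfg) {
  te <- scheme$te_ms; b <- scheme$b_s_mm2
  dte <- te - te_min(scheme)
  tb <- cfg$t2star_bounds; ab <- cfg$adc_bounds
  s0b <- c(1e-12, cfg$s0_max_factor * max(signal, 1e-12))

  at_bmin <- b == min(b)
  at_temin <- te == min(te)
  ll_te <- loglin(dte[at_bmin], signal[at_bmin])
  ll_b <- loglin(b[at_temin], signal[at_temin])
  t2s0 <- if (!is.null(ll_te) && ll_te$slope < 0) -1 / ll_te$slope else mean(tb)
  adc0 <- if (!is.null(ll_b) && ll_b$slope < 0) -ll_b$slope * 1e3 else mean(ab)
  s00 <- max(signal[at_bmin & at_temin][1], 1e-12)
  init <- c(s0 = clamp(s00, s0b[1], s0b[2]), t2star = clamp(t2s0, tb[1], tb[2]),
            adc = clamp(adc0, ab[1], ab[2]))

  fn <- function(p) p[1] * exp(-dte / p[2] - b * p[3] * 1e-3) - signal
  jac <- function(p) {
    e <- exp(-dte / p[2] - b * p[3] * 1e-3)
    cbind(e, p[1] * e * dte / p[2]^2, -p[1] * e * b * 1e-3)
  }
  res <- lm_fit(init, fn, jac,
                lower = c(s0b[1], tb[1], ab[1]), upper = c(s0b[2], tb[2], ab[2]))
  if (is.null(res)) {
    return(fit_result(as.list(init), rss = sum(fn(init)^2),
                      n_points = length(signal), converged = FALSE,
                      init_used = init))
  }
  flagged <- near_bound(res$par[2], tb) || near_bound(res$par[3], ab)
  fit_result(list(s0 = res$par[[1]], t2star = res$par[[2]], adc = res$par[[3]]),
             rss = res$rss, n_points = length(signal), converged = !flagged,
             init_used = init)
}

#' Fit the two-compartment T2*-IVIM model
#'
#' Three-stage procedure:
#' 1. Segmented initialization: the T2*-ADC model is fitted to the
#'    high-b subset (`b >= b_threshold`), where the perfusion compartment
#'    is attenuated, giving the slow compartment (T2*slow, ADC) and its
#'    amplitude.
#' 2. The perfusion fraction and (T2*fast, D*) are initialized from the
#'    low-b residual after subtracting the slow compartment.
#' 3. Joint bounded least squares of all six parameters, with
#'    `n_multistart` seeded multiplicative-jitter restarts; the lowest-RSS
#'    solution wins.
#'
#' Compartment labels are then ordered so that the compartment with the
#' larger diffusivity is the fast/perfusion one (`dstar > adc_slow`),
#' swapping labels and replacing f by 1-f if needed. A fit with f pinned at
#' 0 or 1 is flagged `degenerate`.
#'
#' @inheritParams fit_monoexp
#' @return `fit_result` with params `s0`, `f`, `t2star_fast`,
#'   `t2star_slow`, `dstar`, `adc_slow`
#' @export
fit_t2s_ivim <- function(signal, scheme, cfg = fit_config()) {
  stopifnot(inherits(scheme, "acq_scheme"), length(signal) == nrow(scheme))
  check_te_b(scheme, 3L)
  te <- scheme$te_ms; b <- scheme$b_s_mm2
  dte <- te - te_min(scheme)
  tb <- cfg$t2star_bounds; ab <- cfg$adc_bounds
  db <- cfg$dstar_bounds; fb <- cfg$f_bounds
  s0b <- c(1e-12, cfg$s0_max_factor * max(signal, 1e-12))
  lower <- c(s0b[1], fb[1], tb[1], tb[1], db[1], ab[1])
  upper <- c(s0b[2], fb[2], tb[2], tb[2], db[2], ab[2])

  init <- if (!is.null(cfg$init_override)) {
    with(cfg$init_override, c(s0 = s0, f = f, t2star_fast = t2star_fast,
                              t2star_slow = t2star_slow, dstar = dstar,
                              adc_slow = adc_slow))
  } else {
    ivim_segmented_init(signal, scheme, cfg)
  }
  init <- clamp(init, lower, upper)

  fn <- function(p) {
    ef <- exp(-dte / p[3] - b * p[5] * 1e-3)
    es <- exp(-dte / p[4] - b * p[6] * 1e-3)
    p[1] * (p[2] * ef + (1 - p[2]) * es) - signal
  }
  jac <- function(p) {
    ef <- exp(-dte / p[3] - b * p[5] * 1e-3)
    es <- exp(-dte / p[4] - b * p[6] * 1e-3)
    cbind(p[2] * ef + (1 - p[2]) * es,
          p[1] * (ef - es),
          p[1] * p[2] * ef * dte / p[3]^2,
          p[1] * (1 - p[2]) * es * dte / p[4]^2,
          -p[1] * p[2] * ef * b * 1e-3,
          -p[1] * (1 - p[2]) * es * b * 1e-3)
  }

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)
  best <- NULL
  for (k in seq_len(max(1L, cfg$n_multistart))) {
    start <- if (k == 1L) init else {
      clamp(init * stats::runif(6L, 1 - cfg$jitter, 1 + cfg$jitter), lower, upper)
    }
    res <- lm_fit(start, fn, jac, lower, upper)
    if (!is.null(res) && (is.null(best) || res$rss < best$rss)) best <- res
    if (!is.null(best) && best$rss <= cfg$tolerance) break
  }
  if (is.null(best)) {
    p <- as.list(init)
    names(p) <- c("s0", "f", "t2star_fast", "t2star_slow", "dstar", "adc_slow")
    return(fit_result(p, rss = sum(fn(init)^2), n_points = length(signal),
                      converged = FALSE, init_used = init))
  }
  p <- best$par
  # ordering convention: larger diffusivity is the fast/perfusion compartment
  if (p[5] < p[6]) {
    p <- c(p[1], 1 - p[2], p[4], p[3], p[6], p[5])
  }
  degen <- p[2] <= fb[1] + AT_BOUND_TOL || p[2] >= fb[2] - AT_BOUND_TOL
  params <- list(s0 = p[[1]], f = p[[2]], t2star_fast = p[[3]],
                 t2star_slow = p[[4]], dstar = p[[5]], adc_slow = p[[6]])
  fit_result(params, rss = best$rss, n_points = length(signal),
             converged = TRUE, init_used = init, degenerate = degen)
}

# Stages 1-2: slow compartment from the high-b subset, then f, T2*fast, D*
# from the low-b residual
ivim_segmented_init <- function(signal, scheme, cfg) {
  te <- scheme$te_ms; b <- scheme$b_s_mm2
  dte <- te - te_min(scheme)
  tb <- cfg$t2star_bounds; ab <- cfg$adc_bounds; db <- cfg$dstar_bounds
  hi <- b >= cfg$b_threshold
  if (sum(hi) >= 4L && length(unique(te[hi])) >= 2L && length(unique(b[hi])) >= 2L) {
    sub <- acq_scheme(te[hi], b[hi])
    # shift reference: the subset's TEmin may exceed the full TEmin
    slow <- fit_eq1_engine(signal[hi], sub, cfg)$params
    a_slow <- slow$s0 * exp(-(te_min(sub) - te_min(scheme)) / slow$t2star)
    t2s_slow <- slow$t2star; adc_slow <- slow$adc
  } else {
    a_slow <- 0.7 * max(signal, 1e-12); t2s_slow <- 50; adc_slow <- 1.5
  }
  s_ref <- max(signal[te == min(te) & b == min(b)][1], 1e-12)
  f0 <- clamp(1 - a_slow / s_ref, 0.02, 0.95)
  resid <- signal - a_slow * exp(-dte / t2s_slow - b * adc_slow * 1e-3)
  at_bmin <- b == min(b); at_temin <- te == min(te)
  ll_te <- loglin(dte[at_bmin], resid[at_bmin])
  ll_b <- loglin(b[at_temin], resid[at_temin])
  t2f0 <- if (!is.null(ll_te) && ll_te$slope < 0) -1 / ll_te$slope else 1.5 * t2s_slow
  ds0 <- if (!is.null(ll_b) && ll_b$slope < 0) -ll_b$slope * 1e3 else 30
  c(s0 = s_ref, f = f0,
    t2star_fast = clamp(t2f0, tb[1], tb[2]),
    t2star_slow = clamp(t2s_slow, tb[1], tb[2]),
    dstar = clamp(ds0, max(db[1], adc_slow), db[2]),
    adc_slow = clamp(adc_slow, ab[1], ab[2]))
}

#' Fit one model to every voxel of a signal matrix
#'
#' Workhorse behind [fit_volume()] and the cohort pipeline. Determinism: the
#' multistart stream of voxel i is seeded with `cfg$seed + i`, so results do
#' not depend on evaluation order.
#'
#' @param signals numeric matrix, voxels x scheme points
#' @param scheme the matching `acq_scheme`
#' @param model one of `"mono"`, `"t2s_adc"`, `"t2s_ivim"`
#' @param cfg a [fit_config()]
#' @return data.frame with one row per voxel: fitted parameters plus `rss`,
#'   `converged`, `degenerate`
#' @export
fit_signals <- function(signals, scheme, model = c("mono", "t2s_adc", "t2s_ivim"),
                        cfg = fit_config()) {
  model <- match.arg(model)
  signals <- rbind(signals)
  fitter <- switch(model, mono = fit_monoexp, t2s_adc = fit_t2s_adc,
                   t2s_ivim = fit_t2s_ivim)
  rows <- lapply(seq_len(nrow(signals)), function(i) {
    vcfg <- cfg; vcfg$seed <- cfg$seed + i
    r <- fitter(signals[i, ], scheme, vcfg)
    c(r$params, rss = r$rss, converged = r$converged, degenerate = r$degenerate)
  })
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  rownames(out) <- NULL
  out
}

#' Voxelwise model fitting over a masked volume
#'
#' Fits the chosen model in every mask voxel and assembles one
#' [parameter_map()] per model parameter, plus `rss` and `fit_ok` carried on
#' each map. Voxels outside the mask are NaN.
#'
#' @param img a `multi_contrast_image`
#' @param mask an `roi_mask` on the same grid
#' @param model `"mono"`, `"t2s_adc"` or `"t2s_ivim"`
#' @param cfg a [fit_config()]
#' @return named list of `parameter_map` objects
#' @export
fit_volume <- function(img, mask, model = c("mono", "t2s_adc", "t2s_ivim"),
                       cfg = fit_config()) {
  model <- match.arg(model)
  stopifnot(inherits(img, "multi_contrast_image"), inherits(mask, "roi_mask"))
  if (!identical(dim(img$data)[1:3], dim(unclass(mask)))) {
    stop("image and mask grids differ")
  }
  idx <- which(unclass(mask))
  if (length(idx) == 0L) stop("mask is empty")
  sig <- signals_matrix(img$data)[idx, , drop = FALSE]
  fits <- fit_signals(sig, img$scheme, model, cfg)
  shape <- dim(img$data)[1:3]
  blank <- array(NaN, dim = shape)
  okarr <- array(FALSE, dim = shape)
  okarr[idx] <- fits$converged & !fits$degenerate
  rssarr <- blank; rssarr[idx] <- fits$rss
  pnames <- setdiff(names(fits), c("rss", "converged", "degenerate"))
  maps <- lapply(pnames, function(nm) {
    a <- blank; a[idx] <- fits[[nm]]
    parameter_map(nm, a, okarr, rssarr)
  })
  names(maps) <- pnames
  maps
}
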