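#' Forward signal models
#'
#' Two decay models describe the combined T2*-diffusion signal as a function
#' of echo time TE and diffusion weighting b, both referenced to the lowest
#' acquired echo time TEmin so that S(TEmin, 0) = S0:
#'
#' * T2*-ADC (single compartment):
#'   `S = S0 * exp(-(TE - TEmin)/T2*) * exp(-b * ADC)`
#' * T2*-IVIM (two compartments, fast/perfusing and slow/diffusing):
#'   `S = S0 * ( f * exp(-(TE - TEmin)/T2*fast) * exp(-b * D*)
#'             + (1-f) * exp(-(TE - TEmin)/T2*slow) * exp(-b * ADC) )`
#'
#' Diffusivities are given in 1e-3 mm2/s and b in s/mm2; T2* in ms; f is the
#' perfusion (fast-compartment) signal fraction in `[0, 1]`.
#'
#' @param p named list of parameters (see [eq1_params()] / [eq2_params()])
#' @param scheme an `acq_scheme`
#' @return numeric signal vector, one value per scheme point
#' @name signal_models
NULL

#' Parameters of the T2*-ADC model
#' @param s0 signal at (TEmin, b=0), arbitrary units, > 0
#' @param t2star effective transverse relaxation time, ms, > 0
#' @param adc apparent diffusion coefficient, 1e-3 mm2/s, > 0
#' @return validated named list of class `eq1_params`
#' @export
eq1_params <- function(s0, t2star, adc) {
  stopifnot(s0 > 0, t2star > 0, adc > 0)
  structure(list(s0 = s0, t2star = t2star, adc = adc), class = "eq1_params")
}

#' Parameters of the two-compartment T2*-IVIM model
#' @param s0 signal at (TEmin, b=0), arbitrary units, > 0
#' @param f perfusion fraction in `[0, 1]`
#' @param t2star_fast,t2star_slow T2* of the perfusion / diffusion
#'   compartments, ms, > 0
#' @param dstar pseudo-diffusivity D* (ADC1) of the perfusion compartment,
#'   1e-3 mm2/s
#' @param adc_slow ADC (ADC2) of the diffusion compartment, 1e-3 mm2/s;
#'   by labeling convention `dstar > adc_slow`
#' @return validated named list of class `eq2_params`
#' @export
eq2_params <- function(s0, f, t2star_fast, t2star_slow, dstar, adc_slow) {
  stopifnot(s0 > 0, f >= 0, f <= 1, t2star_fast > 0, t2star_slow > 0,
            dstar > 0, adc_slow > 0)
  structure(list(s0 = s0, f = f, t2star_fast = t2star_fast,
                 t2star_slow = t2star_slow, dstar = dstar,
                 adc_slow = adc_slow), class = "eq2_params")
}

#' @rdname signal_models
#' @export
signal_eq1 <- function(p, scheme) {
  stopifnot(inherits(scheme, "acq_scheme"))
  dte <- scheme$te_ms - te_min(scheme)
  p$s0 * exp(-dte / p$t2star) * exp(-scheme$b_s_mm2 * p$adc * 1e-3)
}

#' @rdname signal_models
#' @export
signal_eq2 <- function(p, scheme) {
  stopifnot(inherits(scheme, "acq_scheme"))
  dte <- scheme$te_ms - te_min(scheme)
  b <- scheme$b_s_mm2
  p$s0 * (p$f * exp(-dte / p$t2star_fast) * exp(-b * p$dstar * 1e-3) +
          (1 - p$f) * exp(-dte / p$t2star_slow) * exp(-b * p$adc_slow * 1e-3))
}

#' Mono-exponential gradient-echo signal
#'
#' Decay over absolute TE (not TE - TEmin), as fitted on the multi-echo
#' gradient-echo series, so that `s0` is proton density.
#' @param s0 proton density (a.u.)
#' @param t2star ms
#' @inheritParams signal_models
#' @return signal vector
#' @export
signal_mono <- function(s0, t2star, scheme) {
  stopifnot(inherits(scheme, "acq_scheme"))
  s0 * exp(-scheme$te_ms / t2star)
}

#' Add Rician noise to magnitude signals
#'
#' Magnitude MRI noise: each sample is replaced by
#' `sqrt((s + n1)^2 + n2^2)` with `n1, n2 ~ Normal(0, sigma^2)`.
#' Deterministic given `seed`; `sigma = 0` returns the input unchanged.
#'
#' @param signal numeric vector/array of noise-free magnitudes
#' @param sigma Gaussian noise SD per channel (>= 0), same units as signal
#' @param seed integer seed; if NULL the current RNG stream is used
#' @return noisy magnitudes, same shape as `signal`
#' @export
add_rician_noise <- function(signal, sigma, seed = NULL) {
  if (length(sigma) != 1L || !is.finite(sigma) || sigma < 0) {
    stop("sigma must be a single finite value >= 0")
  }
  if (sigma == 0) return(signal)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(as.integer(seed))
  }
  n <- length(signal)
  noisy <- sqrt((signal + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
  if (!is.null(dim(signal))) dim(noisy) <- dim(signal)
  noisy
}
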