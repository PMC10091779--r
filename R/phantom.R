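#' Lobule-structured placental phantom
#'
#' Builds a 3D digital phantom emulating the lobular organisation of the
#' placenta: an ellipsoidal parenchymal ROI containing `n_lobules` lobules.
#' The perfusion fraction equals `params_center$f` at each lobule seed point
#' (where the spiral-artery inflow makes the perfusion compartment dominate)
#' and falls off with a Gaussian radial profile to `params_periphery$f` in
#' the inter-lobule septa; every other model parameter is interpolated
#' linearly with the same weight. Voxel signals follow the two-compartment
#' T2*-IVIM model plus Rician noise.
#'
#' @param shape integer length-3 grid size (each >= 16)
#' @param n_lobules number of lobule seed points (>= 1)
#' @param params_center,params_periphery [eq2_params()] at the lobule
#'   centers / in the septa
#' @param scheme `acq_scheme` used to synthesise the signals
#' @param sigma Rician noise SD (0 = noiseless)
#' @param seed integer seed (lobule placement and noise)
#' @param lobule_radius Gaussian falloff SD in voxels (default shape[1]/8)
#' @return list: `image` (`multi_contrast_image`), `mask` (`roi_mask`),
#'   `truth` (named list of ground-truth 3D parameter arrays, NaN outside
#'   the ROI)
#' @export
make_phantom <- function(shape = c(24, 24, 16), n_lobules = 3,
                         params_center = eq2_params(100, 0.6, 120, 50, 40, 1.5),
                         params_periphery = eq2_params(100, 0.1, 120, 50, 40, 1.5),
                         scheme = build_paper_scheme(), sigma = 0, seed = 1,
                         lobule_radius = NULL) {
  stopifnot(length(shape) == 3L)
  if (any(shape < 16L)) stop("phantom shape must be at least 16 voxels per axis")
  if (n_lobules < 1L) stop("need at least one lobule")
  if (is.null(lobule_radius)) lobule_radius <- shape[1] / 8

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  ctr <- (shape + 1) / 2
  semi <- shape / 2 - 1.5
  g <- expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]), z = seq_len(shape[3]))
  inside <- ((g$x - ctr[1]) / semi[1])^2 + ((g$y - ctr[2]) / semi[2])^2 +
            ((g$z - ctr[3]) / semi[3])^2 <= 1
  if (!any(inside)) stop("ROI is empty for the given shape")
  mask <- roi_mask(array(as.numeric(inside), dim = shape))

  # Poisson-disk-style seeds: rejection sampling with a minimum separation
  roi_xyz <- as.matrix(g[inside, ])
  min_sep <- 2.5 * lobule_radius
  seeds <- matrix(NA_real_, 0, 3)
  tries <- 0
  while (nrow(seeds) < n_lobules && tries < 5000) {
    cand <- roi_xyz[sample(nrow(roi_xyz), 1L), ]
    if (nrow(seeds) == 0L ||
        min(sqrt(rowSums(sweep(seeds, 2, cand)^2))) >= min_sep) {
      seeds <- rbind(seeds, cand)
    }
    tries <- tries + 1
  }
  if (nrow(seeds) < n_lobules) {
    # dense packing fallback: accept closest-packed candidates
    extra <- roi_xyz[sample(nrow(roi_xyz), n_lobules - nrow(seeds)), , drop = FALSE]
    seeds <- rbind(seeds, extra)
  }

  # weight w = max over seeds of exp(-d^2 / (2 r^2)): 1 at a seed, -> 0 far away
  w <- rep(0, nrow(g))
  for (i in seq_len(nrow(seeds))) {
    d2 <- (g$x - seeds[i, 1])^2 + (g$y - seeds[i, 2])^2 + (g$z - seeds[i, 3])^2
    w <- pmax(w, exp(-d2 / (2 * lobule_radius^2)))
  }

  blend <- function(nm) params_periphery[[nm]] + w * (params_center[[nm]] - params_periphery[[nm]])
  pnames <- c("s0", "f", "t2star_fast", "t2star_slow", "dstar", "adc_slow")
  vox_par <- vapply(pnames, blend, numeric(nrow(g)))

  n_pts <- nrow(scheme)
  dte <- scheme$te_ms - te_min(scheme)
  b <- scheme$b_s_mm2
  sig <- matrix(0, nrow(g), n_pts)
  idx <- which(inside)
  ef <- exp(-outer(1 / vox_par[idx, "t2star_fast"], dte) -
            outer(vox_par[idx, "dstar"] * 1e-3, b))
  es <- exp(-outer(1 / vox_par[idx, "t2star_slow"], dte) -
            outer(vox_par[idx, "adc_slow"] * 1e-3, b))
  sig[idx, ] <- vox_par[idx, "s0"] *
    (vox_par[idx, "f"] * ef + (1 - vox_par[idx, "f"]) * es)
  if (sigma > 0) sig[idx, ] <- add_rician_noise(sig[idx, ], sigma)

  truth <- lapply(pnames, function(nm) {
    a <- array(NaN, dim = shape)
    a[idx] <- vox_par[idx, nm]
    a
  })
  names(truth) <- pnames
  list(image = multi_contrast_image(array(sig, dim = c(shape, n_pts)), scheme),
       mask = mask, truth = truth, seeds = seeds)
}
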