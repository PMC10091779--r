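#' Multi-contrast image container
#'
#' Couples a 4D array of signal magnitudes (X x Y x Z x N) to the
#' `acq_scheme` describing its N volumes. Signals are magnitudes: negative
#' input values are clipped to zero with a warning. The NIfTI header/affine
#' of the source file is carried opaquely and re-attached on write; the
#' package never resamples.
#'
#' @param data 4D numeric array, nonnegative and finite
#' @param scheme `acq_scheme` with `dim(data)[4]` points
#' @param voxel_size numeric length-3, mm (default 3 mm isotropic)
#' @param reference optional RNifti image to take header/affine from
#' @return object of class `multi_contrast_image`
#' @export
multi_contrast_image <- function(data, scheme, voxel_size = c(3, 3, 3),
                                 reference = NULL) {
  stopifnot(inherits(scheme, "acq_scheme"))
  data <- unclass(data)
  if (length(dim(data)) != 4L) stop("image data must be a 4D array")
  if (dim(data)[4] != nrow(scheme)) {
    stop("volume count mismatch: image has ", dim(data)[4],
         " volumes but scheme has ", nrow(scheme), " points")
  }
  if (any(!is.finite(data))) stop("image data must be finite")
  if (any(data < 0)) {
    warning("negative signal magnitudes clipped to 0")
    data[data < 0] <- 0
  }
  structure(list(data = data, scheme = scheme,
                 voxel_size = as.numeric(voxel_size), reference = reference),
            class = "multi_contrast_image")
}

#' @export
print.multi_contrast_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Multi-contrast image %d x %d x %d, %d volumes\n", d[1], d[2], d[3], d[4]))
  print(x$scheme)
  invisible(x)
}

#' Region-of-interest mask
#'
#' A 3D logical array marking the (manually segmented) placental parenchyma.
#'
#' @param data 3D array; values must be 0/1 (or logical) with at least one
#'   voxel set
#' @return object of class `roi_mask` (logical 3D array)
#' @export
roi_mask <- function(data) {
  data <- unclass(data)
  if (length(dim(data)) != 3L) stop("mask must be a 3D array")
  v <- unique(as.vector(data))
  if (!all(v %in% c(0, 1))) {
    stop("mask is not binary: contains values other than 0/1 (found ",
         paste(utils::head(setdiff(v, c(0, 1)), 3), collapse = ", "), ")")
  }
  m <- array(as.logical(data), dim = dim(data))
  if (!any(m)) stop("mask is empty: no voxel set")
  structure(m, class = "roi_mask")
}

#' Fitted parameter map
#'
#' One 3D map of a fitted quantity plus fit diagnostics. Values are NaN
#' outside the mask used for fitting. Units: ms for T2* quantities,
#' 1e-3 mm2/s for diffusivities, dimensionless for f and S0.
#'
#' @param name quantity label
#' @param data 3D numeric array
#' @param fit_ok 3D logical array (TRUE where the fit converged off-bounds)
#' @param rss 3D numeric array of residual sums of squares
#' @return object of class `parameter_map`
#' @export
parameter_map <- function(name, data, fit_ok, rss) {
  stopifnot(length(dim(data)) == 3L,
            identical(dim(data), dim(fit_ok)),
            identical(dim(data), dim(rss)))
  structure(list(name = name, data = data, fit_ok = fit_ok, rss = rss),
            class = "parameter_map")
}

#' Read a 4D NIfTI series against a scheme
#'
#' @param nifti_path path to a `.nii`/`.nii.gz` file with N volumes
#' @param scheme `acq_scheme` with N points
#' @param voxel_size optional override; default taken from the header
#' @return a `multi_contrast_image`
#' @export
read_image <- function(nifti_path, scheme, voxel_size = NULL) {
  img <- RNifti::readNifti(nifti_path)
  d <- dim(img)
  if (length(d) != 4L) stop("expected a 4D NIfTI, got ", length(d), "D: ", nifti_path)
  if (d[4] != nrow(scheme)) {
    stop("volume count mismatch: ", nifti_path, " has ", d[4],
         " volumes but scheme has ", nrow(scheme), " points")
  }
  if (is.null(voxel_size)) voxel_size <- RNifti::pixdim(img)[1:3]
  multi_contrast_image(array(as.numeric(img), dim = d), scheme,
                       voxel_size = voxel_size, reference = img)
}

#' Read a 3D binary mask
#' @param nifti_path path to a NIfTI mask (values 0/1)
#' @return an `roi_mask`
#' @export
read_mask <- function(nifti_path) {
  img <- RNifti::readNifti(nifti_path)
  if (length(dim(img)) != 3L) stop("expected a 3D mask NIfTI: ", nifti_path)
  roi_mask(array(as.numeric(img), dim = dim(img)))
}

#' Write a parameter map (or any 3D/4D array) as NIfTI
#'
#' The affine/header of `reference` (e.g. the input image) is preserved when
#' given; otherwise a default header with `voxel_size` is used.
#'
#' @param map a `parameter_map`, or a plain array
#' @param nifti_path output path
#' @param reference optional RNifti image or `multi_contrast_image`
#' @param voxel_size mm triplet used when no reference is available
#' @return `nifti_path`, invisibly
#' @export
write_map <- function(map, nifti_path, reference = NULL, voxel_size = c(3, 3, 3)) {
  arr <- if (inherits(map, "parameter_map")) map$data else unclass(map)
  ref <- reference
  if (inherits(ref, "multi_contrast_image")) ref <- ref$reference
  if (!is.null(ref)) {
    img <- RNifti::asNifti(arr, reference = ref)
  } else {
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- c(voxel_size, rep(1, length(dim(arr)) - 3L))
  }
  RNifti::writeNifti(img, nifti_path)
  invisible(nifti_path)
}

#' Average signals across gradient directions
#'
#' The decay models are isotropic in b, so multiple directions acquired on
#' the same (TE, b) shell are pooled by arithmetic mean before fitting. The
#' output scheme has one point per unique (TE, b) pair, in order of TE then
#' b, with a zeroed direction. Idempotent.
#'
#' @param img a `multi_contrast_image`
#' @return a `multi_contrast_image` on the collapsed scheme
#' @export
direction_average <- function(img) {
  stopifnot(inherits(img, "multi_contrast_image"))
  sig <- signals_matrix(img$data)
  avg <- direction_average_signals(sig, img$scheme)
  d <- dim(img$data)
  multi_contrast_image(array(avg$signals, dim = c(d[1:3], ncol(avg$signals))),
                       avg$scheme, voxel_size = img$voxel_size,
                       reference = img$reference)
}

#' @rdname direction_average
#' @param signals numeric matrix, voxels x points (columns follow `scheme`)
#' @param scheme the `acq_scheme` of the columns
#' @return for the matrix form, a list with elements `signals` (voxels x
#'   unique pairs) and `scheme`
#' @export
direction_average_signals <- function(signals, scheme) {
  signals <- rbind(signals)  # tolerate a single-voxel vector
  stopifnot(ncol(signals) == nrow(scheme))
  key <- paste(scheme$te_ms, scheme$b_s_mm2)
  ord <- order(scheme$te_ms, scheme$b_s_mm2)
  ukey <- unique(key[ord])
  grp <- match(key, ukey)
  n <- tabulate(grp, nbins = length(ukey))
  pooled <- signals %*% outer(grp, seq_along(ukey), "==") %*% diag(1 / n, length(ukey))
  first <- match(ukey, key)
  list(signals = pooled,
       scheme = acq_scheme(scheme$te_ms[first], scheme$b_s_mm2[first]))
}

# 4D array -> voxels x points matrix (voxel order = R array order)
signals_matrix <- function(arr4d) {
  d <- dim(arr4d)
  matrix(arr4d, nrow = prod(d[1:3]), ncol = d[4])
}
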