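#' Acquisition schemes for combined T2*-diffusion imaging
#'
#' An acquisition scheme is an ordered table with one row per acquired 4D
#' volume, giving the echo time (ms), the diffusion weighting b (s/mm2) and
#' the unit gradient direction. It is the coordinate system of every signal
#' vector in the package: element i of a signal always corresponds to row i
#' of the scheme.
#'
#' @param te_ms numeric vector of echo times, ms (> 0)
#' @param b_s_mm2 numeric vector of b-values, s/mm2 (>= 0)
#' @param dirs numeric matrix (n x 3) of gradient directions; rows with
#'   b > 0 must be unit vectors, rows with b = 0 are stored as zeros
#' @return an object of class `acq_scheme`: a data.frame with columns
#'   `te_ms`, `b_s_mm2`, `gx`, `gy`, `gz` and attribute `te_min_ms`
#' @export
acq_scheme <- function(te_ms, b_s_mm2, dirs = NULL) {
  n <- length(te_ms)
  if (n < 2L) stop("an acquisition scheme needs at least 2 points")
  if (length(b_s_mm2) != n) stop("te_ms and b_s_mm2 lengths differ")
  if (any(!is.finite(te_ms)) || any(te_ms <= 0)) stop("all echo times must be finite and > 0")
  if (any(!is.finite(b_s_mm2)) || any(b_s_mm2 < 0)) stop("all b-values must be finite and >= 0")
  if (is.null(dirs)) dirs <- matrix(0, n, 3L)
  dirs <- as.matrix(dirs)
  if (nrow(dirs) != n || ncol(dirs) != 3L) stop("dirs must be an n x 3 matrix")
  nrm <- sqrt(rowSums(dirs^2))
  dwi <- b_s_mm2 >= B0_THRESHOLD
  # b>0 rows carry a unit direction, or a zero vector once pooled across
  # directions (the models are isotropic in b, so the direction may be
  # undefined); anything else is malformed
  if (any(dwi & abs(nrm - 1) > 1e-6 & nrm > 1e-6)) {
    stop("gradient directions must be unit vectors (or zero once averaged) where b > 0")
  }
  dirs[!dwi, ] <- 0
  s <- data.frame(te_ms = as.numeric(unname(te_ms)),
                  b_s_mm2 = as.numeric(unname(b_s_mm2)),
                  gx = unname(dirs[, 1]), gy = unname(dirs[, 2]),
                  gz = unname(dirs[, 3]))
  rownames(s) <- NULL
  attr(s, "te_min_ms") <- min(s$te_ms)
  class(s) <- c("acq_scheme", "data.frame")
  s
}

# b-values below this (s/mm2) count as unweighted b=0 references
B0_THRESHOLD <- 1

#' Minimum echo time of a scheme
#' @param scheme an `acq_scheme`
#' @return TEmin in ms, the reference echo time of the decay models
#' @export
te_min <- function(scheme) {
  stopifnot(inherits(scheme, "acq_scheme"))
  min(scheme$te_ms)
}

#' Which scheme points are b=0 references
#' @param scheme an `acq_scheme`
#' @return logical vector, TRUE where b < 1 s/mm2
#' @export
is_b0 <- function(scheme) scheme$b_s_mm2 < B0_THRESHOLD

#' @export
print.acq_scheme <- function(x, ...) {
  cat(sprintf("Acquisition scheme: %d points, %d TEs (TEmin %.6g ms), %d unique b-values\n",
              nrow(x), length(unique(x$te_ms)), te_min(x),
              length(unique(x$b_s_mm2))))
  invisible(x)
}

# Deterministic near-uniform unit vectors: golden-spiral points on the sphere.
# Used for the synthetic multi-direction shells; any unit set is acceptable
# because the signal models are isotropic in b.
sphere_dirs <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Number of b=0 reference volumes interleaved per TE in the default protocol.
# The listed diffusion preparations come to 60 per TE; 6 references bring
# each TE block to 66 and the full scheme to 264 points. Overridable.
PAPER_N_B0_PER_TE <- 6L

#' Build the default combined T2*-diffusion acquisition scheme
#'
#' The protocol acquires 4 TEs of 78, 114, 150 and 186 ms. For each TE the
#' diffusion preparations are: 3 directions at each of
#' b = 5, 10, 25, 50, 100, 200, 400, 600, 1200, 1600 s/mm2; 8 directions at
#' b = 18; 7 at b = 36; 15 at b = 800; plus `n_b0` unweighted reference
#' volumes. With the default `n_b0 = 6` each TE block has 66 preparations
#' and the full factorial scheme has 264 points.
#'
#' @param n_b0 integer, number of b=0 volumes per TE (default 6)
#' @return an `acq_scheme` with `4 * (60 + n_b0)` points, TEmin = 78 ms
#' @export
build_paper_scheme <- function(n_b0 = PAPER_N_B0_PER_TE) {
  tes <- c(78, 114, 150, 186)
  shells <- rbind(
    data.frame(b = rep(c(5, 10, 25, 50, 100, 200, 400, 600, 1200, 1600), each = 3),
               idx = rep(1:3, times = 10), ndir = 3),
    data.frame(b = rep(18, 8), idx = 1:8, ndir = 8),
    data.frame(b = rep(36, 7), idx = 1:7, ndir = 7),
    data.frame(b = rep(800, 15), idx = 1:15, ndir = 15))
  dirs <- t(vapply(seq_len(nrow(shells)),
                   function(i) sphere_dirs(shells$ndir[i])[shells$idx[i], ],
                   numeric(3)))
  b <- c(rep(0, n_b0), shells$b)
  d <- rbind(matrix(0, n_b0, 3L), dirs)
  acq_scheme(te_ms = rep(tes, each = length(b)),
             b_s_mm2 = rep(b, times = length(tes)),
             dirs = d[rep(seq_along(b), times = length(tes)), , drop = FALSE])
}

#' Build the multi-echo gradient-echo (MEGE) scheme
#'
#' Five echoes equally spaced from 18 to 159 ms, no diffusion weighting.
#' Used for mono-exponential T2* and proton-density mapping.
#'
#' @param n_te number of echoes (default 5)
#' @param te_first,te_last first and last TE in ms (defaults 18 and 159)
#' @return an `acq_scheme` with all b = 0
#' @export
build_mege_scheme <- function(n_te = 5L, te_first = 18, te_last = 159) {
  acq_scheme(te_ms = seq(te_first, te_last, length.out = n_te),
             b_s_mm2 = rep(0, n_te))
}

#' Read or write an acquisition scheme
#'
#' Two dialects are supported and auto-detected on read:
#' a single CSV with columns `te_ms, b_s_mm2, gx, gy, gz`, or FSL-style
#' `<stem>.bval` / `<stem>.bvec` files plus a `<stem>.te` sidecar holding one
#' TE (ms) per volume. `read_scheme(write_scheme(s, path), ...)` returns `s`
#' to floating-point equality.
#'
#' @param path for the CSV dialect, the `.csv` file; for the FSL dialect,
#'   the stem (with or without `.bval`)
#' @param scheme an `acq_scheme`
#' @param format `"csv"` or `"fsl"` (write only; read auto-detects)
#' @return `read_scheme`: an `acq_scheme`. `write_scheme`: `path`, invisibly.
#' @export
read_scheme <- function(path) {
  if (grepl("\\.csv$", path)) {
    d <- utils::read.csv(path)
    need <- c("te_ms", "b_s_mm2", "gx", "gy", "gz")
    if (!all(need %in% names(d))) {
      stop("scheme CSV ", path, " must have columns ", paste(need, collapse = ", "))
    }
    return(acq_scheme(d$te_ms, d$b_s_mm2, as.matrix(d[, c("gx", "gy", "gz")])))
  }
  stem <- sub("\\.bval$", "", path)
  fb <- paste0(stem, ".bval"); fv <- paste0(stem, ".bvec"); ft <- paste0(stem, ".te")
  for (f in c(fb, fv, ft)) if (!file.exists(f)) stop("scheme file not found: ", f)
  bval <- scan(fb, quiet = TRUE)
  bvec <- as.matrix(utils::read.table(fv))  # FSL layout: 3 rows x n columns
  te <- scan(ft, quiet = TRUE)
  if (nrow(bvec) != 3L) stop("format error in ", fv, ": expected 3 rows of gradient components")
  if (ncol(bvec) != length(bval)) {
    stop("format error: ", fv, " has ", ncol(bvec), " volumes but ", fb, " has ", length(bval))
  }
  if (length(te) != length(bval)) {
    stop("format error: ", ft, " has ", length(te), " volumes but ", fb, " has ", length(bval))
  }
  acq_scheme(te, bval, t(bvec))
}

#' @rdname read_scheme
#' @export
write_scheme <- function(scheme, path, format = c("csv", "fsl")) {
  stopifnot(inherits(scheme, "acq_scheme"))
  format <- match.arg(format)
  fmt <- function(x) sprintf("%.17g", x)  # lossless double -> text
  if (format == "csv") {
    if (!grepl("\\.csv$", path)) path <- paste0(path, ".csv")
    d <- data.frame(te_ms = fmt(scheme$te_ms), b_s_mm2 = fmt(scheme$b_s_mm2),
                    gx = fmt(scheme$gx), gy = fmt(scheme$gy), gz = fmt(scheme$gz))
    utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  } else {
    stem <- sub("\\.bval$", "", path)
    writeLines(paste(fmt(scheme$b_s_mm2), collapse = " "), paste0(stem, ".bval"))
    bvec <- t(as.matrix(scheme[, c("gx", "gy", "gz")]))
    writeLines(apply(bvec, 1, function(r) paste(fmt(r), collapse = " ")),
               paste0(stem, ".bvec"))
    writeLines(paste(fmt(scheme$te_ms), collapse = " "), paste0(stem, ".te"))
  }
  invisible(path)
}
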