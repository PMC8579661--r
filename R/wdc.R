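#' Voxel-wise weighted degree centrality
#'
#' For every in-mask voxel i, the raw weighted degree is the sum of Pearson
#' correlations r_ij with all *other* in-mask voxels j that exceed the
#' threshold (strictly r > threshold; only positive correlations can
#' qualify, and the self-correlation is excluded):
#' \deqn{wDC_i = \sum_{j \ne i,\; r_{ij} > r_0} r_{ij}}
#' The computation is chunked so the full voxel-by-voxel correlation matrix
#' is never materialized: peak extra storage is (voxels x block_size).
#'
#' Voxels with zero temporal variance cannot carry a correlation; they are
#' dropped from the analysis mask (recorded in the `dropped` attribute) and
#' given raw value 0.
#'
#' @param vol a `volume4d` (preprocessed).
#' @param mask logical 3D array (brain mask).
#' @param r_threshold correlation threshold (default 0.25).
#' @param block_size voxels per correlation block (default 2048).
#' @return object of class `wdc_map`: list with `raw` (3D array), `z`
#'   (NULL until [standardize_map()]), `mask`, `affine`, `params`.
#' @export
compute_wdc_raw <- function(vol, mask, r_threshold = 0.25,
                            block_size = 2048L) {
  stopifnot(inherits(vol, "volume4d"))
  d <- dim(vol$data)
  stopifnot(all(dim(mask) == d[1:3]))
  nt <- d[4]
  if (nt < 3L) stop("compute_wdc_raw: need at least 3 time points")
  flat <- matrix(vol$data, nrow = prod(d[1:3]), ncol = nt)
  idx <- which(mask)
  if (length(idx) < 2L) stop("compute_wdc_raw: need >= 2 in-mask voxels")
  Y <- t(flat[idx, , drop = FALSE])                    # t x V
  mu <- colMeans(Y)
  Yc <- sweep(Y, 2L, mu)
  ss <- sqrt(colSums(Yc^2))
  ok <- ss > 0
  if (!any(ok)) stop("compute_wdc_raw: all in-mask voxels are constant")
  dropped <- idx[!ok]
  if (length(dropped)) {
    message("compute_wdc_raw: dropping ", length(dropped),
            " zero-variance voxel(s) from the analysis mask")
  }
  Z <- sweep(Yc[, ok, drop = FALSE], 2L, ss[ok], `/`)  # unit-norm columns
  V <- ncol(Z)
  raw <- numeric(V)
  block_size <- max(1L, as.integer(block_size))
  for (start in seq(1L, V, by = block_size)) {
    cols <- start:min(V, start + block_size - 1L)
    R <- crossprod(Z, Z[, cols, drop = FALSE])         # V x b correlations
    R[R <= r_threshold] <- 0
    raw[cols] <- colSums(R) - 1                        # self r = 1 always passes
  }
  out <- array(0, dim = d[1:3])
  eff_mask <- array(FALSE, dim = d[1:3])
  eff_mask[idx[ok]] <- TRUE
  out[idx[ok]] <- raw
  structure(list(raw = out, z = NULL, mask = eff_mask, affine = vol$affine,
                 params = list(r_threshold = r_threshold,
                               block_size = block_size, fwhm = NULL),
                 dropped = dropped),
            class = "wdc_map")
}

#' @export
print.wdc_map <- function(x, ...) {
  cat("wdc_map:", paste(dim(x$raw), collapse = " x "), "grid,",
      sum(x$mask), "in-mask voxels, r >", x$params$r_threshold,
      if (!is.null(x$z)) "| z-standardized" else "",
      if (!is.null(x$params$fwhm)) paste("| smoothed", x$params$fwhm, "mm") else "",
      "\n")
  invisible(x)
}

#' Z-standardize a wDC map across in-mask voxels
#'
#' @param map a `wdc_map` (raw computed).
#' @param mask optional logical 3D array; defaults to the map's own mask.
#' @return the `wdc_map` with `z` filled: mean 0, sd 1 over the mask;
#'   out-of-mask voxels 0.
#' @export
standardize_map <- function(map, mask = NULL) {
  stopifnot(inherits(map, "wdc_map"))
  if (is.null(mask)) mask <- map$mask
  vals <- map$raw[mask]
  s <- stats::sd(vals)
  if (!is.finite(s) || s == 0) {
    stop("standardize_map: zero variance across in-mask voxels")
  }
  z <- array(0, dim = dim(map$raw))
  z[mask] <- (vals - mean(vals)) / s
  map$z <- z
  map
}

#' Separable 3D Gaussian smoothing
#'
#' Convolves a 3D array with an axis-separable Gaussian whose full width at
#' half maximum is given in millimetres; the per-axis sigma in voxels is
#' FWHM / (2 sqrt(2 ln 2)) / voxel_size, honouring anisotropic voxels.
#' Boundaries use reflection, so a constant image is exactly preserved.
#'
#' @param arr 3D numeric array.
#' @param fwhm_mm kernel FWHM in mm (>= 0; 0 is the identity).
#' @param voxel_size numeric length-3, voxel edges in mm.
#' @return smoothed 3D array.
#' @export
gaussian_smooth3d <- function(arr, fwhm_mm, voxel_size) {
  stopifnot(length(dim(arr)) == 3L, length(voxel_size) == 3L)
  if (fwhm_mm < 0) stop("gaussian_smooth3d: negative FWHM")
  if (fwhm_mm == 0) return(arr)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size
  kern <- lapply(sigma, function(s) {
    r <- max(1L, ceiling(4 * s))
    k <- exp(-(seq(-r, r))^2 / (2 * s^2))
    k / sum(k)
  })
  # fold any integer index into 1..n by symmetric (edge-repeating) reflection
  reflect_index <- function(i, n) {
    j <- (i - 1L) %% (2L * n)
    ifelse(j < n, j + 1L, 2L * n - j)
  }
  conv_axis <- function(a, k, axis) {
    r <- (length(k) - 1L) / 2L
    n <- dim(a)[axis]
    pad <- reflect_index((1L - r):(n + r), n)
    perm <- c(axis, setdiff(1:3, axis))
    ap <- aperm(a, perm)
    dp <- dim(ap)
    m <- matrix(ap, nrow = dp[1])
    mp <- m[pad, , drop = FALSE]
    out <- matrix(0, nrow = n, ncol = ncol(m))
    for (i in seq_along(k)) {
      out <- out + k[i] * mp[i:(i + n - 1L), , drop = FALSE]
    }
    aperm(array(out, dim = dp), order(perm))
  }
  for (axis in 1:3) arr <- conv_axis(arr, kern[[axis]], axis)
  arr
}

#' Smooth a standardized wDC map
#'
#' Smoothing is applied to the z map, after standardization; voxel sizes are
#' taken from the affine.
#'
#' @param map a `wdc_map` with `z` present.
#' @param fwhm_mm Gaussian FWHM in mm (default 8).
#' @return the `wdc_map` with smoothed `z` and `params$fwhm` recorded.
#' @export
smooth_map <- function(map, fwhm_mm = 8) {
  stopifnot(inherits(map, "wdc_map"))
  if (is.null(map$z)) stop("smooth_map: standardize the map first")
  if (fwhm_mm < 0) stop("smooth_map: negative FWHM")
  vox <- sqrt(colSums(map$affine[1:3, 1:3]^2))
  map$z <- gaussian_smooth3d(map$z, fwhm_mm, vox)
  map$params$fwhm <- fwhm_mm
  map
}

#' Compute a subject's standardized, smoothed wDC map
#'
#' Convenience wrapper: raw weighted degree, z-standardization, smoothing.
#'
#' @inheritParams compute_wdc_raw
#' @param fwhm_mm smoothing FWHM in mm (default 8; 0 disables).
#' @return a `wdc_map` with raw and z fields.
#' @export
wdc_map <- function(vol, mask, r_threshold = 0.25, fwhm_mm = 8,
                    block_size = 2048L) {
  m <- compute_wdc_raw(vol, mask, r_threshold, block_size)
  m <- standardize_map(m)
  if (fwhm_mm > 0) m <- smooth_map(m, fwhm_mm) else m$params$fwhm <- 0
  m
}
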