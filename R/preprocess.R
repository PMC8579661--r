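#' 4D volume container
#'
#' @param data 4D numeric array indexed (x, y, z, t).
#' @param affine 4x4 voxel(0-based)-to-mm transform; must be invertible.
#' @param tr repetition time in seconds (> 0).
#' @return object of class `volume4d`.
#' @export
volume4d <- function(data, affine = diag(4), tr) {
  stopifnot(length(dim(data)) == 4L, dim(data)[4] >= 2L,
            is.matrix(affine), all(dim(affine) == c(4, 4)),
            abs(det(affine)) > 0, tr > 0)
  structure(list(data = data, affine = affine, tr = tr), class = "volume4d")
}

#' @export
print.volume4d <- function(x, ...) {
  d <- dim(x$data)
  cat("volume4d:", paste(d[1:3], collapse = " x "), "voxels,",
      d[4], "volumes, TR =", x$tr, "s\n")
  invisible(x)
}

#' Read / write a 4D volume as NIfTI-1
#' @param path `.nii` / `.nii.gz` path.
#' @param tr repetition time override; defaults to the header value.
#' @export
read_volume4d <- function(path, tr = NULL) {
  nii <- read_nifti(path)
  if (length(dim(nii$data)) != 4L) stop("read_volume4d: not a 4D image: ", path)
  volume4d(nii$data, nii$affine, if (is.null(tr)) nii$tr else tr)
}

#' @rdname read_volume4d
#' @param vol a `volume4d`.
#' @export
write_volume4d <- function(vol, path) {
  stopifnot(inherits(vol, "volume4d"))
  write_nifti(vol$data, path, vol$affine, tr = vol$tr)
}

#' Discard initial volumes
#'
#' Scanner equilibration frames at the start of a run are discarded before
#' any modelling; the default removes the first 5 of the acquired volumes.
#'
#' @param vol a `volume4d`.
#' @param k number of initial frames to drop (0 <= k < number of frames).
#' @return a `volume4d` with `k` fewer frames.
#' @export
drop_initial_volumes <- function(vol, k = 5L) {
  stopifnot(inherits(vol, "volume4d"))
  nt <- dim(vol$data)[4]
  k <- as.integer(k)
  if (k < 0L) stop("drop_initial_volumes: k must be >= 0")
  if (k >= nt) stop("drop_initial_volumes: k = ", k, " leaves no frames (t = ", nt, ")")
  if (k == 0L) return(vol)
  volume4d(vol$data[, , , (k + 1L):nt, drop = FALSE], vol$affine, vol$tr)
}

#' Build the confound design matrix
#'
#' Assembles the Friston-24 motion expansion — for each of the 6 realignment
#' parameters m(t): m(t), m(t)^2, m(t-1), m(t-1)^2, with the lagged row at
#' t = 1 zero-padded — plus white-matter and CSF signals, polynomial trend
#' columns up to `poly_order` and an intercept (the order-0 trend term).
#' Column count is 24 + 2 + (poly_order + 1).
#'
#' @param motion6 matrix/data.frame with 6 motion columns, one row per
#'   retained volume.
#' @param wm,csf numeric vectors (mean tissue signals), same length.
#' @param n_volumes expected row count (alignment check).
#' @param poly_order polynomial trend order (default 1 = linear).
#' @return numeric matrix with named columns.
#' @export
build_confound_matrix <- function(motion6, wm, csf, n_volumes,
                                  poly_order = 1L) {
  motion6 <- as.matrix(motion6)
  if (ncol(motion6) != 6L) stop("build_confound_matrix: motion6 must have 6 columns")
  n <- nrow(motion6)
  if (n != n_volumes || length(wm) != n || length(csf) != n) {
    stop("build_confound_matrix: misaligned lengths (motion ", n,
         ", wm ", length(wm), ", csf ", length(csf),
         ", expected ", n_volumes, ")")
  }
  lag1 <- rbind(0, motion6[-n, , drop = FALSE])
  fr24 <- cbind(motion6, motion6^2, lag1, lag1^2)
  colnames(fr24) <- c(paste0("mot", 1:6), paste0("mot", 1:6, "_sq"),
                      paste0("mot", 1:6, "_lag"), paste0("mot", 1:6, "_lagsq"))
  tt <- seq_len(n) - (n + 1) / 2
  poly <- vapply(0:poly_order, function(p) tt^p, numeric(n))
  colnames(poly) <- paste0("poly", 0:poly_order)
  out <- cbind(fr24, wm = as.numeric(wm), csf = as.numeric(csf), poly)
  out
}

# drop all-zero columns (with a message), rescale columns to unit norm
# (projection-invariant, but keeps tiny-magnitude regressors such as squared
# rotations from tripping the relative QR tolerance) and verify column rank
.prune_confounds <- function(X) {
  zero <- apply(X, 2L, function(v) all(v == 0))
  if (any(zero)) {
    message("confounds: pruning all-zero column(s): ",
            paste(colnames(X)[zero], collapse = ", "))
    X <- X[, !zero, drop = FALSE]
  }
  X <- sweep(X, 2L, sqrt(colSums(X^2)), `/`)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    dep <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    stop("confounds: design is rank-deficient; collinear column(s): ",
         paste(dep, collapse = ", "))
  }
  X
}

#' Regress confounds out of every voxel time series
#'
#' Replaces each in-mask voxel's series by its least-squares residual on the
#' confound columns; out-of-mask voxels are zeroed.
#'
#' @param vol a `volume4d`.
#' @param confounds confound matrix from [build_confound_matrix()] (or any
#'   full-rank matrix with one row per frame).
#' @param mask logical 3D array on the volume grid.
#' @return a `volume4d` of residuals.
#' @export
regress_confounds <- function(vol, confounds, mask) {
  stopifnot(inherits(vol, "volume4d"))
  d <- dim(vol$data)
  stopifnot(all(dim(mask) == d[1:3]))
  X <- .prune_confounds(as.matrix(confounds))
  if (nrow(X) != d[4]) {
    stop("regress_confounds: confound rows (", nrow(X),
         ") != frames (", d[4], ")")
  }
  flat <- matrix(vol$data, nrow = prod(d[1:3]), ncol = d[4])
  idx <- which(mask)
  Y <- t(flat[idx, , drop = FALSE])          # frames x voxels
  res <- qr.resid(qr(X), Y)
  out <- matrix(0, nrow = prod(d[1:3]), ncol = d[4])
  out[idx, ] <- t(res)
  volume4d(array(out, dim = d), vol$affine, vol$tr)
}

#' Ideal band-pass filter of a time series matrix
#'
#' Rectangular (ideal) frequency-domain filter: discrete-Fourier components
#' whose frequency f satisfies `low <= f <= high` are retained, all others
#' (including the DC component whenever `low > 0`) are zeroed. The filter is
#' idempotent and passes exact in-band DFT-bin sinusoids unchanged.
#'
#' @param x numeric vector or matrix with one series per column.
#' @param tr sampling interval in seconds.
#' @param low,high band edges in Hz; `0 <= low < high <= 1/(2 tr)`.
#' @return filtered series, same shape as `x`.
#' @export
bandpass_series <- function(x, tr, low = 0.01, high = 0.1) {
  nyq <- 1 / (2 * tr)
  if (!(low >= 0 && low < high)) stop("bandpass_series: need 0 <= low < high")
  if (high > nyq + 1e-12) {
    stop("bandpass_series: high = ", high, " Hz exceeds Nyquist ", nyq, " Hz")
  }
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, ncol = 1L) else as.matrix(x)
  n <- nrow(X)
  k <- 0:(n - 1)
  freq <- pmin(k, n - k) / (n * tr)          # folded (two-sided) frequencies
  keep <- freq >= low - 1e-12 & freq <= high + 1e-12
  if (low > 0) keep[1] <- FALSE
  F <- stats::mvfft(X)
  F[!keep, ] <- 0
  out <- Re(stats::mvfft(F, inverse = TRUE)) / n
  if (vec) out[, 1] else out
}

#' Band-pass filter a 4D volume
#'
#' @param vol a `volume4d`.
#' @param low,high band edges in Hz (defaults 0.01 and 0.1).
#' @param mask logical 3D array; voxels outside are zeroed.
#' @return a `volume4d`.
#' @export
bandpass_filter <- function(vol, low = 0.01, high = 0.1, mask = NULL) {
  stopifnot(inherits(vol, "volume4d"))
  d <- dim(vol$data)
  if (is.null(mask)) mask <- array(TRUE, dim = d[1:3])
  stopifnot(all(dim(mask) == d[1:3]))
  flat <- matrix(vol$data, nrow = prod(d[1:3]), ncol = d[4])
  idx <- which(mask)
  filt <- bandpass_series(t(flat[idx, , drop = FALSE]), vol$tr, low, high)
  out <- matrix(0, nrow = prod(d[1:3]), ncol = d[4])
  out[idx, ] <- t(filt)
  volume4d(array(out, dim = d), vol$affine, vol$tr)
}

#' Full time-series cleaning for one subject
#'
#' Fixed order: drop initial volumes, regress confounds (Friston-24 + WM +
#' CSF + polynomial trend), band-pass 0.01-0.1 Hz.
#'
#' @param vol a `volume4d` (raw, all acquired frames).
#' @param confounds data.frame with columns trans_x, trans_y, trans_z,
#'   rot_x, rot_y, rot_z, wm, csf; one row per acquired frame.
#' @param mask logical 3D array.
#' @param drop_volumes frames discarded at the start (default 5).
#' @param band numeric length-2, band edges in Hz.
#' @param poly_order polynomial trend order (default 1).
#' @return a cleaned `volume4d`.
#' @export
preprocess_subject <- function(vol, confounds, mask, drop_volumes = 5L,
                               band = c(0.01, 0.1), poly_order = 1L) {
  stopifnot(inherits(vol, "volume4d"))
  motion_cols <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  if (!all(c(motion_cols, "wm", "csf") %in% names(confounds))) {
    stop("preprocess_subject: confounds must contain ",
         paste(c(motion_cols, "wm", "csf"), collapse = ", "))
  }
  v <- drop_initial_volumes(vol, drop_volumes)
  keep <- (drop_volumes + 1L):dim(vol$data)[4]
  cf <- confounds[keep, , drop = FALSE]
  X <- build_confound_matrix(cf[motion_cols], cf$wm, cf$csf,
                             n_volumes = length(keep), poly_order = poly_order)
  v <- regress_confounds(v, X, mask)
  bandpass_filter(v, band[1], band[2], mask)
}
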