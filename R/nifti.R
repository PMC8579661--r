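#' Minimal NIfTI-1 input/output
#'
#' Reads and writes single-file NIfTI-1 images (`.nii`, `.nii.gz`) covering the
#' needs of this pipeline: 3D label/mask images and 4D time-series volumes.
#' The affine is written as an sform (code 2); on read, the sform is preferred,
#' falling back to a diagonal pixdim affine. Supported on-disk types: uint8,
#' int16, int32, float32, float64. Data are returned as numeric arrays with
#' any scl_slope/scl_inter applied.
#'
#' @param path file path ending in `.nii` or `.nii.gz`.
#' @return `read_nifti()`: a list with `data` (numeric array), `affine`
#'   (4x4 voxel-to-mm transform, 0-based voxel indices), `pixdim`, and `tr`
#'   (seconds; `NA` for 3D images).
#' @name nifti_io
NULL

.nifti_dtypes <- list(
  `2`  = list(what = "integer", size = 1, signed = FALSE),
  `4`  = list(what = "integer", size = 2, signed = TRUE),
  `8`  = list(what = "integer", size = 4, signed = TRUE),
  `16` = list(what = "double",  size = 4, signed = TRUE),
  `64` = list(what = "double",  size = 8, signed = TRUE)
)

.open_nii <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' @rdname nifti_io
#' @param data numeric/integer array, 3 or 4 dimensions.
#' @param affine 4x4 voxel(0-based)-to-mm transform.
#' @param tr repetition time in seconds, stored in pixdim[4] for 4D images.
#' @param datatype on-disk type: "float32", "float64" or "int32".
#' @export
write_nifti <- function(data, path, affine = diag(4), tr = NA_real_,
                        datatype = c("float32", "float64", "int32")) {
  datatype <- match.arg(datatype)
  nd <- length(dim(data))
  if (!(nd %in% c(3L, 4L))) stop("write_nifti: data must be 3D or 4D")
  stopifnot(is.matrix(affine), all(dim(affine) == c(4L, 4L)))
  dims <- dim(data)
  dim8 <- c(nd, dims, rep(1L, 7L - length(dims)))
  vox <- sqrt(colSums(affine[1:3, 1:3]^2))
  pixdim <- c(1, vox, if (nd == 4L && is.finite(tr)) tr else 1, 1, 1, 1)
  code <- switch(datatype, float32 = 16L, float64 = 64L, int32 = 8L)
  bitpix <- switch(datatype, float32 = 32L, float64 = 64L, int32 = 32L)

  buf <- raw(0)
  app_i <- function(x, size) c(buf, writeBin(as.integer(x), raw(), size = size, endian = "little"))
  app_f <- function(x) c(buf, writeBin(as.double(x), raw(), size = 4L, endian = "little"))
  app_c <- function(s, n) {
    r <- charToRaw(s)
    c(buf, r, raw(n - length(r)))
  }
  buf <- app_i(348L, 4)
  buf <- app_c("", 10); buf <- app_c("", 18)
  buf <- app_i(0L, 4); buf <- app_i(0L, 2); buf <- app_c("", 1); buf <- app_c("", 1)
  buf <- app_i(dim8, 2)
  buf <- app_f(c(0, 0, 0)); buf <- app_i(0L, 2)
  buf <- app_i(code, 2); buf <- app_i(bitpix, 2); buf <- app_i(0L, 2)
  buf <- app_f(pixdim)
  buf <- app_f(352); buf <- app_f(1); buf <- app_f(0)
  buf <- app_i(0L, 2); buf <- c(buf, as.raw(0L), as.raw(10L))  # slice_end, slice_code, xyzt = mm|sec
  buf <- app_f(c(0, 0, 0, 0))      # cal_max, cal_min, slice_duration, toffset
  buf <- app_i(c(0L, 0L), 4)       # glmax, glmin
  buf <- app_c("", 80); buf <- app_c("", 24)   # descrip, aux_file
  buf <- app_i(c(0L, 2L), 2)       # qform_code = 0, sform_code = 2
  buf <- app_f(rep(0, 6))          # quatern b,c,d + qoffset x,y,z
  buf <- app_f(affine[1, ]); buf <- app_f(affine[2, ]); buf <- app_f(affine[3, ])
  buf <- app_c("", 16)             # intent_name
  buf <- app_c("n+1", 4)           # magic "n+1\0"
  buf <- c(buf, raw(4))            # extension flag
  stopifnot(length(buf) == 352L)

  con <- .open_nii(path, "wb")
  on.exit(close(con))
  writeBin(buf, con)
  if (datatype == "int32") {
    writeBin(as.integer(data), con, size = 4L, endian = "little")
  } else {
    writeBin(as.double(data), con, size = bitpix %/% 8L, endian = "little")
  }
  invisible(path)
}

#' @rdname nifti_io
#' @export
read_nifti <- function(path) {
  con <- .open_nii(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 352L)
  if (length(hdr) < 348L) stop("read_nifti: truncated header in ", path)
  endian <- "little"
  sz <- readBin(hdr[1:4], "integer", size = 4L, endian = endian)
  if (sz != 348L) {
    endian <- "big"
    sz <- readBin(hdr[1:4], "integer", size = 4L, endian = endian)
    if (sz != 348L) stop("read_nifti: not a NIfTI-1 file: ", path)
  }
  ri <- function(off, n, size) readBin(hdr[(off + 1):(off + n * size)], "integer",
                                       n = n, size = size, endian = endian)
  rf <- function(off, n) readBin(hdr[(off + 1):(off + n * 4L)], "double",
                                 n = n, size = 4L, endian = endian)
  dim8 <- ri(40, 8, 2)
  nd <- dim8[1]
  if (!(nd %in% c(3L, 4L))) stop("read_nifti: only 3D/4D images supported")
  dims <- dim8[2:(1 + nd)]
  datatype <- ri(70, 1, 2)
  dt <- .nifti_dtypes[[as.character(datatype)]]
  if (is.null(dt)) stop("read_nifti: unsupported datatype code ", datatype)
  pixdim <- rf(76, 8)
  vox_offset <- rf(108, 1)
  scl_slope <- rf(112, 1); scl_inter <- rf(116, 1)
  sform_code <- ri(254, 1, 2)
  srow <- rbind(rf(280, 4), rf(296, 4), rf(312, 4))
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("read_nifti: bad magic '", magic, "'")

  nvox <- prod(dims)
  skip <- as.integer(round(vox_offset)) - 352L
  if (skip > 0) readBin(con, "raw", n = skip)
  vals <- readBin(con, dt$what, n = nvox, size = dt$size,
                  signed = dt$signed, endian = endian)
  if (length(vals) != nvox) stop("read_nifti: truncated data in ", path)
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  affine <- if (sform_code > 0) {
    rbind(srow, c(0, 0, 0, 1))
  } else {
    a <- diag(4); diag(a)[1:3] <- pixdim[2:4]; a
  }
  list(data = array(vals, dim = dims),
       affine = affine,
       pixdim = pixdim,
       tr = if (nd == 4L) pixdim[5] else NA_real_)
}
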