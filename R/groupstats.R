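#' Voxel-wise one- and two-sample t maps
#'
#' One-sample: t = mean / (sd / sqrt(n)) against 0, df = n - 1. Two-sample:
#' pooled-variance t of group A minus group B, df = nA + nB - 2. Voxels with
#' zero (pooled) variance get t = 0 and are flagged.
#'
#' @param maps_a list of 3D arrays (or `wdc_map`s; the z map is used), or a
#'   subjects x voxels matrix together with `mask`.
#' @param maps_b optional second group (two-sample comparison, A - B).
#' @param mask logical 3D array.
#' @return object of class `stat_map`: `t` (3D array), `df`, `contrast`,
#'   `mask`, `n_flagged` (zero-variance voxels).
#' @export
t_map <- function(maps_a, maps_b = NULL, mask) {
  as_mat <- function(maps) {
    t(vapply(maps, function(m) {
      a <- if (inherits(m, "wdc_map")) m$z else m
      stopifnot(all(dim(a) == dim(mask)))
      a[mask]
    }, numeric(sum(mask))))
  }
  A <- as_mat(maps_a)
  if (nrow(A) < 2L) stop("t_map: need >= 2 maps per group")
  idx <- which(mask)
  if (is.null(maps_b)) {
    n <- nrow(A)
    mu <- colMeans(A)
    sdv <- sqrt(colSums(sweep(A, 2L, mu)^2) / (n - 1))
    flagged <- sdv == 0
    tv <- ifelse(flagged, 0, mu / (sdv / sqrt(n)))
    df <- n - 1L
    contrast <- sprintf("one-sample (n = %d) vs 0", n)
  } else {
    B <- as_mat(maps_b)
    if (nrow(B) < 2L) stop("t_map: need >= 2 maps per group")
    na <- nrow(A); nb <- nrow(B)
    ma <- colMeans(A); mb <- colMeans(B)
    ssa <- colSums(sweep(A, 2L, ma)^2)
    ssb <- colSums(sweep(B, 2L, mb)^2)
    sp2 <- (ssa + ssb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    flagged <- se == 0
    tv <- ifelse(flagged, 0, (ma - mb) / se)
    df <- na + nb - 2L
    contrast <- sprintf("two-sample (nA = %d, nB = %d), A - B", na, nb)
  }
  tarr <- array(0, dim = dim(mask))
  tarr[idx] <- tv
  structure(list(t = tarr, df = df, contrast = contrast, mask = mask,
                 n_flagged = sum(flagged)), class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat("stat_map:", x$contrast, "| df =", x$df,
      "| max t =", signif(max(x$t[x$mask]), 4), "\n")
  invisible(x)
}

# neighbour offsets for 6 / 18 / 26 connectivity
.neighbour_offsets <- function(connectivity) {
  stopifnot(connectivity %in% c(6L, 18L, 26L))
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  ord <- abs(g$dx) + abs(g$dy) + abs(g$dz)
  keep <- switch(as.character(connectivity),
                 `6` = ord == 1, `18` = ord <= 2, `26` = ord <= 3)
  as.matrix(g[keep, ])
}

# label connected components among TRUE voxels of a 3D logical array
.connected_components <- function(flag, connectivity = 18L) {
  d <- dim(flag)
  offs <- .neighbour_offsets(connectivity)
  labels <- array(0L, dim = d)
  vox <- which(flag, arr.ind = TRUE)
  if (!nrow(vox)) return(labels)
  lin <- which(flag)
  current <- 0L
  for (v in seq_along(lin)) {
    if (labels[lin[v]] != 0L) next
    current <- current + 1L
    stack <- matrix(vox[v, ], ncol = 3)
    labels[lin[v]] <- current
    while (nrow(stack)) {
      p <- stack[nrow(stack), ]
      stack <- stack[-nrow(stack), , drop = FALSE]
      nb <- sweep(offs, 2L, p, `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      if (!nrow(nb)) next
      nlin <- nb[, 1] + d[1] * (nb[, 2] - 1L) + d[1] * d[2] * (nb[, 3] - 1L)
      new <- flag[nlin] & labels[nlin] == 0L
      if (any(new)) {
        labels[nlin[new]] <- current
        stack <- rbind(stack, nb[new, , drop = FALSE])
      }
    }
  }
  labels
}

#' Suprathreshold clusters of a t map
#'
#' Thresholds the map at the one-tailed cluster-forming p (t >
#' qt(1 - p_form, df) in the contrast direction), groups surviving voxels
#' into connected components, and discards components smaller than `k_min`.
#'
#' @param stat a `stat_map`.
#' @param p_form cluster-forming voxel p (one-tailed; default 0.005).
#' @param k_min minimum cluster extent in voxels (default 20).
#' @param connectivity 6, 18 (default) or 26.
#' @param affine optional 4x4 affine for peak mm coordinates.
#' @return object of class `cluster_result`: data.frame `clusters` (size,
#'   peak_t, peak i/j/k, peak mm, corrected_p = NA), `labels` (3D integer
#'   array), plus thresholds used.
#' @export
find_clusters <- function(stat, p_form = 0.005, k_min = 20L,
                          connectivity = 18L, affine = NULL) {
  stopifnot(inherits(stat, "stat_map"), p_form > 0, p_form < 1, k_min >= 1)
  t_thr <- stats::qt(1 - p_form, df = stat$df)
  flag <- stat$t > t_thr & stat$mask
  labels <- .connected_components(flag, connectivity)
  sizes <- tabulate(labels[labels > 0L])
  keep <- which(sizes >= k_min)
  rows <- lapply(seq_along(keep), function(i) {
    id <- keep[i]
    lin <- which(labels == id)
    peak <- lin[which.max(stat$t[lin])]
    pk <- arrayInd(peak, dim(labels))
    mm <- if (!is.null(affine)) as.numeric(affine %*% c(pk - 1L, 1))[1:3]
          else rep(NA_real_, 3)
    data.frame(cluster = i, size = sizes[id], peak_t = stat$t[peak],
               peak_i = pk[1], peak_j = pk[2], peak_k = pk[3],
               peak_x_mm = mm[1], peak_y_mm = mm[2], peak_z_mm = mm[3],
               corrected_p = NA_real_)
  })
  relab <- array(0L, dim = dim(labels))
  for (i in seq_along(keep)) relab[labels == keep[i]] <- i
  structure(list(clusters = if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster = integer(0), size = integer(0), peak_t = numeric(0),
               peak_i = integer(0), peak_j = integer(0), peak_k = integer(0),
               peak_x_mm = numeric(0), peak_y_mm = numeric(0),
               peak_z_mm = numeric(0), corrected_p = numeric(0)),
    labels = relab, t_threshold = t_thr, p_form = p_form, k_min = k_min,
    connectivity = connectivity), class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("cluster_result:", nrow(x$clusters), "cluster(s) at t >",
      signif(x$t_threshold, 4), ", k >=", x$k_min, "\n")
  if (nrow(x$clusters)) print(x$clusters, digits = 4, row.names = FALSE)
  invisible(x)
}

# max suprathreshold cluster size of a t map given flat group data
.max_cluster_size <- function(tvals, mask, t_thr, connectivity) {
  flag <- array(FALSE, dim = dim(mask))
  flag[which(mask)] <- tvals > t_thr
  labels <- .connected_components(flag, connectivity)
  if (!any(labels > 0L)) return(0L)
  max(tabulate(labels[labels > 0L]))
}

# flat two-sample pooled t on an n x V matrix given group-1 row indices
.flat_two_sample_t <- function(X, ia) {
  ib <- setdiff(seq_len(nrow(X)), ia)
  na <- length(ia); nb <- length(ib)
  ma <- colMeans(X[ia, , drop = FALSE]); mb <- colMeans(X[ib, , drop = FALSE])
  ssa <- colSums(X[ia, , drop = FALSE]^2) - na * ma^2
  ssb <- colSums(X[ib, , drop = FALSE]^2) - nb * mb^2
  se <- sqrt(pmax(ssa + ssb, 0) / (na + nb - 2) * (1 / na + 1 / nb))
  ifelse(se == 0, 0, (ma - mb) / se)
}

# flat one-sample t given a sign-flip vector
.flat_one_sample_t <- function(X, signs) {
  Xs <- X * signs
  n <- nrow(X)
  mu <- colMeans(Xs)
  sdv <- sqrt(pmax(colSums(Xs^2) - n * mu^2, 0) / (n - 1))
  ifelse(sdv == 0, 0, mu / (sdv / sqrt(n)))
}

#' Permutation cluster-extent correction
#'
#' Builds the null distribution of the maximum suprathreshold cluster size
#' by permuting group labels (two-sample) or flipping subject signs
#' (one-sample), and assigns each observed cluster the corrected p
#' \deqn{p = (1 + \#\{null\ max \ge size\}) / (n_{perm} + 1).}
#' When the number of distinct permutations does not exceed `n_perm` the
#' full set is enumerated instead (logged via a message).
#'
#' @param maps_a,maps_b lists of 3D arrays / `wdc_map`s (B = NULL for the
#'   one-sample sign-flip test).
#' @param mask logical 3D array.
#' @param p_form cluster-forming one-tailed voxel p (default 0.005).
#' @param k_min minimum cluster extent (default 20).
#' @param n_perm number of permutations (>= 100; default 1000).
#' @param seed RNG seed for the permutation draw.
#' @param connectivity 6 / 18 / 26 (default 18).
#' @param affine optional affine for peak coordinates.
#' @return a `cluster_result` with `corrected_p` filled and the null
#'   maximum-size distribution in `null_max`.
#' @export
permutation_cluster_p <- function(maps_a, maps_b = NULL, mask,
                                  p_form = 0.005, k_min = 20L,
                                  n_perm = 1000L, seed = 1L,
                                  connectivity = 18L, affine = NULL) {
  if (n_perm < 100L) stop("permutation_cluster_p: n_perm must be >= 100")
  obs_stat <- t_map(maps_a, maps_b, mask)
  obs <- find_clusters(obs_stat, p_form, k_min, connectivity, affine)
  t_thr <- obs$t_threshold

  flatten <- function(maps) t(vapply(maps, function(m) {
    a <- if (inherits(m, "wdc_map")) m$z else m
    a[mask]
  }, numeric(sum(mask))))

  set.seed(seed)
  if (is.null(maps_b)) {
    X <- flatten(maps_a)
    n <- nrow(X)
    exhaustive <- 2^n <= n_perm
    if (exhaustive) {
      message("permutation_cluster_p: enumerating all ", 2^n, " sign flips")
      signs_list <- lapply(0:(2^n - 1), function(b)
        ifelse(bitwAnd(b, 2^(0:(n - 1))) > 0, -1, 1))
    } else {
      signs_list <- replicate(n_perm, sample(c(-1, 1), n, replace = TRUE),
                              simplify = FALSE)
    }
    null_max <- vapply(signs_list, function(s)
      .max_cluster_size(.flat_one_sample_t(X, s), mask, t_thr, connectivity),
      integer(1))
  } else {
    X <- rbind(flatten(maps_a), flatten(maps_b))
    na <- length(maps_a); n <- nrow(X)
    n_distinct <- choose(n, na)
    exhaustive <- n_distinct <= n_perm
    if (exhaustive) {
      message("permutation_cluster_p: enumerating all ", n_distinct,
              " group assignments")
      combs <- utils::combn(n, na, simplify = FALSE)
    } else {
      combs <- replicate(n_perm, sample.int(n, na), simplify = FALSE)
    }
    null_max <- vapply(combs, function(ia)
      .max_cluster_size(.flat_two_sample_t(X, ia), mask, t_thr, connectivity),
      integer(1))
  }
  m <- length(null_max)
  if (nrow(obs$clusters)) {
    obs$clusters$corrected_p <- vapply(obs$clusters$size, function(sz)
      (1 + sum(null_max >= sz)) / (m + 1), numeric(1))
  }
  obs$null_max <- null_max
  obs$n_perm <- m
  obs$exhaustive <- exhaustive
  obs
}
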