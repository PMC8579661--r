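rand_maps <- function(n, d = c(6, 5, 4), mu = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lapply(1:n, function(i) array(rnorm(prod(d), mean = mu), d))
}

test_that("voxel-wise t maps match the scalar t-test oracle", {
  d <- c(30, 1, 1)
  mask <- array(TRUE, d)
  A <- rand_maps(6, d, seed = 40)
  B <- rand_maps(8, d, mu = 0.5)

  two <- t_map(A, B, mask)
  expect_identical(two$df, 12L)
  for (i in seq(1, 30, by = 5)) {
    a <- vapply(A, function(m) m[i, 1, 1], 0)
    b <- vapply(B, function(m) m[i, 1, 1], 0)
    ref <- t.test(a, b, var.equal = TRUE)$statistic
    expect_equal(two$t[i, 1, 1], unname(ref), tolerance = 1e-10)
  }

  one <- t_map(A, mask = mask)
  expect_identical(one$df, 5L)
  for (i in c(1, 15, 30)) {
    a <- vapply(A, function(m) m[i, 1, 1], 0)
    expect_equal(one$t[i, 1, 1], unname(t.test(a)$statistic), tolerance = 1e-10)
  }

  # identical groups -> t identically zero
  expect_true(all(t_map(A, A, mask)$t == 0))

  # positive constant + tiny jitter -> uniformly large positive t
  C <- lapply(1:5, function(i) array(2 + rnorm(prod(d), sd = 1e-3), d))
  expect_true(all(t_map(C, mask = mask)$t[mask] > 100))

  # zero-variance voxels are flagged with t = 0
  Z <- rand_maps(4, d, seed = 41)
  for (k in seq_along(Z)) Z[[k]][3, 1, 1] <- 1
  z1 <- t_map(Z, mask = mask)
  expect_identical(z1$t[3, 1, 1], 0)
  expect_identical(z1$n_flagged, 1L)

  expect_error(t_map(A[1], mask = mask), ">= 2 maps")
})

test_that("connected components agree with an independent oracle", {
  set.seed(42)
  d <- c(8, 8, 6)
  for (conn in c(6L, 18L, 26L)) {
    for (r in 1:4) {
      flag <- array(runif(prod(d)) < 0.18, d)
      got <- wdcfinger:::.connected_components(flag, conn)
      ref <- cc_oracle(flag, conn)
      # same partition: identical size multisets and label-agreement map
      expect_identical(cluster_sizes(got), cluster_sizes(ref))
      expect_identical(got > 0, ref > 0)
      agree <- table(got[flag], ref[flag])
      expect_true(all(rowSums(agree > 0) == 1) && all(colSums(agree > 0) == 1))
    }
  }
})

test_that("cluster extraction applies threshold, extent and peak logic", {
  d <- c(12, 12, 10)
  mask <- array(TRUE, d)
  tarr <- array(0, d)
  stat <- structure(list(t = tarr, df = 20L, contrast = "toy", mask = mask,
                         n_flagged = 0L), class = "stat_map")
  expect_identical(nrow(find_clusters(stat)$clusters), 0L)

  # planted 3x3x3 suprathreshold block survives k_min = 20 as one cluster
  stat$t[4:6, 4:6, 4:6] <- 10
  stat$t[5, 5, 5] <- 12
  res <- find_clusters(stat, p_form = 0.005, k_min = 20)
  expect_identical(nrow(res$clusters), 1L)
  expect_identical(res$clusters$size, 27L)
  expect_equal(res$clusters$peak_t, 12)
  expect_identical(c(res$clusters$peak_i, res$clusters$peak_j,
                     res$clusters$peak_k), c(5L, 5L, 5L))

  # a second, smaller blob is removed by the extent criterion
  stat$t[10:11, 10, 8] <- 10
  res2 <- find_clusters(stat, k_min = 20)
  expect_identical(nrow(res2$clusters), 1L)
  res3 <- find_clusters(stat, k_min = 1)
  expect_identical(sort(res3$clusters$size), c(2L, 27L))

  # peak world coordinates follow the affine (0-based voxel indices)
  aff <- diag(c(3, 3, 4, 1)); aff[1:3, 4] <- c(-16.5, -16.5, -18)
  res4 <- find_clusters(stat, k_min = 20, affine = aff)
  expect_equal(c(res4$clusters$peak_x_mm, res4$clusters$peak_y_mm,
                 res4$clusters$peak_z_mm),
               as.numeric(aff %*% c(4, 4, 4, 1))[1:3])
})

test_that("cluster labelling is invariant under axis permutation", {
  set.seed(43)
  d <- c(7, 6, 5)
  tarr <- array(rnorm(prod(d), sd = 2), d)
  mk <- function(t_arr, df) structure(list(t = t_arr, df = df, contrast = "x",
                                           mask = array(TRUE, dim(t_arr)),
                                           n_flagged = 0L), class = "stat_map")
  a <- find_clusters(mk(tarr, 15L), p_form = 0.05, k_min = 1)
  b <- find_clusters(mk(aperm(tarr, c(3, 1, 2)), 15L), p_form = 0.05, k_min = 1)
  expect_identical(cluster_sizes(a$labels), cluster_sizes(b$labels))
})

test_that("permutation correction assigns valid, monotone corrected p-values", {
  d <- c(8, 8, 6)
  mask <- array(TRUE, d)

  # exchangeable null: nothing significant at the 0.05 level
  A <- rand_maps(8, d, seed = 44)
  B <- rand_maps(8, d)
  null_res <- permutation_cluster_p(A, B, mask, p_form = 0.05, k_min = 1,
                                    n_perm = 300, seed = 9)
  if (nrow(null_res$clusters)) {
    expect_true(all(null_res$clusters$corrected_p > 0.05))
    expect_true(all(null_res$clusters$corrected_p <= 1))
    ord <- order(null_res$clusters$size)
    expect_true(all(diff(null_res$clusters$corrected_p[ord]) <= 1e-12))
  }

  # planted 3-sd block effect is detected at corrected p <= 0.05
  A2 <- rand_maps(8, d, seed = 45)
  for (k in seq_along(A2)) A2[[k]][2:5, 2:5, 2:4] <- A2[[k]][2:5, 2:5, 2:4] + 3
  B2 <- rand_maps(8, d)
  eff <- permutation_cluster_p(A2, B2, mask, p_form = 0.005, k_min = 20,
                               n_perm = 200, seed = 10)
  expect_gte(nrow(eff$clusters), 1L)
  expect_lte(min(eff$clusters$corrected_p), 0.05)

  expect_error(permutation_cluster_p(A, B, mask, n_perm = 50), ">= 100")
})

test_that("small designs fall back to exhaustive enumeration", {
  d <- c(5, 5, 4)
  mask <- array(TRUE, d)
  A <- rand_maps(3, d, seed = 46)
  B <- rand_maps(3, d)
  expect_message(res <- permutation_cluster_p(A, B, mask, p_form = 0.05,
                                              k_min = 1, n_perm = 100,
                                              seed = 2),
                 "enumerating all 20")
  expect_identical(res$n_perm, 20L)
  expect_true(res$exhaustive)

  # one-sample sign flips: 2^4 = 16 <= 100
  expect_message(one <- permutation_cluster_p(rand_maps(4, d, seed = 47),
                                              mask = mask, p_form = 0.05,
                                              k_min = 1, n_perm = 100,
                                              seed = 3),
                 "enumerating all 16")
  expect_identical(one$n_perm, 16L)
})
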