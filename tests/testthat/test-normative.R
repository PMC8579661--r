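test_that("Crawford-Howell statistic matches its closed form", {
  set.seed(20)
  ctl <- rnorm(18, mean = 3, sd = 2)
  at_mean <- crawford_t(mean(ctl), ctl)
  expect_equal(at_mean$t, 0)
  expect_equal(at_mean$p, 1)
  expect_identical(at_mean$df, 17L)

  two_sd <- crawford_t(mean(ctl) + 2 * sd(ctl), ctl)
  expect_equal(two_sd$t, 2 / sqrt(19 / 18), tolerance = 1e-12)
  expect_equal(two_sd$p, 2 * pt(-2 / sqrt(19 / 18), 17), tolerance = 1e-12)

  # scale invariance: multiplying all inputs by a constant leaves t unchanged
  scaled <- crawford_t(7 * (mean(ctl) + 2 * sd(ctl)), 7 * ctl)
  expect_equal(scaled$t, two_sd$t, tolerance = 1e-12)

  expect_error(crawford_t(1, c(2, 2, 2)), "zero control variance")
  expect_error(crawford_t(1, 2), "at least 2")
})

test_that("with a huge normative sample the test converges to the z-test", {
  set.seed(21)
  big <- as.numeric(scale(rnorm(1e5)))   # exact mean 0, sd 1
  res <- crawford_t(2, big)
  expect_lt(abs(res$p - 2 * pnorm(-2)), 1e-3)
})

test_that("voxel-wise Crawford map equals the scalar loop oracle", {
  set.seed(22)
  v <- 50; n <- 18
  ctl <- lapply(1:n, function(i) array(rnorm(v), c(v, 1, 1)))
  case <- array(rnorm(v), c(v, 1, 1))
  cm <- crawford_map(case, ctl, line_mask(v))
  for (i in seq(1, v, by = 7)) {
    ref <- crawford_t(case[i, 1, 1], vapply(ctl, function(m) m[i, 1, 1], 0))
    expect_equal(cm$t[i, 1, 1], ref$t, tolerance = 1e-12)
    expect_equal(cm$p[i, 1, 1], ref$p, tolerance = 1e-12)
  }
  expect_identical(cm$df, 17L)

  # case equal to the voxel-wise control mean -> t identically 0
  mean_map <- array(rowMeans(vapply(ctl, function(m) m[, 1, 1], numeric(v))),
                    c(v, 1, 1))
  expect_true(all(abs(crawford_map(mean_map, ctl, line_mask(v))$t) < 1e-12))

  # a +10 control-sd inflated voxel attains the map maximum
  case2 <- mean_map
  sd17 <- sd(vapply(ctl, function(m) m[17, 1, 1], 0))
  case2[17, 1, 1] <- case2[17, 1, 1] + 10 * sd17
  cm2 <- crawford_map(case2, ctl, line_mask(v))
  expect_identical(which.max(cm2$t), 17L)

  expect_error(crawford_map(array(0, c(3, 1, 1)), ctl, line_mask(v)),
               "grid mismatch")
  expect_error(crawford_map(case, ctl[1], line_mask(v)), "at least 2")
})

test_that("ROI summaries count only significant increases", {
  v <- 30
  cm <- structure(list(t = array(0, c(v, 1, 1)), p = array(1, c(v, 1, 1)),
                       df = 17L, n_controls = 18L, mask = line_mask(v)),
                  class = "crawford_map")
  roi <- array(FALSE, c(v, 1, 1)); roi[5:14] <- TRUE

  s0 <- summarize_roi(cm, roi)
  expect_identical(s0$indicator, 0L)
  expect_identical(s0$n_sig, 0L)
  expect_identical(s0$n_roi, 10L)

  cm$p[7, 1, 1] <- 0.001; cm$t[7, 1, 1] <- 4
  s1 <- summarize_roi(cm, roi)
  expect_identical(s1$indicator, 1L)
  expect_identical(s1$n_sig, 1L)

  # significant decreases never count toward "increase"
  cm$p[9, 1, 1] <- 1e-4; cm$t[9, 1, 1] <- -5
  set.seed(23)
  cm$p[10:12, 1, 1] <- runif(3, 0, 0.004)
  cm$t[10:12, 1, 1] <- c(3, -3, 3)
  s2 <- summarize_roi(cm, roi)
  oracle <- sum(cm$p[roi] < 0.005 & cm$t[roi] > 0)
  expect_identical(s2$n_sig, oracle)
  expect_identical(summarize_roi(cm, roi, direction = "decrease")$n_sig,
                   sum(cm$p[roi] < 0.005 & cm$t[roi] < 0))

  expect_error(summarize_roi(cm, array(FALSE, c(v, 1, 1))), "empty ROI")
})

test_that("indicator is monotone in the case values", {
  set.seed(24)
  v <- 20
  ctl <- lapply(1:18, function(i) array(rnorm(v), c(v, 1, 1)))
  roi <- array(TRUE, c(v, 1, 1))
  case <- array(rnorm(v), c(v, 1, 1))
  for (bump in c(0, 1, 3, 10)) {
    ind <- summarize_roi(crawford_map(case + bump, ctl, line_mask(v)),
                         roi)$indicator
    if (bump == 0) prev <- ind
    expect_gte(ind, prev)
    prev <- ind
  }
})

test_that("Type-I error of the single-case test is controlled at alpha", {
  # quick screen (2,000 draws); the full 20,000-draw calibration check
  # lives with the acceptance suite
  set.seed(25)
  n_rep <- 2000
  ctl <- matrix(rnorm(n_rep * 18), n_rep, 18)
  case <- rnorm(n_rep)
  mu <- rowMeans(ctl)
  s <- apply(ctl, 1, sd)
  tt <- (case - mu) / (s * sqrt(19 / 18))
  p <- 2 * pt(-abs(tt), 17)
  rate <- mean(p < 0.005)
  expect_lt(abs(rate - 0.005), 4 * sqrt(0.005 * 0.995 / n_rep))
})

test_that("cohort tabulation matches a counting oracle", {
  set.seed(26)
  ids <- sprintf("p%02d", 1:30)
  pt <- data.frame(id = ids,
                   outcome = rep(c("SF", "nonSF"), c(14, 16)),
                   stringsAsFactors = FALSE)
  rois <- expand.grid(roi = c("mesial", "pole", "lateral"),
                      side = c("ipsilateral", "contralateral"),
                      stringsAsFactors = FALSE)
  summaries <- lapply(ids, function(id) {
    data.frame(roi = rois$roi, side = rois$side,
               indicator = rbinom(6, 1, 0.4),
               n_sig = rpois(6, 2), n_roi = 50L, stringsAsFactors = FALSE)
  })
  names(summaries) <- ids
  tab <- tabulate_cohort(summaries, pt)
  expect_identical(nrow(tab), 18L)    # 6 ROIs x {All, SF, nonSF}

  for (k in sample(nrow(tab), 6)) {
    row <- tab[k, ]
    grp_ids <- switch(row$group, All = ids,
                      SF = ids[pt$outcome == "SF"],
                      nonSF = ids[pt$outcome == "nonSF"])
    cnt <- sum(vapply(grp_ids, function(id) {
      s <- summaries[[id]]
      s$indicator[s$roi == row$roi & s$side == row$side] == 1L
    }, TRUE))
    expect_identical(row$n_increased, cnt)
    expect_equal(row$pct_increased, round(100 * cnt / length(grp_ids), 1))
  }
  # 7 of 30 -> 23.3% as printed
  stub <- summaries
  for (id in ids) stub[[id]]$indicator <- 0L
  for (id in ids[1:7]) {
    stub[[id]]$indicator[stub[[id]]$roi == "mesial" &
                           stub[[id]]$side == "ipsilateral"] <- 1L
  }
  t2 <- tabulate_cohort(stub, pt)
  r <- t2[t2$roi == "mesial" & t2$side == "ipsilateral" & t2$group == "All", ]
  expect_equal(r$pct_increased, 23.3)
  all0 <- t2[t2$roi == "pole" & t2$group == "All", ]
  expect_true(all(all0$n_increased == 0L))
  expect_true(all(all0$pct_increased == 0))

  expect_error(tabulate_cohort(summaries[1:29], pt), "ids")
})

test_that("feature table joins indicators, counts and outcome coding", {
  ids <- c("a", "b")
  pt <- data.frame(id = ids, outcome = c("SF", "nonSF"),
                   stringsAsFactors = FALSE)
  mk <- function(ind) data.frame(
    roi = rep(c("mesial", "pole", "lateral"), each = 2),
    side = rep(c("ipsilateral", "contralateral"), 3),
    indicator = ind, n_sig = ind * 3L, n_roi = 10L, stringsAsFactors = FALSE)
  summaries <- list(a = mk(c(1L, 0L, 0L, 0L, 1L, 0L)),
                    b = mk(rep(0L, 6)))
  ft <- build_feature_table(summaries, pt)
  expect_identical(ft$y, c(1L, 0L))
  expect_identical(ft$ind_mesial_ipsilateral, c(1L, 0L))
  expect_identical(ft$nvox_lateral_ipsilateral, c(3L, 0L))
  expect_identical(ncol(ft), 14L)  # id + y + 6 indicators + 6 counts
})
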