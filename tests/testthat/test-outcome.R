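# expand a 2x2 table (rows: predictor 1/0, cols: outcome 1/0) to patient data
table_to_df <- function(n11, n10, n01, n00) {
  data.frame(y = rep(c(1L, 0L, 1L, 0L), c(n11, n10, n01, n00)),
             x = rep(c(1L, 1L, 0L, 0L), c(n11, n10, n01, n00)))
}

test_that("single-predictor fit equals the closed-form 2x2 log odds ratio", {
  # increased/not x SF/non-SF margins 6,1 / 8,15: OR = (6*15)/(1*8) = 11.25
  df <- table_to_df(6, 1, 8, 15)
  fit <- fit_logistic(df, "x")
  expect_s3_class(fit, "wdc_logit")
  expect_equal(unname(coef(fit)["x"]), log(11.25), tolerance = 1e-6)
  expect_equal(unname(coef(fit)["(Intercept)"]), log(8 / 15), tolerance = 1e-6)

  # balanced table: slope exactly 0
  bal <- fit_logistic(table_to_df(5, 5, 5, 5), "x")
  expect_equal(unname(coef(bal)["x"]), 0, tolerance = 1e-8)
})

test_that("intercept-only model fits the Bernoulli MLE", {
  df <- data.frame(y = rep(c(1L, 0L), c(14, 16)))
  fit <- fit_logistic(df, character(0))
  expect_true(all(abs(fit$fitted - 14 / 30) < 1e-9))
  expect_equal(fit$ll1, fit$ll0, tolerance = 1e-9)
  expect_equal(fit$chisq, 0, tolerance = 1e-7)
})

test_that("degenerate outcomes and separation are handled as specified", {
  expect_error(fit_logistic(data.frame(y = rep(1L, 10), x = rnorm(10)), "x"),
               "constant outcome")
  expect_error(fit_logistic(data.frame(y = c(0, 1, 0), x = 1:3, z = 3:1, w = 1:3),
                            c("x", "z", "w")), "need n")
  # perfectly separating predictor: flagged, not an exception
  sep <- data.frame(y = rep(c(0L, 1L), each = 10),
                    x = c(rnorm(10, -3), rnorm(10, 3)))
  fit <- fit_logistic(sep, "x")
  expect_true(fit$separation)
})

test_that("backward stepwise removes noise before planted signal", {
  set.seed(30)
  n <- 500
  x_true <- rbinom(n, 1, 0.4)
  x_noise <- sample(x_true)               # permuted copy: no association
  y <- rbinom(n, 1, plogis(-1 + 2.5 * x_true))
  df <- data.frame(y = y, planted = x_true, irrelevant = x_noise)
  fit <- backward_stepwise(df, c("planted", "irrelevant"))
  expect_identical(fit$removal_log$removed, "irrelevant")
  expect_identical(fit$predictors, "planted")
  expect_gt(unname(coef(fit)["planted"]), 0)

  # a single predictor below p-to-remove is a fixed point of the procedure
  single <- backward_stepwise(df, "planted")
  expect_identical(nrow(single$removal_log), 0L)
  expect_equal(coef(single), coef(fit_logistic(df, "planted")))
})

test_that("pure-noise predictors usually collapse to the intercept-only model", {
  set.seed(31)
  kept <- vapply(1:30, function(r) {
    df <- data.frame(y = rbinom(400, 1, 0.5),
                     a = rbinom(400, 1, 0.5), b = rbinom(400, 1, 0.5))
    length(backward_stepwise(df, c("a", "b"))$predictors)
  }, numeric(1))
  # removal criterion p > 0.10: each noise predictor survives ~10% of runs
  expect_lt(mean(kept > 0), 0.5)
})

test_that("likelihood fit indices reproduce the published arithmetic", {
  ll0 <- 14 * log(14 / 30) + 16 * log(16 / 30)
  idx <- fit_indices(ll0, ll0 + 15.19 / 2, n = 30)
  expect_equal(idx$chisq, 15.19, tolerance = 1e-12)
  expect_equal(idx$r2_coxsnell, 1 - exp(-15.19 / 30), tolerance = 1e-12)
  expect_equal(idx$r2_coxsnell, 0.397, tolerance = 1e-3)
  expect_equal(idx$r2_nagelkerke, 0.53, tolerance = 5e-3)

  zero <- fit_indices(ll0, ll0, 30)
  expect_identical(zero$chisq, 0)
  expect_identical(zero$r2_coxsnell, 0)
  expect_identical(zero$r2_nagelkerke, 0)

  # ordering property on random inputs
  set.seed(32)
  for (r in 1:25) {
    n <- sample(10:200, 1)
    y <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(y)) < 2) next
    l0 <- sum(y * log(mean(y)) + (1 - y) * log(1 - mean(y)))
    l1 <- l0 + rexp(1, 1 / 3)
    i <- fit_indices(l0, min(l1, -1e-9), n)
    expect_gte(i$r2_nagelkerke, i$r2_coxsnell)
    expect_lt(i$r2_coxsnell, 1)
    expect_lte(i$r2_nagelkerke, 1 + 1e-12)
  }
  expect_error(fit_indices(-10, -11, 30), "ll1 < ll0")
})

test_that("Hosmer-Lemeshow is zero under perfect calibration and matches arithmetic", {
  # groups whose predicted probability equals the observed frequency
  p <- rep(c(0.2, 0.8), each = 5)
  y <- c(1, 0, 0, 0, 0, 1, 1, 1, 1, 0)
  hl <- suppressWarnings(hosmer_lemeshow(p, y))
  expect_equal(hl$C, 0, tolerance = 1e-12)
  expect_identical(hl$n_groups, 2L)

  # hand-built 2-group arithmetic oracle
  p2 <- rep(c(0.3, 0.6), each = 4)
  y2 <- c(1, 1, 0, 0, 1, 1, 1, 0)
  hl2 <- suppressWarnings(hosmer_lemeshow(p2, y2))
  C_oracle <- (2 - 1.2)^2 / 1.2 + (2 - 2.8)^2 / 2.8 +
    (3 - 2.4)^2 / 2.4 + (1 - 1.6)^2 / 1.6
  expect_equal(hl2$C, C_oracle, tolerance = 1e-12)
  expect_warning(hosmer_lemeshow(p2, y2), "suppressed")
  expect_true(is.na(suppressWarnings(hosmer_lemeshow(p2, y2))$p))

  expect_error(hosmer_lemeshow(c(0, 0.5), c(0, 1)))
})

test_that("Hosmer-Lemeshow C is approximately chi-square under the null", {
  # the g - 2 degrees of freedom hold for *fitted* probabilities, so each
  # replicate fits a correctly specified logistic model before grouping
  set.seed(33)
  n <- 500
  stats <- vapply(1:1000, function(r) {
    x <- rnorm(n)
    y <- rbinom(n, 1, plogis(-0.3 + 0.8 * x))
    p_hat <- fitted(glm(y ~ x, family = binomial()))
    hosmer_lemeshow(p_hat, y, 10)$C
  }, numeric(1))
  expect_lt(abs(mean(stats) - 8) / 8, 0.10)   # mean of chi-square(8)
})

test_that("classification table counts match the cutoff rule", {
  p <- c(0.9, 0.8, 0.2, 0.4, 0.6, 0.1)
  y <- c(1, 1, 0, 0, 0, 1)
  ct <- classification_table(p, y, 0.5)
  expect_equal(ct$overall_pct, 100 * 4 / 6)
  expect_equal(ct$pct_class1, 100 * 2 / 3)
  expect_equal(ct$pct_class0, 100 * 2 / 3)

  perfect <- classification_table(c(0.99, 0.99, 0.01), c(1, 1, 0))
  expect_equal(perfect$overall_pct, 100)
  expect_equal(perfect$pct_class1, 100)

  low <- classification_table(rep(0.4, 10), rep(c(0, 1), 5))
  expect_equal(low$overall_pct, 50)    # everyone predicted 0
  expect_equal(low$pct_class0, 100)
  expect_equal(low$pct_class1, 0)

  # counting oracle on a random fixture
  set.seed(34)
  p <- runif(40); y <- rbinom(40, 1, 0.5)
  ct <- classification_table(p, y, 0.35)
  pred <- as.integer(p >= 0.35)
  expect_equal(ct$overall_pct, 100 * mean(pred == y))
  expect_identical(as.integer(ct$table["1", "1"]), sum(pred == 1 & y == 1))
})

test_that("AUC equals the all-pairs concordance and the ROC trapezoid", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(rep(0.5, 8), rep(c(0, 1), 4))$auc, 0.5)
  expect_error(roc_auc(runif(5), rep(1, 5)), "both classes")

  set.seed(35)
  for (r in 1:5) {
    p <- sample(round(runif(20), 2))   # rounding forces some ties
    y <- rbinom(20, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    res <- roc_auc(p, y)
    # brute-force all-pairs concordance with 0.5 tie credit
    pairs <- expand.grid(i = which(y == 1), j = which(y == 0))
    oracle <- mean(ifelse(p[pairs$i] > p[pairs$j], 1,
                          ifelse(p[pairs$i] == p[pairs$j], 0.5, 0)))
    expect_equal(res$auc, oracle, tolerance = 1e-12)
    # trapezoidal integral over the ROC curve
    cv <- res$curve[order(1 - res$curve$specificity, res$curve$sensitivity), ]
    fpr <- 1 - cv$specificity; tpr <- cv$sensitivity
    trap <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
    expect_equal(trap, oracle, tolerance = 1e-12)
  }
})

test_that("the fitted model object exposes the standard methods", {
  set.seed(36)
  n <- 60
  x <- rbinom(n, 1, 0.5)
  df <- data.frame(y = rbinom(n, 1, plogis(-0.5 + 1.5 * x)), x = x,
                   z = rbinom(n, 1, 0.5))
  fit <- backward_stepwise(df, c("x", "z"))
  expect_output(print(fit), "Logistic outcome model")
  expect_output(summary(fit), "Coefficients")
  expect_length(predict(fit), n)
  expect_equal(predict(fit, newdata = df), fit$fitted, ignore_attr = TRUE)
  expect_length(residuals(fit), n)
  expect_true(is.finite(fit$roc$auc))
  f <- tempfile(fileext = ".pdf")
  grDevices::pdf(f); plot(fit); grDevices::dev.off()
  expect_true(file.exists(f)); unlink(f)
})
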