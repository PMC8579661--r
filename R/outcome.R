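#' Logistic outcome model with the study's fit report
#'
#' Fits a binary logistic regression of seizure freedom (y = 1) on ROI
#' features by maximum likelihood and assembles the full clinical report:
#' Wald coefficient table, likelihood-ratio model test, Cox-Snell and
#' Nagelkerke pseudo-R², Hosmer-Lemeshow calibration, the classification
#' table at a probability cutoff, and the ROC curve with its
#' Mann-Whitney AUC. Quasi-complete separation is detected (diverging
#' coefficients / saturated fitted probabilities) and flagged on the
#' returned object rather than raised.
#'
#' @param data data.frame containing the outcome and predictors (e.g. from
#'   [build_feature_table()]).
#' @param predictors character vector of predictor column names; may be
#'   empty for an intercept-only model.
#' @param y name of the 0/1 outcome column (default "y").
#' @param cutoff classification cutoff on the predicted probability
#'   (default 0.5).
#' @return object of class `wdc_logit`.
#' @seealso [backward_stepwise()], [fit_indices()], [hosmer_lemeshow()],
#'   [classification_table()], [roc_auc()]
#' @export
fit_logistic <- function(data, predictors, y = "y", cutoff = 0.5) {
  stopifnot(is.data.frame(data), y %in% names(data))
  yy <- data[[y]]
  if (any(is.na(yy)) || !all(yy %in% c(0, 1))) {
    stop("fit_logistic: outcome must be 0/1 with no missing values")
  }
  if (length(unique(yy)) < 2L) stop("fit_logistic: constant outcome")
  missing <- setdiff(predictors, names(data))
  if (length(missing)) {
    stop("fit_logistic: unknown predictor(s): ", paste(missing, collapse = ", "))
  }
  n <- nrow(data)
  if (n <= length(predictors) + 1L) {
    stop("fit_logistic: need n > number of predictors + 1")
  }
  fml <- if (length(predictors)) {
    stats::reformulate(predictors, response = y)
  } else {
    stats::as.formula(paste(y, "~ 1"))
  }
  fit <- suppressWarnings(
    stats::glm(fml, data = data, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)))
  p_hat <- stats::fitted(fit)
  separation <- !fit$converged ||
    any(abs(stats::coef(fit)[-1]) > 15) ||
    any(p_hat > 1 - 1e-8 | p_hat < 1e-8)

  ll1 <- as.numeric(stats::logLik(fit))
  ll0 <- sum(yy * log(mean(yy)) + (1 - yy) * log(1 - mean(yy)))
  idx <- fit_indices(ll0, ll1, n)

  sm <- summary(fit)$coefficients
  coefs <- data.frame(term = rownames(sm), B = sm[, 1], SE = sm[, 2],
                      wald_z = sm[, 3], p = sm[, 4],
                      row.names = NULL, stringsAsFactors = FALSE)

  hl <- if (length(predictors)) hosmer_lemeshow(p_hat, yy) else
    list(C = NA_real_, p = NA_real_, table = NULL, n_groups = 0L)
  structure(list(
    call = match.call(), formula = fml, glm = fit,
    predictors = predictors, outcome_coding = paste0("1 = seizure-free (", y, ")"),
    coefficients = coefs,
    ll0 = ll0, ll1 = ll1,
    chisq = idx$chisq, model_df = length(predictors),
    model_p = if (length(predictors))
      stats::pchisq(idx$chisq, df = length(predictors), lower.tail = FALSE)
    else NA_real_,
    r2_coxsnell = idx$r2_coxsnell, r2_nagelkerke = idx$r2_nagelkerke,
    hosmer_lemeshow = hl,
    fitted = p_hat, y = yy, cutoff = cutoff,
    classification = classification_table(p_hat, yy, cutoff),
    roc = roc_auc(p_hat, yy),
    separation = separation, converged = fit$converged,
    removal_log = NULL), class = "wdc_logit")
}

#' Backward-stepwise predictor elimination by likelihood-ratio test
#'
#' Starts from the full predictor set and repeatedly refits reduced models,
#' removing the predictor whose likelihood-ratio removal test has the
#' largest p-value while that p exceeds `p_remove` (default 0.10, the
#' conventional backward-LR criterion); stops when every remaining
#' predictor's removal p is at or below the criterion, or no predictors
#' remain.
#'
#' @inheritParams fit_logistic
#' @param p_remove p-to-remove threshold (default 0.10).
#' @return a `wdc_logit` for the final model, with `removal_log` recording
#'   each eliminated predictor and its removal p.
#' @export
backward_stepwise <- function(data, predictors, y = "y", p_remove = 0.10,
                              cutoff = 0.5) {
  current <- predictors
  log_rows <- list()
  # removal tests only need the reduced log-likelihood, so intermediate
  # refits skip the full clinical report
  ll_of <- function(preds) {
    fml <- if (length(preds)) stats::reformulate(preds, response = y)
           else stats::as.formula(paste(y, "~ 1"))
    fit <- suppressWarnings(
      stats::glm(fml, data = data, family = stats::binomial(),
                 control = stats::glm.control(epsilon = 1e-8, maxit = 100)))
    as.numeric(stats::logLik(fit))
  }
  ll_current <- ll_of(current)
  step <- 0L
  while (length(current)) {
    pvals <- vapply(current, function(pr) {
      stats::pchisq(2 * (ll_current - ll_of(setdiff(current, pr))),
                    df = 1L, lower.tail = FALSE)
    }, numeric(1))
    worst <- which.max(pvals)
    if (pvals[worst] <= p_remove) break
    step <- step + 1L
    log_rows[[step]] <- data.frame(step = step, removed = current[worst],
                                   p_removal = unname(pvals[worst]),
                                   stringsAsFactors = FALSE)
    current <- current[-worst]
    ll_current <- ll_of(current)
  }
  fit <- fit_logistic(data, current, y = y, cutoff = cutoff)
  fit$removal_log <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(step = integer(0), removed = character(0),
               p_removal = numeric(0))
  fit$call <- match.call()
  fit
}

#' Likelihood-based fit indices
#'
#' @param ll0 intercept-only log-likelihood.
#' @param ll1 model log-likelihood (>= ll0).
#' @param n sample size.
#' @return list: `chisq` = -2(ll0 - ll1), `r2_coxsnell` = 1 - exp(-chisq/n),
#'   `r2_nagelkerke` = Cox-Snell / (1 - exp(2 ll0 / n)).
#' @export
fit_indices <- function(ll0, ll1, n) {
  stopifnot(n >= 1)
  if (ll1 < ll0 - 1e-8) stop("fit_indices: ll1 < ll0")
  chisq <- max(0, -2 * (ll0 - ll1))
  cs <- 1 - exp(-chisq / n)
  max_cs <- 1 - exp(2 * ll0 / n)
  ng <- if (max_cs > 0) cs / max_cs else 0
  list(chisq = chisq, r2_coxsnell = cs, r2_nagelkerke = ng)
}

#' Hosmer-Lemeshow calibration statistic
#'
#' Deciles-of-risk grouping: subjects are sorted by predicted probability
#' and split into `n_groups` near-equal groups with tied probabilities kept
#' together (the effective group count drops to the number of distinct
#' probabilities when fewer). C sums (observed - expected)^2 / expected
#' over both outcomes in every group; p comes from chi-square with
#' groups - 2 df.
#'
#' @param p_hat predicted probabilities in (0,1).
#' @param y 0/1 outcomes.
#' @param n_groups target group count (default 10).
#' @return list: `C`, `p` (NA with a warning when < 3 effective groups),
#'   `n_groups` (effective), `table` (per-group observed/expected).
#' @export
hosmer_lemeshow <- function(p_hat, y, n_groups = 10L) {
  stopifnot(length(p_hat) == length(y), all(p_hat > 0 & p_hat < 1))
  n <- length(y)
  ord <- order(p_hat)
  ps <- p_hat[ord]; ys <- y[ord]
  distinct <- unique(ps)
  k <- min(n_groups, length(distinct))
  if (k == length(distinct)) {
    grp <- match(ps, distinct)
  } else {
    # quantile bins on sorted order; ties share the bin of their first member
    bin <- ceiling(seq_len(n) / (n / k))
    grp <- stats::ave(bin, match(ps, distinct), FUN = function(b) b[1])
    grp <- match(grp, sort(unique(grp)))
  }
  tab <- do.call(rbind, lapply(sort(unique(grp)), function(g) {
    sel <- grp == g
    data.frame(group = g, n = sum(sel), obs1 = sum(ys[sel]),
               exp1 = sum(ps[sel]), mean_p = mean(ps[sel]))
  }))
  eff <- nrow(tab)
  exp0 <- tab$n - tab$exp1
  obs0 <- tab$n - tab$obs1
  C <- sum((tab$obs1 - tab$exp1)^2 / tab$exp1 + (obs0 - exp0)^2 / exp0)
  if (eff < 3L) {
    warning("hosmer_lemeshow: only ", eff,
            " effective group(s); p-value suppressed")
    p <- NA_real_
  } else {
    p <- stats::pchisq(C, df = eff - 2L, lower.tail = FALSE)
  }
  list(C = C, p = p, n_groups = eff, table = tab)
}

#' Classification table at a probability cutoff
#'
#' @param p_hat predicted probabilities.
#' @param y 0/1 outcomes.
#' @param cutoff predicted class is 1 iff p_hat >= cutoff (default 0.5).
#' @return list: `overall_pct`, `pct_class1`, `pct_class0` (percent correct),
#'   `table` (2x2 observed x predicted counts).
#' @export
classification_table <- function(p_hat, y, cutoff = 0.5) {
  stopifnot(cutoff > 0, cutoff < 1, length(p_hat) == length(y))
  pred <- as.integer(p_hat >= cutoff)
  tab <- table(observed = factor(y, levels = 0:1),
               predicted = factor(pred, levels = 0:1))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  list(overall_pct = 100 * mean(pred == y),
       pct_class1 = if (n1) 100 * sum(pred == 1 & y == 1) / n1 else NA_real_,
       pct_class0 = if (n0) 100 * sum(pred == 0 & y == 0) / n0 else NA_real_,
       table = tab)
}

#' ROC curve and Mann-Whitney AUC
#'
#' The AUC is the Mann-Whitney concordance probability (ties credited 0.5);
#' the curve enumerates all distinct score cutoffs, for which the
#' trapezoidal integral equals the Mann-Whitney form exactly.
#'
#' @param p_hat scores (higher = more likely class 1).
#' @param y 0/1 outcomes, both classes present.
#' @return object of class `roc_result`: list with `curve` (data.frame:
#'   cutoff, sensitivity, specificity) and `auc`.
#' @export
roc_auc <- function(p_hat, y) {
  stopifnot(length(p_hat) == length(y))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L) stop("roc_auc: both classes must be present")
  r <- rank(p_hat)                     # average ranks give the 0.5 tie credit
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  cuts <- c(Inf, sort(unique(p_hat), decreasing = TRUE))
  curve <- do.call(rbind, lapply(cuts, function(cc) {
    pred <- p_hat >= cc
    data.frame(cutoff = cc,
               sensitivity = sum(pred & y == 1) / n1,
               specificity = sum(!pred & y == 0) / n0)
  }))
  structure(list(curve = curve, auc = auc), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("ROC:", nrow(x$curve), "operating points, AUC =",
      sprintf("%.3f", x$auc), "\n")
  invisible(x)
}

# ---- wdc_logit methods ------------------------------------------------------

#' @export
print.wdc_logit <- function(x, digits = 3, ...) {
  cat("Logistic outcome model (", x$outcome_coding, ")\n", sep = "")
  if (length(x$predictors)) {
    cat("Predictors retained:", paste(x$predictors, collapse = ", "), "\n")
  } else {
    cat("Intercept-only model\n")
  }
  if (!is.null(x$removal_log) && nrow(x$removal_log)) {
    cat("Removed (backward LR):",
        paste(x$removal_log$removed, collapse = " -> "), "\n")
  }
  cat(sprintf("Model X2 = %.*f on %d df (p = %.3g); Cox-Snell R2 = %.*f, Nagelkerke R2 = %.*f\n",
              digits, x$chisq, x$model_df, x$model_p,
              digits, x$r2_coxsnell, digits, x$r2_nagelkerke))
  if (!is.na(x$hosmer_lemeshow$C)) {
    cat(sprintf("Hosmer-Lemeshow C = %.*f (%d groups, p = %.3g)\n",
                digits, x$hosmer_lemeshow$C, x$hosmer_lemeshow$n_groups,
                x$hosmer_lemeshow$p))
  }
  cl <- x$classification
  cat(sprintf("Classified correctly: %.1f%% overall (%.1f%% seizure-free, %.1f%% not); AUC = %.3f\n",
              cl$overall_pct, cl$pct_class1, cl$pct_class0, x$roc$auc))
  if (x$separation) cat("NOTE: quasi-complete separation flagged; Wald statistics unreliable\n")
  invisible(x)
}

#' @export
summary.wdc_logit <- function(object, ...) {
  print(object)
  cat("\nCoefficients:\n")
  print(object$coefficients, digits = 4, row.names = FALSE)
  invisible(object)
}

#' @export
coef.wdc_logit <- function(object, ...) stats::coef(object$glm)

#' @export
predict.wdc_logit <- function(object, newdata = NULL,
                              type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    if (type == "response") object$fitted else stats::predict(object$glm)
  } else {
    stats::predict(object$glm, newdata = newdata, type = type)
  }
}

#' @export
residuals.wdc_logit <- function(object, type = "deviance", ...) {
  stats::residuals(object$glm, type = type)
}

#' @export
plot.wdc_logit <- function(x, ...) {
  cv <- x$roc$curve
  plot(1 - cv$specificity, cv$sensitivity, type = "s",
       xlab = "1 - specificity", ylab = "sensitivity",
       main = sprintf("ROC (AUC = %.3f)", x$roc$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}
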