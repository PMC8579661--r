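#' Crawford-Howell single-case t-test
#'
#' Compares one observation x with a small control sample (mean x̄, sd s,
#' size N):
#' \deqn{t = \frac{x - \bar{x}}{s \sqrt{(N+1)/N}}, \quad df = N - 1}
#' with a two-tailed p from the t distribution. The statistic treats the
#' case as a sample of one, so the control sd enters inflated by
#' sqrt((N+1)/N) — the canonical "modified t-test" for single-case
#' normative comparison.
#'
#' @param case_value scalar (or vector, tested element-wise against the same
#'   controls).
#' @param control_values numeric vector, length N >= 2, sd > 0.
#' @return list with `t`, `p` (two-tailed), `df`.
#' @examples
#' crawford_t(2, rnorm(18))
#' @export
crawford_t <- function(case_value, control_values) {
  n <- length(control_values)
  if (n < 2L) stop("crawford_t: need at least 2 controls")
  s <- stats::sd(control_values)
  if (!is.finite(s) || s == 0) stop("crawford_t: zero control variance")
  tval <- (case_value - mean(control_values)) / (s * sqrt((n + 1) / n))
  list(t = tval, p = 2 * stats::pt(-abs(tval), df = n - 1L), df = n - 1L)
}

#' Voxel-wise Crawford map of one patient against the normative sample
#'
#' Applies the Crawford-Howell test at every in-mask voxel of a patient's
#' standardized wDC map against the N control maps.
#'
#' @param case_map a `wdc_map` (z present) or 3D array.
#' @param controls list of control `wdc_map`s (or 3D arrays) on the same
#'   grid.
#' @param mask logical 3D array; defaults to the case map's mask.
#' @return object of class `crawford_map`: list with `t` and `p` 3D arrays
#'   (0 / 1 outside the mask), `df`, `n_controls`, `mask`.
#' @export
crawford_map <- function(case_map, controls, mask = NULL) {
  get_z <- function(m) {
    if (inherits(m, "wdc_map")) {
      if (is.null(m$z)) stop("crawford_map: wdc_map not standardized")
      m$z
    } else {
      m
    }
  }
  case <- get_z(case_map)
  if (is.null(mask)) {
    mask <- if (inherits(case_map, "wdc_map")) case_map$mask else array(TRUE, dim(case))
  }
  ctl <- lapply(controls, get_z)
  n <- length(ctl)
  if (n < 2L) stop("crawford_map: need at least 2 control maps")
  for (m in ctl) {
    if (!all(dim(m) == dim(case))) stop("crawford_map: grid mismatch between case and controls")
  }
  stopifnot(all(dim(mask) == dim(case)))
  idx <- which(mask)
  C <- vapply(ctl, function(m) m[idx], numeric(length(idx)))   # vox x N
  mu <- rowMeans(C)
  sdc <- sqrt(rowSums((C - mu)^2) / (n - 1))
  if (any(sdc == 0)) stop("crawford_map: zero control variance at ",
                          sum(sdc == 0), " voxel(s)")
  tv <- (case[idx] - mu) / (sdc * sqrt((n + 1) / n))
  pv <- 2 * stats::pt(-abs(tv), df = n - 1L)
  tarr <- array(0, dim = dim(case)); tarr[idx] <- tv
  parr <- array(1, dim = dim(case)); parr[idx] <- pv
  structure(list(t = tarr, p = parr, df = n - 1L, n_controls = n, mask = mask),
            class = "crawford_map")
}

#' @export
print.crawford_map <- function(x, ...) {
  cat("crawford_map:", paste(dim(x$t), collapse = " x "), "grid,",
      x$n_controls, "controls (df =", x$df, "), max |t| =",
      signif(max(abs(x$t[x$mask])), 4), "\n")
  invisible(x)
}

#' Summarize a Crawford map over one ROI
#'
#' A voxel counts as a significant *increase* iff its two-tailed p < alpha
#' and t > 0. The ROI indicator is 1 iff at least one such voxel lies in the
#' ROI; the significant-voxel count is kept as a companion covariate.
#'
#' @param cmap a `crawford_map`.
#' @param roi logical 3D array (ROI voxel mask).
#' @param alpha significance threshold on the two-tailed p (default 0.005).
#' @param direction only `"increase"` is used by the pipeline; `"decrease"`
#'   counts t < 0 voxels instead.
#' @return list with `indicator` (0/1), `n_sig`, `n_roi`.
#' @export
summarize_roi <- function(cmap, roi, alpha = 0.005,
                          direction = c("increase", "decrease")) {
  direction <- match.arg(direction)
  stopifnot(inherits(cmap, "crawford_map"), alpha > 0, alpha < 1)
  stopifnot(all(dim(roi) == dim(cmap$t)))
  n_roi <- sum(roi)
  if (n_roi == 0L) stop("summarize_roi: empty ROI")
  sig <- cmap$p < alpha & (if (direction == "increase") cmap$t > 0 else cmap$t < 0)
  n_sig <- sum(sig & roi)
  list(indicator = as.integer(n_sig >= 1L), n_sig = n_sig, n_roi = n_roi)
}

#' Per-patient ROI summary table
#'
#' @param cmap a `crawford_map` for one patient.
#' @param atlas a `label_atlas`.
#' @param patient_side `"left"` or `"right"` (resection side).
#' @param alpha voxel-level significance threshold (default 0.005).
#' @return data.frame with one row per ROI: roi, side, indicator, n_sig,
#'   n_roi.
#' @export
summarize_patient <- function(cmap, atlas, patient_side, alpha = 0.005) {
  rois <- resolve_rois(atlas, patient_side)
  rows <- lapply(names(rois), function(key) {
    r <- rois[[key]]
    s <- summarize_roi(cmap, roi_mask(atlas, r), alpha = alpha)
    data.frame(roi = r$name, side = r$side, indicator = s$indicator,
               n_sig = s$n_sig, n_roi = s$n_roi, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cohort tabulation of increased-wDC indicators
#'
#' Counts, per ROI and outcome group, how many patients show an increased
#' weighted degree (indicator 1) versus not, with percentages to one
#' decimal — the cohort summary layout of the study.
#'
#' @param summaries named list (by patient id) of [summarize_patient()]
#'   data.frames.
#' @param patient_table data.frame with columns id and outcome
#'   (`"SF"`/`"nonSF"`).
#' @param subset optional character vector of patient ids to restrict to
#'   (e.g. a pathology subgroup).
#' @return data.frame: roi, side, group, n_group, n_increased,
#'   pct_increased, n_not_increased, pct_not_increased.
#' @export
tabulate_cohort <- function(summaries, patient_table, subset = NULL) {
  ids <- names(summaries)
  if (!setequal(ids, patient_table$id)) {
    stop("tabulate_cohort: patient ids in summaries and patient_table differ")
  }
  if (!is.null(subset)) ids <- intersect(ids, subset)
  long <- do.call(rbind, lapply(ids, function(id) {
    cbind(id = id, summaries[[id]],
          outcome = patient_table$outcome[patient_table$id == id],
          stringsAsFactors = FALSE)
  }))
  groups <- list(All = ids,
                 SF = ids[vapply(ids, function(i)
                   patient_table$outcome[patient_table$id == i] == "SF", TRUE)],
                 nonSF = ids[vapply(ids, function(i)
                   patient_table$outcome[patient_table$id == i] == "nonSF", TRUE)])
  combos <- unique(long[, c("roi", "side")])
  out <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    do.call(rbind, lapply(names(groups), function(g) {
      sel <- long$roi == combos$roi[i] & long$side == combos$side[i] &
        long$id %in% groups[[g]]
      n <- sum(sel)
      inc <- sum(long$indicator[sel] == 1L)
      data.frame(roi = combos$roi[i], side = combos$side[i], group = g,
                 n_group = n, n_increased = inc,
                 pct_increased = round(100 * inc / max(n, 1L), 1),
                 n_not_increased = n - inc,
                 pct_not_increased = round(100 * (n - inc) / max(n, 1L), 1),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Build the outcome-model feature table
#'
#' Joins the six ROI indicators and significant-voxel counts of every
#' patient with the binary surgical outcome (1 = seizure-free).
#'
#' @inheritParams tabulate_cohort
#' @return data.frame: id, y, ind_<roi>_<side> (6), nvox_<roi>_<side> (6).
#' @export
build_feature_table <- function(summaries, patient_table) {
  ids <- patient_table$id
  if (!setequal(names(summaries), ids)) {
    stop("build_feature_table: patient ids mismatch")
  }
  rows <- lapply(ids, function(id) {
    s <- summaries[[id]]
    key <- paste(s$roi, s$side, sep = "_")
    v <- c(s$indicator, s$n_sig)
    names(v) <- c(paste0("ind_", key), paste0("nvox_", key))
    as.data.frame(as.list(v))
  })
  feats <- do.call(rbind, rows)
  data.frame(id = ids, y = as.integer(patient_table$outcome == "SF"),
             feats, stringsAsFactors = FALSE)
}
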