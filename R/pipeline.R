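#' Pipeline configuration
#'
#' Assembles and validates the configuration for an end-to-end run. Two
#' entry modes: `simulate` (a [sim_config()]; the cohort is generated) or
#' `paths` (a named list pointing at existing files: `volumes` — named
#' character vector of 4D NIfTI paths, `mask`, `atlas`, `label_table`,
#' `confounds` — named TSV paths aligned with `volumes`, `patient_table` —
#' CSV with id/side/outcome; control subjects are those absent from the
#' patient table).
#'
#' @param simulate optional [sim_config()].
#' @param paths optional list of input paths (see above).
#' @param out_dir output directory.
#' @param drop_volumes,band,poly_order preprocessing parameters.
#' @param r_threshold,fwhm,block_size wDC parameters.
#' @param alpha Crawford voxel significance threshold (default 0.005).
#' @param p_remove backward-stepwise removal criterion (default 0.10).
#' @param cutoff classification cutoff (default 0.5).
#' @param run_groupstats run the two-sample patients-vs-controls cluster
#'   analysis (default FALSE).
#' @param p_form,k_min,n_perm,connectivity cluster-inference parameters.
#' @param seed master seed.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = NULL, paths = NULL, out_dir,
                            drop_volumes = 5L, band = c(0.01, 0.1),
                            poly_order = 1L, r_threshold = 0.25, fwhm = 8,
                            block_size = 2048L, alpha = 0.005,
                            p_remove = 0.10, cutoff = 0.5,
                            run_groupstats = FALSE, p_form = 0.005,
                            k_min = 20L, n_perm = 500L, connectivity = 18L,
                            seed = 1L) {
  if (is.null(simulate) == is.null(paths)) {
    stop("pipeline_config: give exactly one of 'simulate' or 'paths'")
  }
  if (!is.null(simulate)) stopifnot(inherits(simulate, "sim_config"))
  if (!is.null(paths)) {
    need <- c("volumes", "mask", "atlas", "label_table", "confounds",
              "patient_table")
    missing_fields <- setdiff(need, names(paths))
    if (length(missing_fields)) {
      stop("pipeline_config: paths is missing ", paste(missing_fields, collapse = ", "))
    }
    all_files <- c(paths$volumes, paths$mask, paths$atlas, paths$label_table,
                   paths$confounds, paths$patient_table)
    absent <- all_files[!file.exists(all_files)]
    if (length(absent)) {
      stop("pipeline_config: file(s) not found: ", paste(absent, collapse = ", "))
    }
  }
  stopifnot(drop_volumes >= 0, band[1] >= 0, band[1] < band[2],
            r_threshold > 0, r_threshold < 1, fwhm >= 0,
            alpha > 0, alpha < 1, p_remove > 0, p_remove < 1,
            cutoff > 0, cutoff < 1, p_form > 0, p_form < 1, k_min >= 1)
  structure(list(simulate = simulate, paths = paths, out_dir = out_dir,
                 drop_volumes = as.integer(drop_volumes), band = band,
                 poly_order = as.integer(poly_order),
                 r_threshold = r_threshold, fwhm = fwhm,
                 block_size = as.integer(block_size), alpha = alpha,
                 p_remove = p_remove, cutoff = cutoff,
                 run_groupstats = run_groupstats, p_form = p_form,
                 k_min = as.integer(k_min), n_perm = as.integer(n_perm),
                 connectivity = as.integer(connectivity),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

.load_inputs <- function(config) {
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    sim$seed <- config$seed
    cohort <- simulate_cohort(sim)
    atlas <- cohort$atlas
    list(atlas = atlas, mask = atlas_mask(atlas),
         subjects = c(cohort$controls, cohort$patients),
         patient_table = cohort$patient_table,
         ground_truth = cohort$ground_truth)
  } else {
    p <- config$paths
    atlas_img <- read_nifti(p$atlas)
    tab <- read_label_table(p$label_table)
    atlas <- structure(list(labels = array(as.integer(round(atlas_img$data)),
                                           dim = dim(atlas_img$data)),
                            affine = atlas_img$affine,
                            voxel_size = sqrt(colSums(atlas_img$affine[1:3, 1:3]^2)),
                            table = tab), class = "label_atlas")
    mask <- read_nifti(p$mask)$data > 0
    subjects <- lapply(names(p$volumes), function(id) {
      list(vol = read_volume4d(p$volumes[[id]]),
           confounds = utils::read.table(p$confounds[[id]], sep = "\t",
                                         header = TRUE))
    })
    names(subjects) <- names(p$volumes)
    list(atlas = atlas, mask = mask, subjects = subjects,
         patient_table = utils::read.csv(p$patient_table,
                                         stringsAsFactors = FALSE),
         ground_truth = NULL)
  }
}

#' Run the full connectivity-fingerprint pipeline
#'
#' Executes simulate/load, per-subject preprocessing, wDC mapping,
#' single-case normative comparison, cohort tabulation and the
#' backward-stepwise logistic outcome model (optionally the permutation
#' cluster group comparison), writing all artifacts plus a manifest of
#' parameters, seeds and output md5 hashes to `out_dir`. Re-running the
#' same configuration reproduces identical outputs and manifest hashes.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return (invisibly) list with `zmaps`, `summaries`, `cohort_table`,
#'   `features`, `model` (a `wdc_logit`), optional `groupstats`,
#'   `ground_truth`, `manifest`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message("[wdcfinger] ", ...)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  say("loading inputs")
  inp <- .load_inputs(config)
  atlas <- inp$atlas; mask <- inp$mask
  pt <- inp$patient_table
  control_ids <- setdiff(names(inp$subjects), pt$id)
  if (length(control_ids) < 2L) {
    stop("run_pipeline: need at least 2 control subjects")
  }

  say("preprocessing + wDC for ", length(inp$subjects), " subjects")
  zmaps <- lapply(inp$subjects, function(s) {
    v <- preprocess_subject(s$vol, s$confounds, mask,
                            drop_volumes = config$drop_volumes,
                            band = config$band,
                            poly_order = config$poly_order)
    wdc_map(v, mask, r_threshold = config$r_threshold, fwhm = config$fwhm,
            block_size = config$block_size)
  })

  say("normative comparison for ", nrow(pt), " patients")
  ctl_maps <- zmaps[control_ids]
  summaries <- lapply(pt$id, function(id) {
    cm <- crawford_map(zmaps[[id]], ctl_maps, mask)
    summarize_patient(cm, atlas, pt$side[pt$id == id], alpha = config$alpha)
  })
  names(summaries) <- pt$id

  cohort_table <- tabulate_cohort(summaries, pt)
  features <- build_feature_table(summaries, pt)

  say("outcome model (backward stepwise LR)")
  pred_cols <- grep("^(ind|nvox)_", names(features), value = TRUE)
  # predictors constant across patients carry no information and break the fit
  usable <- pred_cols[vapply(features[pred_cols],
                             function(v) length(unique(v)) > 1L, TRUE)]
  if (length(setdiff(pred_cols, usable))) {
    say("dropping constant predictor(s): ",
        paste(setdiff(pred_cols, usable), collapse = ", "))
  }
  # tiny cohorts cannot support the full 12-column design: prefer the
  # indicator features, then truncate to keep the model identifiable
  max_p <- nrow(features) - 2L
  if (length(usable) > max_p) {
    usable <- usable[order(!startsWith(usable, "ind_"))]
    say("cohort of ", nrow(features), " supports at most ", max_p,
        " predictors; starting from: ",
        paste(utils::head(usable, max_p), collapse = ", "))
    usable <- utils::head(usable, max_p)
  }
  model <- if (length(unique(features$y)) < 2L) {
    warning("run_pipeline: single-class outcome; outcome model skipped")
    NULL
  } else {
    backward_stepwise(features, usable, p_remove = config$p_remove,
                      cutoff = config$cutoff)
  }

  gs <- NULL
  if (config$run_groupstats) {
    say("group comparison: patients vs controls (", config$n_perm, " permutations)")
    gs <- permutation_cluster_p(zmaps[pt$id], zmaps[control_ids], mask,
                                p_form = config$p_form, k_min = config$k_min,
                                n_perm = config$n_perm,
                                seed = config$seed + 1L,
                                connectivity = config$connectivity,
                                affine = atlas$affine)
  }

  say("writing artifacts to ", config$out_dir)
  outputs <- character(0)
  wout <- function(fn, name) { fn; outputs <<- c(outputs, name); name }
  for (id in names(zmaps)) {
    f <- file.path(config$out_dir, paste0(id, "_zwdc.nii.gz"))
    wout(write_nifti(zmaps[[id]]$z, f, atlas$affine), f)
  }
  f <- file.path(config$out_dir, "features.csv")
  wout(utils::write.csv(features, f, row.names = FALSE), f)
  f <- file.path(config$out_dir, "cohort_table.csv")
  wout(utils::write.csv(cohort_table, f, row.names = FALSE), f)
  if (!is.null(model)) {
    f <- file.path(config$out_dir, "model_coefficients.csv")
    wout(utils::write.csv(model$coefficients, f, row.names = FALSE), f)
    f <- file.path(config$out_dir, "roc_curve.csv")
    wout(utils::write.csv(model$roc$curve, f, row.names = FALSE), f)
    f <- file.path(config$out_dir, "model_report.txt")
    sink(f); print(model); sink()
    outputs <- c(outputs, f)
  }
  if (!is.null(gs)) {
    f <- file.path(config$out_dir, "clusters.csv")
    wout(utils::write.csv(gs$clusters, f, row.names = FALSE), f)
  }

  manifest <- list(
    package = "wdcfinger",
    version = as.character(utils::packageVersion("wdcfinger")),
    seed = config$seed,
    parameters = config[setdiff(names(config), c("simulate", "paths", "out_dir"))],
    outputs = as.list(tools::md5sum(sort(outputs))))
  mf <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  invisible(list(zmaps = zmaps, summaries = summaries,
                 cohort_table = cohort_table, features = features,
                 model = model, groupstats = gs,
                 ground_truth = inp$ground_truth, manifest = manifest,
                 atlas = atlas, mask = mask, patient_table = pt))
}
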