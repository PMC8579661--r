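#' Simulation configuration for synthetic resting-state cohorts
#'
#' Collects the generative parameters for a synthetic cohort of controls and
#' temporal-lobe epilepsy patients. Defaults mirror the acquisition the
#' pipeline targets: 110 volumes at TR = 2 s, 3x3x4 mm voxels, 18 controls
#' and 30 patients. Each voxel time series is
#' \deqn{x_v(t) = \lambda_v s_{R(v)}(t) + g(t) + \epsilon_v(t)}
#' with a latent unit-variance signal \eqn{s_R} shared within its atlas
#' region, a low-amplitude global signal \eqn{g}, and white noise. Voxels in
#' a patient's planted hub ROIs load with `lambda`; all other brain voxels
#' load with `baseline_lambda`. With `lambda = noise_sd` and no global
#' signal the expected within-hub voxel-pair correlation is
#' \eqn{\lambda^2/(\lambda^2 + \sigma^2) = 0.5}.
#'
#' @param grid_dims 3 positive integers, each >= 8.
#' @param n_volumes number of time points (>= 16; default 110).
#' @param tr repetition time in seconds (default 2).
#' @param voxel_size 3 voxel edge lengths in mm (default 3,3,4).
#' @param n_controls,n_patients cohort sizes (defaults 18 and 30).
#' @param hub_rois data.frame with columns `name` (mesial/pole/lateral),
#'   `side` (ipsilateral/contralateral), `lambda` (loading, >= 0) and `prob`
#'   (per-patient probability the hub is planted). Defaults plant
#'   ipsilateral mesial and temporal-pole hubs with lambda 1 at the observed
#'   cohort marginal rates (7/30 and 17/30).
#' @param baseline_lambda latent loading outside planted hubs (default 0.15,
#'   giving a true within-region correlation ~0.06 after band-passing — comfortably below the 0.25 degree threshold even with the ~0.16 sampling noise of 105 band-passed frames).
#' @param global_sd standard deviation of the shared global signal
#'   (default 0.05).
#' @param noise_sd white-noise standard deviation (default 1).
#' @param band_limited if TRUE (default) latent and global signals are
#'   pre-filtered to 0.01-0.1 Hz and re-scaled to unit variance, so the
#'   planted correlation structure survives the preprocessing band-pass.
#' @param outcome_coefs named numeric: `intercept` plus per-ROI coefficients
#'   on the true hub indicators, on the logit of P(seizure-free). Defaults:
#'   intercept -2.5, mesial_ipsilateral +2.88, pole_ipsilateral +2.91 —
#'   the expected seizure-free fraction under the default hub rates is then
#'   ~14/30.
#' @param seed integer master seed; per-subject substreams are derived from
#'   it so any subject is reproducible in isolation.
#' @return a `sim_config` list.
#' @export
sim_config <- function(grid_dims = c(24, 24, 16),
                       n_volumes = 110L,
                       tr = 2,
                       voxel_size = c(3, 3, 4),
                       n_controls = 18L,
                       n_patients = 30L,
                       hub_rois = data.frame(
                         name = c("mesial", "pole"),
                         side = "ipsilateral",
                         lambda = 1,
                         prob = c(7 / 30, 17 / 30),
                         stringsAsFactors = FALSE),
                       baseline_lambda = 0.15,
                       global_sd = 0.05,
                       noise_sd = 1,
                       band_limited = TRUE,
                       outcome_coefs = c(intercept = -2.5,
                                         mesial_ipsilateral = 2.88,
                                         pole_ipsilateral = 2.91),
                       seed = 1L) {
  grid_dims <- as.integer(grid_dims)
  n_volumes <- as.integer(n_volumes)
  stopifnot(length(grid_dims) == 3L, all(grid_dims >= 8L),
            n_volumes >= 16L, tr > 0, all(voxel_size > 0),
            n_controls >= 1L, n_patients >= 1L,
            noise_sd > 0, global_sd >= 0, baseline_lambda >= 0)
  stopifnot(is.data.frame(hub_rois),
            all(c("name", "side", "lambda", "prob") %in% names(hub_rois)),
            all(hub_rois$lambda >= 0),
            all(hub_rois$prob >= 0 & hub_rois$prob <= 1),
            all(hub_rois$name %in% .roi_names),
            all(hub_rois$side %in% c("ipsilateral", "contralateral")))
  stopifnot("intercept" %in% names(outcome_coefs))
  structure(list(grid_dims = grid_dims, n_volumes = n_volumes, tr = tr,
                 voxel_size = as.numeric(voxel_size),
                 n_controls = as.integer(n_controls),
                 n_patients = as.integer(n_patients),
                 hub_rois = hub_rois, baseline_lambda = baseline_lambda,
                 global_sd = global_sd, noise_sd = noise_sd,
                 band_limited = band_limited, outcome_coefs = outcome_coefs,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# latent generator: unit-variance series, optionally band-limited to the
# analysis band so the planted structure survives preprocessing
.latent_series <- function(n, tr, band_limited) {
  s <- stats::rnorm(n)
  if (band_limited) {
    s <- bandpass_series(s, tr, 0.01, 0.1)
    sdv <- stats::sd(s)
    if (sdv > 0) s <- s / sdv
  }
  s
}

#' Simulate one subject's 4D volume and confound table
#'
#' @param config a [sim_config()].
#' @param atlas a `label_atlas` on `config$grid_dims`.
#' @param hub_spec data.frame with columns `name` and `hemisphere`
#'   (left/right) and `lambda`, listing the ROI blocks planted as
#'   connectivity hubs for this subject; zero rows for a control.
#' @param seed integer substream seed for this subject.
#' @return list with `vol` (a `volume4d`) and `confounds` (data.frame with
#'   columns trans_x..rot_z, wm, csf; one row per volume).
#' @export
simulate_subject <- function(config, atlas, hub_spec = NULL, seed) {
  stopifnot(inherits(config, "sim_config"), inherits(atlas, "label_atlas"),
            all(dim(atlas$labels) == config$grid_dims))
  if (is.null(hub_spec)) {
    hub_spec <- data.frame(name = character(0), hemisphere = character(0),
                           lambda = numeric(0), stringsAsFactors = FALSE)
  }
  tab <- atlas$table
  hub_labels <- integer(0)
  hub_lambda <- numeric(0)
  if (nrow(hub_spec)) {
    for (i in seq_len(nrow(hub_spec))) {
      m <- tab$label[tab$name == hub_spec$name[i] &
                       tab$hemisphere == hub_spec$hemisphere[i]]
      if (!length(m)) {
        stop("simulate_subject: unknown ROI '", hub_spec$name[i], "' (",
             hub_spec$hemisphere[i], ") in hub_spec")
      }
      hub_labels <- c(hub_labels, m)
      hub_lambda <- c(hub_lambda, rep(hub_spec$lambda[i], length(m)))
    }
  }

  nt <- config$n_volumes
  set.seed(seed)
  labs <- atlas$labels
  brain <- which(labs > 0L)
  region_of <- labs[brain]
  region_ids <- sort(unique(region_of))

  latents <- vapply(region_ids, function(r)
    .latent_series(nt, config$tr, config$band_limited), numeric(nt))
  colnames(latents) <- as.character(region_ids)
  g <- if (config$global_sd > 0) {
    config$global_sd * .latent_series(nt, config$tr, config$band_limited)
  } else {
    numeric(nt)
  }

  lam <- rep(config$baseline_lambda, length(brain))
  if (length(hub_labels)) {
    idx <- match(region_of, hub_labels)
    hit <- !is.na(idx)
    lam[hit] <- hub_lambda[idx[hit]]
  }

  # nt x n_brain signal matrix: latent of each voxel's region times loading
  sig <- latents[, as.character(region_of), drop = FALSE]
  sig <- sweep(sig, 2L, lam, `*`) + g
  noise <- matrix(stats::rnorm(nt * length(brain), sd = config$noise_sd),
                  nrow = nt)
  series <- sig + noise

  data <- array(0, dim = c(config$grid_dims, nt))
  flat <- matrix(data, nrow = prod(config$grid_dims), ncol = nt)
  flat[brain, ] <- t(series)
  data <- array(flat, dim = c(config$grid_dims, nt))

  # slow-drift motion (random walks) and tissue regressor stand-ins
  rw <- function(scale) cumsum(stats::rnorm(nt, sd = scale))
  confounds <- data.frame(
    trans_x = rw(0.02), trans_y = rw(0.02), trans_z = rw(0.02),
    rot_x = rw(0.0005), rot_y = rw(0.0005), rot_z = rw(0.0005),
    wm = rw(0.05) + stats::rnorm(nt, sd = 0.1),
    csf = rw(0.05) + stats::rnorm(nt, sd = 0.1))

  list(vol = volume4d(data, atlas$affine, config$tr), confounds = confounds)
}

#' Simulate a full cohort with ground truth
#'
#' Controls carry only baseline loadings. Each patient gets a resection side
#' (alternating left/right), independently receives each hub in
#' `config$hub_rois` with its planting probability, and a seizure-free
#' outcome drawn from the logistic model in `config$outcome_coefs` applied to
#' the true hub indicators.
#'
#' @param config a [sim_config()].
#' @param atlas optional `label_atlas`; built from the config grid if NULL.
#' @param dir optional directory: when given, writes per-subject NIfTI
#'   volumes (`.nii.gz`), confound TSVs, the atlas + mask images, the label
#'   table TSV and the patient table CSV.
#' @param imaging if FALSE, skips time-series generation and returns only
#'   the patient table and ground truth (fast path for outcome-model
#'   studies).
#' @return list with `atlas`, `controls`, `patients` (lists of
#'   [simulate_subject()] outputs), `patient_table` (id, side, outcome
#'   SF/nonSF) and `ground_truth` (per-patient true indicators for all six
#'   ROIs, true probability, outcome).
#' @export
simulate_cohort <- function(config, atlas = NULL, dir = NULL, imaging = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(atlas)) atlas <- make_toy_atlas(config$grid_dims, config$voxel_size)

  set.seed(config$seed)
  n_subj <- config$n_controls + config$n_patients
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_subj)

  ids_pat <- sprintf("pat%02d", seq_len(config$n_patients))
  side <- rep(c("left", "right"), length.out = config$n_patients)

  hubs <- config$hub_rois
  roi_cols <- paste(rep(.roi_names, each = 2),
                    c("ipsilateral", "contralateral"), sep = "_")
  ind <- matrix(0L, nrow = config$n_patients, ncol = length(roi_cols),
                dimnames = list(ids_pat, roi_cols))
  for (j in seq_len(nrow(hubs))) {
    col <- paste(hubs$name[j], hubs$side[j], sep = "_")
    ind[, col] <- as.integer(stats::runif(config$n_patients) < hubs$prob[j])
  }
  coefs <- config$outcome_coefs
  eta <- rep(coefs[["intercept"]], config$n_patients)
  for (nm in setdiff(names(coefs), "intercept")) {
    if (!nm %in% roi_cols) stop("simulate_cohort: unknown coefficient ", nm)
    eta <- eta + coefs[[nm]] * ind[, nm]
  }
  prob_sf <- stats::plogis(eta)
  outcome <- ifelse(stats::runif(config$n_patients) < prob_sf, "SF", "nonSF")

  patient_table <- data.frame(id = ids_pat, side = side, outcome = outcome,
                              stringsAsFactors = FALSE)
  ground_truth <- data.frame(id = ids_pat, side = side,
                             as.data.frame(ind), prob_sf = prob_sf,
                             outcome = outcome, stringsAsFactors = FALSE)

  controls <- patients <- NULL
  if (imaging) {
    controls <- lapply(seq_len(config$n_controls), function(i)
      simulate_subject(config, atlas, NULL, sub_seeds[i]))
    names(controls) <- sprintf("ctl%02d", seq_len(config$n_controls))
    patients <- lapply(seq_len(config$n_patients), function(i) {
      planted <- ind[i, ] == 1L
      spec <- NULL
      if (any(planted)) {
        parts <- strsplit(roi_cols[planted], "_")
        hemi <- vapply(parts, function(p) {
          if (p[2] == "ipsilateral") side[i]
          else if (side[i] == "left") "right" else "left"
        }, "")
        nm <- vapply(parts, `[`, "", 1L)
        lam <- hubs$lambda[match(paste(nm, vapply(parts, `[`, "", 2L)),
                                 paste(hubs$name, hubs$side))]
        lam[is.na(lam)] <- max(hubs$lambda)
        spec <- data.frame(name = nm, hemisphere = hemi, lambda = lam,
                           stringsAsFactors = FALSE)
      }
      simulate_subject(config, atlas, spec, sub_seeds[config$n_controls + i])
    })
    names(patients) <- ids_pat
  }

  out <- list(atlas = atlas, controls = controls, patients = patients,
              patient_table = patient_table, ground_truth = ground_truth,
              config = config)
  if (!is.null(dir)) write_cohort(out, dir)
  invisible(out)
}

#' Write a simulated cohort to disk
#'
#' @param cohort output of [simulate_cohort()] (with imaging).
#' @param dir output directory, created if needed.
#' @export
write_cohort <- function(cohort, dir) {
  if (is.null(cohort$controls)) stop("write_cohort: cohort has no imaging data")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  atlas <- cohort$atlas
  write_nifti(atlas$labels, file.path(dir, "atlas.nii.gz"),
              atlas$affine, datatype = "int32")
  write_nifti(array(as.integer(atlas_mask(atlas)), dim = dim(atlas$labels)),
              file.path(dir, "mask.nii.gz"), atlas$affine, datatype = "int32")
  write_label_table(atlas, file.path(dir, "labels.tsv"))
  utils::write.csv(cohort$patient_table, file.path(dir, "patients.csv"),
                   row.names = FALSE)
  subjects <- c(cohort$controls, cohort$patients)
  for (id in names(subjects)) {
    s <- subjects[[id]]
    write_nifti(s$vol$data, file.path(dir, paste0(id, "_bold.nii.gz")),
                s$vol$affine, tr = s$vol$tr)
    utils::write.table(s$confounds, file.path(dir, paste0(id, "_confounds.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Fast ground-truth feature simulation for outcome-model studies
#'
#' Draws hub indicators and outcomes from the configured logistic model for
#' `n` hypothetical patients, without any imaging — used to study the
#' operating characteristics of the outcome model at sample sizes where
#' simulating images would be wasteful.
#'
#' @param n number of patients.
#' @param config a [sim_config()]; only `hub_rois` and `outcome_coefs` used.
#' @param seed integer seed.
#' @return data.frame: id, six `ind_*` indicator columns, prob_sf, y (1 =
#'   seizure-free).
#' @export
simulate_features <- function(n, config = sim_config(), seed = 1L) {
  set.seed(seed)
  roi_cols <- paste(rep(.roi_names, each = 2),
                    c("ipsilateral", "contralateral"), sep = "_")
  ind <- matrix(0L, nrow = n, ncol = length(roi_cols),
                dimnames = list(NULL, roi_cols))
  hubs <- config$hub_rois
  for (j in seq_len(nrow(hubs))) {
    col <- paste(hubs$name[j], hubs$side[j], sep = "_")
    ind[, col] <- as.integer(stats::runif(n) < hubs$prob[j])
  }
  coefs <- config$outcome_coefs
  eta <- rep(coefs[["intercept"]], n)
  for (nm in setdiff(names(coefs), "intercept")) {
    eta <- eta + coefs[[nm]] * ind[, nm]
  }
  prob_sf <- stats::plogis(eta)
  y <- as.integer(stats::runif(n) < prob_sf)
  out <- data.frame(id = sprintf("sim%04d", seq_len(n)), as.data.frame(ind),
                    prob_sf = prob_sf, y = y, stringsAsFactors = FALSE)
  names(out)[2:7] <- paste0("ind_", roi_cols)
  out
}
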