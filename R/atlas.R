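#' Toy temporal-lobe parcellation
#'
#' Builds a rectangular-block stand-in for an anatomical parcellation on a
#' small 3D grid: six temporal-lobe regions of interest ({mesial, pole,
#' lateral} x {left, right}) plus six mirror-symmetric "rest of brain" filler
#' blocks, with background 0. Left and right blocks are mirror images about
#' the mid-sagittal plane, so homologous regions have identical voxel counts.
#' The ROI blocks are separated by several voxels of non-ROI tissue so that
#' spatial smoothing of centrality maps does not bleed one ROI into another.
#'
#' The affine is RAS+ diagonal in the voxel sizes, origin at the grid centre,
#' applied to 0-based voxel indices.
#'
#' @param grid_dims integer vector of 3 voxel counts, each >= 8.
#' @param voxel_size numeric vector of 3 voxel edge lengths in mm
#'   (default `c(3, 3, 4)`).
#' @return An object of class `label_atlas`: list with `labels` (3D integer
#'   array), `affine`, `voxel_size`, and `table` (data.frame: label, name,
#'   hemisphere).
#' @examples
#' atl <- make_toy_atlas(c(24, 24, 16))
#' table(atl$labels[atl$labels > 0])
#' @export
make_toy_atlas <- function(grid_dims, voxel_size = c(3, 3, 4)) {
  grid_dims <- as.integer(grid_dims)
  stopifnot(length(grid_dims) == 3L, length(voxel_size) == 3L,
            all(voxel_size > 0))
  if (any(grid_dims < 8L)) {
    stop("make_toy_atlas: grid too small, need >= 8 voxels per axis to host ",
         "all ROI blocks (got ", paste(grid_dims, collapse = "x"), ")")
  }
  nx <- grid_dims[1]; ny <- grid_dims[2]; nz <- grid_dims[3]
  band <- function(lo, hi, n) {
    i <- (floor(lo * n) + 1L):ceiling(hi * n)
    i[i >= 1L & i <= n]
  }
  roi_x <- band(0.10, 0.26, nx)
  y_mes <- band(0.14, 0.30, ny)
  y_pol <- band(0.46, 0.62, ny)
  y_lat <- band(0.78, 0.94, ny)
  roi_z <- band(0.28, 0.55, nz)
  # filler blocks mirror the ROI columns higher up (2-voxel z gap when the
  # grid allows), keeping every region at the same spatial scale so no
  # region dominates the degree distribution by sheer partner count
  rest_z <- roi_z + (max(roi_z) - min(roi_z) + 3L)
  rest_z <- rest_z[rest_z <= nz]

  blocks <- list(
    mesial  = list(x = roi_x, y = y_mes, z = roi_z),
    pole    = list(x = roi_x, y = y_pol, z = roi_z),
    lateral = list(x = roi_x, y = y_lat, z = roi_z),
    rest_a  = list(x = roi_x, y = y_mes, z = rest_z),
    rest_b  = list(x = roi_x, y = y_pol, z = rest_z),
    rest_c  = list(x = roi_x, y = y_lat, z = rest_z)
  )
  bad <- names(blocks)[vapply(blocks, function(b)
    any(lengths(b) == 0L) || any(vapply(b, function(i) any(diff(i) < 0), TRUE)),
    TRUE)]
  if (length(bad)) {
    stop("make_toy_atlas: grid ", paste(grid_dims, collapse = "x"),
         " too small: empty block(s) ", paste(bad, collapse = ", "))
  }

  labels <- array(0L, dim = grid_dims)
  tab <- data.frame(label = integer(0), name = character(0),
                    hemisphere = character(0), stringsAsFactors = FALSE)
  lab <- 0L
  for (nm in names(blocks)) {
    b <- blocks[[nm]]
    for (hemi in c("left", "right")) {
      lab <- lab + 1L
      xs <- if (hemi == "left") b$x else nx + 1L - b$x
      if (any(labels[xs, b$y, b$z] != 0L)) {
        stop("make_toy_atlas: internal block overlap at label ", lab)
      }
      labels[xs, b$y, b$z] <- lab
      tab <- rbind(tab, data.frame(label = lab, name = nm, hemisphere = hemi,
                                   stringsAsFactors = FALSE))
    }
  }
  affine <- diag(c(voxel_size, 1))
  affine[1:3, 4] <- -voxel_size * (grid_dims - 1) / 2
  structure(list(labels = labels, affine = affine,
                 voxel_size = as.numeric(voxel_size), table = tab),
            class = "label_atlas")
}

#' @export
print.label_atlas <- function(x, ...) {
  cat("label_atlas:", paste(dim(x$labels), collapse = " x "),
      "grid,", nrow(x$table), "labelled blocks,",
      sum(x$labels > 0), "brain voxels\n")
  invisible(x)
}

#' Brain mask of an atlas
#'
#' @param atlas a `label_atlas`.
#' @return logical 3D array, TRUE where any label is assigned.
#' @export
atlas_mask <- function(atlas) {
  stopifnot(inherits(atlas, "label_atlas"))
  atlas$labels > 0L
}

.roi_names <- c("mesial", "pole", "lateral")

#' Resolve ipsi-/contralateral temporal ROIs for a patient
#'
#' Maps the six hemisphere-tagged temporal ROI blocks (mesial, temporal pole,
#' lateral temporal cortex, each left and right) to the ipsilateral /
#' contralateral frame of a given patient: ipsilateral is the side of the
#' planned resection.
#'
#' @param atlas a `label_atlas` (or any atlas-like list with `labels` and a
#'   `table` with columns label/name/hemisphere).
#' @param patient_side `"left"` or `"right"` — side of resection.
#' @return list of six `roi_definition` objects (fields: name, side, labels),
#'   named e.g. `"mesial_ipsilateral"`.
#' @export
resolve_rois <- function(atlas, patient_side = c("left", "right")) {
  patient_side <- match.arg(patient_side)
  tab <- atlas$table
  missing <- setdiff(.roi_names, tab$name)
  if (length(missing)) {
    stop("resolve_rois: atlas is missing ROI label(s): ",
         paste(missing, collapse = ", "))
  }
  contra <- if (patient_side == "left") "right" else "left"
  out <- list()
  for (nm in .roi_names) {
    for (side in c("ipsilateral", "contralateral")) {
      hemi <- if (side == "ipsilateral") patient_side else contra
      labs <- tab$label[tab$name == nm & tab$hemisphere == hemi]
      if (!length(labs)) {
        stop("resolve_rois: no ", hemi, " labels for ROI '", nm, "'")
      }
      out[[paste(nm, side, sep = "_")]] <-
        structure(list(name = nm, side = side, labels = labs),
                  class = "roi_definition")
    }
  }
  out
}

#' Voxel mask of one ROI definition
#'
#' @param atlas a `label_atlas`.
#' @param roi a `roi_definition` from [resolve_rois()].
#' @return logical 3D array.
#' @export
roi_mask <- function(atlas, roi) {
  stopifnot(inherits(roi, "roi_definition"))
  array(atlas$labels %in% roi$labels, dim = dim(atlas$labels))
}

#' Write / read the atlas label table as TSV
#'
#' @param atlas a `label_atlas`.
#' @param path TSV path (columns label, name, hemisphere).
#' @export
write_label_table <- function(atlas, path) {
  utils::write.table(atlas$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_label_table
#' @export
read_label_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
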