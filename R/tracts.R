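#' Threshold a probabilistic tract atlas into binary masks
#'
#' A voxel belongs to a tract mask when its membership probability is greater
#' than or equal to the threshold (inclusive comparison).
#'
#' @param atlas A [tract_atlas()].
#' @param threshold Probability threshold in (0, 1); default 0.1.
#' @return An object of class `tract_masks`: named list of logical 3D arrays
#'   plus the grid and threshold.
#' @export
binarize_atlas <- function(atlas, threshold = 0.1) {
  stopifnot(inherits(atlas, "tract_atlas"))
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must be in (0,1)", call. = FALSE)
  masks <- lapply(atlas$prob, function(p) p >= threshold)
  structure(
    list(masks = masks, grid = atlas$grid, threshold = threshold),
    class = "tract_masks"
  )
}

#' @export
print.tract_masks <- function(x, ...) {
  sz <- vapply(x$masks, sum, numeric(1))
  cat(sprintf("<tract_masks> threshold %g: %s\n", x$threshold,
              paste(sprintf("%s (%d vox)", names(sz), as.integer(sz)), collapse = ", ")))
  invisible(x)
}

#' Apply the tract-selection rule to voxelwise results
#'
#' For each tract, counts the significant voxels falling inside the tract
#' mask and the largest overlap of any single significant cluster with the
#' mask. A tract is selected when it contains more than `min_total`
#' significant voxels, or a single cluster overlapping it in more than
#' `min_cluster` voxels (both comparisons strict). Clusters are labelled on
#' the global significance mask and then intersected with each tract;
#' `recluster = TRUE` instead re-labels within each tract mask.
#'
#' @param fdr An `fdr_result` from [bh_fdr()] (or a logical significance
#'   array).
#' @param clusters A `cluster_labels` from [label_clusters()] on the same
#'   mask; computed automatically when `NULL`.
#' @param masks A `tract_masks` from [binarize_atlas()].
#' @param min_total Voxel-count threshold (strict >), default 50.
#' @param min_cluster Single-cluster overlap threshold (strict >), default 5.
#' @param connectivity Used when clusters must be (re)computed.
#' @param recluster Re-label clusters within each tract mask instead of
#'   intersecting global clusters.
#' @return A tibble of class `tract_summary`: one row per tract with
#'   `n_sig_voxels`, `largest_cluster`, `selected`; rule parameters are kept
#'   as attributes.
#' @export
tract_summary <- function(fdr, clusters = NULL, masks, min_total = 50,
                          min_cluster = 5, connectivity = 26,
                          recluster = FALSE) {
  stopifnot(inherits(masks, "tract_masks"))
  sig <- if (inherits(fdr, "fdr_result")) {
    stopifnot_same_grid(fdr$grid, masks$grid, "VLSM results and atlas")
    fdr$mask
  } else {
    if (!all(dim(fdr) == masks$grid$shape))
      stop("grid mismatch between significance mask and atlas", call. = FALSE)
    fdr != 0
  }
  if (is.null(clusters) && !recluster)
    clusters <- label_clusters(sig, connectivity)

  rows <- lapply(names(masks$masks), function(nm) {
    tm <- masks$masks[[nm]]
    inside <- sig & tm
    n_sig <- sum(inside)
    largest <- if (n_sig == 0) {
      0L
    } else if (recluster) {
      cl <- label_clusters(inside, connectivity)
      max(cl$sizes$n_voxels)
    } else {
      labs <- clusters$labels[inside]
      labs <- labs[labs > 0L]
      if (length(labs)) max(tabulate(labs)) else 0L
    }
    tibble::tibble(tract = nm, n_sig_voxels = as.integer(n_sig),
                   largest_cluster = as.integer(largest),
                   selected = n_sig > min_total || largest > min_cluster)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "min_total") <- min_total
  attr(out, "min_cluster") <- min_cluster
  attr(out, "recluster") <- recluster
  class(out) <- c("tract_summary", class(out))
  out
}

#' Per-patient regional lesion volumes within tracts
#'
#' The volume of each patient's lesions of each class falling inside each
#' binary tract mask, in ml of template space. Overlapping tract masks are
#' allowed; volumes are computed independently per tract.
#'
#' @param cohort A [lesion_cohort()].
#' @param masks A `tract_masks` from [binarize_atlas()].
#' @return A tibble with columns `patient_id`, `tract`, `class`, `volume_ml`.
#' @export
regional_volumes <- function(cohort, masks) {
  stopifnot(inherits(cohort, "lesion_cohort"), inherits(masks, "tract_masks"))
  stopifnot_same_grid(cohort$grid, masks$grid, "cohort and tract masks")
  vml <- voxel_volume_ml(cohort$grid)
  rows <- lapply(names(masks$masks), function(nm) {
    idx <- which(masks$masks[[nm]])
    lapply(c("wml", "ll"), function(cls) {
      counts <- if (length(idx)) {
        rowSums(cohort[[cls]][, idx, drop = FALSE])
      } else rep(0, cohort$n)
      tibble::tibble(patient_id = cohort$patient_ids, tract = nm, class = cls,
                     volume_ml = counts * vml)
    })
  })
  dplyr::bind_rows(unlist(rows, recursive = FALSE))
}
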