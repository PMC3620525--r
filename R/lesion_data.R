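#' Construct a lesion cohort
#'
#' Holds the binary white-matter-lesion (WML) and lacunar-lesion (LL) maps of
#' every patient on one shared voxel grid, stored as patients-by-voxels 0/1
#' matrices in array (column-major) voxel order.
#'
#' @param wml,ll Integer matrices, `n_patients` rows by `prod(grid$shape)`
#'   columns, values in \{0, 1\}.
#' @param patient_ids Character vector of unique patient identifiers.
#' @param grid The shared [voxel_grid()].
#'
#' @return An object of class `lesion_cohort`.
#' @export
lesion_cohort <- function(wml, ll, patient_ids, grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  n <- length(patient_ids)
  if (anyDuplicated(patient_ids))
    stop("duplicate patient_id: ",
         paste(unique(patient_ids[duplicated(patient_ids)]), collapse = ", "),
         call. = FALSE)
  V <- n_voxels(grid)
  for (nm in c("wml", "ll")) {
    m <- get(nm)
    if (!is.matrix(m) || nrow(m) != n || ncol(m) != V)
      stop("`", nm, "` must be an n_patients x n_voxels matrix", call. = FALSE)
    if (!all(m == 0L | m == 1L))
      stop("`", nm, "` maps must be strictly binary (0/1)", call. = FALSE)
  }
  structure(
    list(wml = wml, ll = ll, patient_ids = as.character(patient_ids),
         grid = grid, n = n),
    class = "lesion_cohort"
  )
}

#' @export
print.lesion_cohort <- function(x, ...) {
  v <- lesion_volumes(x)
  cat(sprintf("<lesion_cohort> %d patients; %d (%.0f%%) with >=1 LL\n",
              x$n, sum(v$ll_present), 100 * mean(v$ll_present)))
  print(x$grid)
  cat(sprintf("median WML volume %.2f ml, median LL volume (among LL patients) %.2f ml\n",
              stats::median(v$wml_volume_ml),
              if (any(v$ll_present == 1)) stats::median(v$ll_volume_ml[v$ll_present == 1]) else NA))
  invisible(x)
}

#' Read a cohort of co-registered binary lesion maps
#'
#' Loads per-patient WML and LL NIfTI volumes listed in a manifest. All
#' volumes must share one grid: dimensions must match exactly and the affines
#' stored in the headers must agree to within 1 mm/1e4 elementwise, otherwise
#' the offending patient is named. Maps must be strictly binary; no
#' resampling or binarization is performed.
#'
#' @param manifest Data frame with columns `patient_id`, `wml_path`, `ll_path`,
#'   or the path of a tab-separated file with those columns.
#' @param reference Spatial reference tag recorded on the grid.
#' @return A [lesion_cohort()].
#' @export
read_cohort <- function(manifest, reference = "template") {
  if (is.character(manifest) && length(manifest) == 1) {
    manifest <- utils::read.delim(manifest, stringsAsFactors = FALSE)
  }
  manifest <- as.data.frame(manifest)
  need <- c("patient_id", "wml_path", "ll_path")
  if (!all(need %in% names(manifest)))
    stop("manifest must have columns ", paste(need, collapse = ", "), call. = FALSE)
  if (anyDuplicated(manifest$patient_id))
    stop("duplicate patient_id in manifest: ",
         paste(unique(manifest$patient_id[duplicated(manifest$patient_id)]), collapse = ", "),
         call. = FALSE)
  n <- nrow(manifest)
  if (n < 1) stop("empty manifest", call. = FALSE)

  grid <- NULL
  ref_xform <- NULL
  wml <- NULL
  ll <- NULL
  for (i in seq_len(n)) {
    pid <- manifest$patient_id[i]
    for (cls in c("wml", "ll")) {
      path <- manifest[[paste0(cls, "_path")]][i]
      if (!file.exists(path))
        stop("patient ", pid, ": file not found: ", path, call. = FALSE)
      img <- RNifti::readNifti(path)
      a <- as.array(img)
      if (length(dim(a)) == 4 && dim(a)[4] == 1) a <- a[, , , 1]
      if (length(dim(a)) != 3)
        stop("patient ", pid, ": ", path, " is not a 3D volume", call. = FALSE)
      if (is.null(grid)) {
        grid <- voxel_grid(dim(a), RNifti::pixdim(img)[1:3], reference)
        ref_xform <- RNifti::xform(img)
        V <- n_voxels(grid)
        wml <- matrix(0L, n, V)
        ll <- matrix(0L, n, V)
      } else {
        if (!all(dim(a) == grid$shape))
          stop("patient ", pid, ": grid mismatch in ", path, call. = FALSE)
        if (max(abs(RNifti::xform(img) - ref_xform)) > 1e-4)
          stop("patient ", pid, ": affine mismatch in ", path,
               " (all volumes must be voxel-aligned; no resampling is done)",
               call. = FALSE)
      }
      vals <- as.vector(a)
      if (!all(vals %in% c(0, 1)))
        stop("non-binary values in ", path, " (patient ", pid,
             "); lesion maps must contain only 0 and 1", call. = FALSE)
      if (cls == "wml") wml[i, ] <- as.integer(vals) else ll[i, ] <- as.integer(vals)
    }
  }
  lesion_cohort(wml, ll, manifest$patient_id, grid)
}

#' Total normalized lesion volumes per patient
#'
#' Volumes are computed in the shared (template) grid: lesioned-voxel count
#' times voxel volume, reported in ml.
#'
#' @param cohort A [lesion_cohort()].
#' @return A tibble with columns `patient_id`, `wml_volume_ml`,
#'   `ll_volume_ml`, `ll_present` (0/1 indicator of any LL).
#' @export
lesion_volumes <- function(cohort) {
  stopifnot(inherits(cohort, "lesion_cohort"))
  vml <- voxel_volume_ml(cohort$grid)
  ll_n <- rowSums(cohort$ll)
  tibble::tibble(
    patient_id = cohort$patient_ids,
    wml_volume_ml = rowSums(cohort$wml) * vml,
    ll_volume_ml = ll_n * vml,
    ll_present = as.integer(ll_n > 0)
  )
}

#' Lesion prevalence map
#'
#' Per-voxel count of patients with a lesion of the given class.
#'
#' @param cohort A [lesion_cohort()].
#' @param class `"wml"` or `"ll"`.
#' @return An object of class `prevalence_map` with the 3D count array in
#'   `$counts`.
#' @export
prevalence_map <- function(cohort, class = c("wml", "ll")) {
  stopifnot(inherits(cohort, "lesion_cohort"))
  class <- match.arg(class)
  counts <- array(as.integer(colSums(cohort[[class]])), dim = cohort$grid$shape)
  structure(
    list(counts = counts, class = class, n_patients = cohort$n, grid = cohort$grid),
    class = "prevalence_map"
  )
}

#' @export
print.prevalence_map <- function(x, ...) {
  cat(sprintf("<prevalence_map> class %s, %d patients, max count %d, %d voxels affected\n",
              toupper(x$class), x$n_patients, max(x$counts), sum(x$counts > 0)))
  invisible(x)
}

#' Voxel eligibility mask
#'
#' Marks voxels affected in at least `min_patients` patients; voxels below the
#' threshold are not considered for voxelwise analysis. The comparison is
#' inclusive: a voxel affected in exactly `min_patients` patients is eligible.
#'
#' @param prev A [prevalence_map()].
#' @param min_patients Minimum number of affected patients (default 5).
#' @return An object of class `analysis_mask` with the logical 3D array in
#'   `$mask`.
#' @export
analysis_mask <- function(prev, min_patients = 5) {
  stopifnot(inherits(prev, "prevalence_map"))
  if (min_patients < 1) stop("min_patients must be >= 1", call. = FALSE)
  structure(
    list(mask = prev$counts >= min_patients,
         min_patients = as.integer(min_patients),
         class = prev$class, grid = prev$grid),
    class = "analysis_mask"
  )
}

#' @export
print.analysis_mask <- function(x, ...) {
  cat(sprintf("<analysis_mask> class %s, min_patients %d, %d eligible voxels\n",
              toupper(x$class), x$min_patients, sum(x$mask)))
  invisible(x)
}

# ---- NIfTI output helpers -------------------------------------------------

as_nifti_volume <- function(arr, grid) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- grid$voxel_size
  img
}

#' Write a 3D array as NIfTI on a cohort grid
#'
#' @param arr 3D array (numeric, integer or logical).
#' @param grid The [voxel_grid()] supplying voxel sizes.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param datatype NIfTI storage type, e.g. `"uint8"`, `"int16"`, `"float"`.
#' @return The path, invisibly.
#' @export
write_volume <- function(arr, grid, path, datatype = "auto") {
  if (is.logical(arr)) {
    arr <- array(as.integer(arr), dim = dim(arr))
    if (datatype == "auto") datatype <- "uint8"
  }
  RNifti::writeNifti(as_nifti_volume(arr, grid), path, datatype = datatype)
  invisible(path)
}

#' Write a simulated cohort to disk
#'
#' Per-patient uint8 NIfTI lesion maps (`<id>_wml.nii.gz`, `<id>_ll.nii.gz`),
#' per-tract atlas NIfTIs, tab-separated covariate and subtest tables keyed by
#' `patient_id`, a manifest readable by [read_cohort()], and a
#' `ground_truth.json` sidecar with the planted parameters.
#'
#' @param sim Result of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- sim$cohort
  grid <- cohort$grid
  rows <- lapply(seq_len(cohort$n), function(i) {
    pid <- cohort$patient_ids[i]
    wp <- file.path(dir, paste0(pid, "_wml.nii.gz"))
    lp <- file.path(dir, paste0(pid, "_ll.nii.gz"))
    write_volume(array(cohort$wml[i, ], grid$shape), grid, wp, "uint8")
    write_volume(array(cohort$ll[i, ], grid$shape), grid, lp, "uint8")
    data.frame(patient_id = pid, wml_path = wp, ll_path = lp)
  })
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  for (nm in names(sim$atlas$prob)) {
    write_volume(sim$atlas$prob[[nm]], grid,
                 file.path(dir, paste0("atlas_", nm, ".nii.gz")), "float")
  }
  utils::write.table(sim$covariates, file.path(dir, "covariates.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(sim$subtests, file.path(dir, "subtests.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(sim$ground_truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
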