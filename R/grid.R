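#' Define a shared voxel grid
#'
#' All lesion maps, atlas volumes and statistical maps in an analysis live on
#' one common grid: co-registration to that grid (e.g. a 2 mm template space)
#' is assumed to have happened upstream.
#'
#' @param shape Integer vector of length 3: array dimensions (i, j, k).
#' @param voxel_size Numeric vector of length 3: voxel edge lengths in mm.
#' @param reference Free-text tag naming the spatial reference (template name).
#'
#' @return An object of class `voxel_grid`.
#' @export
#' @examples
#' voxel_grid(c(48, 48, 24))
voxel_grid <- function(shape, voxel_size = c(2, 2, 2), reference = "synthetic-template") {
  shape <- as.integer(shape)
  voxel_size <- as.numeric(voxel_size)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("`shape` must be 3 positive integers", call. = FALSE)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("`voxel_size` must be 3 positive reals (mm)", call. = FALSE)
  structure(
    list(shape = shape, voxel_size = voxel_size, reference = as.character(reference)[1]),
    class = "voxel_grid"
  )
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf(
    "<voxel_grid> %d x %d x %d voxels, %.3g x %.3g x %.3g mm (%s)\n",
    x$shape[1], x$shape[2], x$shape[3],
    x$voxel_size[1], x$voxel_size[2], x$voxel_size[3], x$reference
  ))
  invisible(x)
}

n_voxels <- function(grid) prod(grid$shape)

# voxel volume in ml (1 ml = 1000 mm^3)
voxel_volume_ml <- function(grid) prod(grid$voxel_size) / 1000

same_grid <- function(a, b, tol = 1e-4) {
  identical(a$shape, b$shape) && all(abs(a$voxel_size - b$voxel_size) <= tol)
}

stopifnot_same_grid <- function(a, b, what = "volumes") {
  if (!same_grid(a, b))
    stop("grid mismatch: ", what, " must share one voxel grid", call. = FALSE)
  invisible(TRUE)
}

# linear voxel index -> (i, j, k); used for reporting cluster/voxel locations
voxel_coords <- function(idx, grid) {
  arrayInd(idx, .dim = grid$shape)
}
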