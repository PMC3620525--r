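# Separable truncated-Gaussian smoothing of 3D arrays, used by the synthetic
# white-matter-lesion field generator. The kernel is truncated at 4 sigma and
# applied by dense per-axis matrix multiplication, which is fast at the grid
# sizes used here (tens of voxels per axis).

gauss_kernel_matrix <- function(n, sigma) {
  d <- outer(seq_len(n), seq_len(n), "-")
  K <- exp(-0.5 * d^2 / sigma^2)
  K[abs(d) > ceiling(4 * sigma)] <- 0
  K
}

apply_along_axis <- function(arr, K, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  m <- K %*% matrix(a, nrow = d[axis])
  aperm(array(m, d[perm]), match(1:3, perm))
}

smooth_gaussian_3d <- function(arr, sigma, kernels = NULL) {
  d <- dim(arr)
  if (is.null(kernels)) kernels <- lapply(d, gauss_kernel_matrix, sigma = sigma)
  for (ax in 1:3) arr <- apply_along_axis(arr, kernels[[ax]], ax)
  arr
}

# Exact per-voxel standard deviation of smoothed iid N(0,1) noise. Because the
# kernel is separable, Var at voxel (i,j,k) = prod over axes of the row sums of
# the squared kernel matrices; dividing by this map makes the smoothed field
# marginally standard normal at every voxel, including near edges.
smoothed_sd_map <- function(shape, sigma, kernels = NULL) {
  if (is.null(kernels)) kernels <- lapply(shape, gauss_kernel_matrix, sigma = sigma)
  v <- lapply(kernels, function(K) rowSums(K^2))
  sqrt(outer(outer(v[[1]], v[[2]]), v[[3]]))
}

# Standard-normal marginal spatially correlated random field on `shape`.
standard_random_field <- function(shape, sigma, kernels = NULL, sd_map = NULL) {
  if (is.null(kernels)) kernels <- lapply(shape, gauss_kernel_matrix, sigma = sigma)
  if (is.null(sd_map)) sd_map <- smoothed_sd_map(shape, sigma, kernels)
  z <- array(stats::rnorm(prod(shape)), dim = shape)
  smooth_gaussian_3d(z, sigma, kernels) / sd_map
}
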