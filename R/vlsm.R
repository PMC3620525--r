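#' Voxelwise lesion-symptom t-map
#'
#' At every eligible voxel, compares the covariate-adjusted cognitive scores
#' of patients with versus without a lesion of the given class at that voxel,
#' using a pooled-variance (Student) two-sample t-test with
#' `df = n_lesioned + n_intact - 2`. The sign convention is
#' `t = (mean_intact - mean_lesioned) / pooled SE`, so t > 0 means lesioned
#' patients perform worse. By default p-values are one-sided in the deficit
#' direction (the direction that is subsequently thresholded); two-sided and
#' Welch variants are available.
#'
#' Voxels where the scores are constant within both groups (zero pooled
#' variance) have no defined t and are dropped from the map with a warning;
#' the count is recorded in the result.
#'
#' @param cohort A [lesion_cohort()].
#' @param residuals Data frame with `patient_id` and the adjusted score, e.g.
#'   one domain column of [residualize()] output.
#' @param mask An [analysis_mask()] marking eligible voxels.
#' @param class Lesion class, `"wml"` or `"ll"`.
#' @param score Name of the score column; defaults to the single non-id
#'   column.
#' @param alternative `"deficit"` (one-sided, lesioned worse) or
#'   `"two.sided"`.
#' @param var_equal Pooled-variance t if `TRUE` (default); Welch otherwise.
#' @return An object of class `tmap` holding per-voxel `t`, `df`, `p` (vectors
#'   over the retained eligible voxels, with `voxel` linear indices), the grid,
#'   and convention tags.
#' @export
voxelwise_t <- function(cohort, residuals, mask, class = c("wml", "ll"),
                        score = NULL, alternative = c("deficit", "two.sided"),
                        var_equal = TRUE) {
  stopifnot(inherits(cohort, "lesion_cohort"), inherits(mask, "analysis_mask"))
  class <- match.arg(class)
  alternative <- match.arg(alternative)
  stopifnot_same_grid(cohort$grid, mask$grid, "cohort and mask")
  residuals <- tibble::as_tibble(residuals)
  if (is.null(score)) {
    cand <- setdiff(names(residuals), "patient_id")
    if (length(cand) != 1)
      stop("`score` must name one of: ", paste(cand, collapse = ", "), call. = FALSE)
    score <- cand
  }
  idx <- match(cohort$patient_ids, residuals$patient_id)
  if (anyNA(idx))
    stop("residual scores do not cover all cohort patients", call. = FALSE)
  r <- as.numeric(residuals[[score]][idx])
  if (anyNA(r)) stop("missing scores for some cohort patients", call. = FALSE)

  vox <- which(mask$mask)
  if (length(vox) == 0)
    stop("analysis mask is empty; no eligible voxels", call. = FALSE)
  L <- cohort[[class]][, vox, drop = FALSE]
  storage.mode(L) <- "double"
  n <- cohort$n
  n1 <- colSums(L)                 # lesioned
  n0 <- n - n1                     # intact
  if (any(n1 < 2) || any(n0 < 2))
    stop("mask construction bug: an eligible voxel has fewer than 2 patients ",
         "in one group", call. = FALSE)

  s1 <- as.numeric(crossprod(L, r))
  q1 <- as.numeric(crossprod(L, r^2))
  s0 <- sum(r) - s1
  q0 <- sum(r^2) - q1
  m1 <- s1 / n1
  m0 <- s0 / n0
  ss1 <- pmax(q1 - n1 * m1^2, 0)
  ss0 <- pmax(q0 - n0 * m0^2, 0)

  if (var_equal) {
    df <- rep(n - 2, length(vox))
    sp2 <- (ss1 + ss0) / df
    se <- sqrt(sp2 * (1 / n0 + 1 / n1))
  } else {
    v1 <- ss1 / (n1 - 1)
    v0 <- ss0 / (n0 - 1)
    se <- sqrt(v1 / n1 + v0 / n0)
    df <- (v0 / n0 + v1 / n1)^2 /
      ((v0 / n0)^2 / (n0 - 1) + (v1 / n1)^2 / (n1 - 1))
  }

  ok <- se > 0
  n_dropped <- sum(!ok)
  if (n_dropped > 0)
    warning(n_dropped, " zero-variance voxel(s) dropped from the t-map")
  tstat <- (m0[ok] - m1[ok]) / se[ok]
  dfk <- df[ok]
  p <- if (alternative == "deficit") {
    stats::pt(tstat, dfk, lower.tail = FALSE)
  } else {
    2 * stats::pt(-abs(tstat), dfk)
  }

  structure(
    list(voxel = vox[ok], t = tstat, df = dfk, p = p,
         n_lesioned = n1[ok], n_intact = n0[ok],
         grid = cohort$grid, class = class, score = score,
         alternative = alternative, var_equal = var_equal,
         n_patients = n, n_dropped_zero_variance = n_dropped),
    class = "tmap"
  )
}

#' @export
print.tmap <- function(x, ...) {
  cat(sprintf(
    "<tmap> class %s, score '%s', %d voxels; t range %.2f to %.2f (%s p, %s)\n",
    toupper(x$class), x$score, length(x$t), min(x$t), max(x$t),
    x$alternative, if (x$var_equal) "pooled variance" else "Welch"))
  invisible(x)
}

#' Tidy a voxelwise t-map
#'
#' @param x A `tmap`.
#' @param ... Unused.
#' @return A tibble with voxel linear index, (i, j, k) coordinates, group
#'   sizes, t, df and p per eligible voxel.
#' @export
tidy.tmap <- function(x, ...) {
  co <- voxel_coords(x$voxel, x$grid)
  tibble::tibble(
    voxel = x$voxel, i = co[, 1], j = co[, 2], k = co[, 3],
    n_lesioned = x$n_lesioned, n_intact = x$n_intact,
    t = x$t, df = x$df, p = x$p
  )
}

#' 3D array of t statistics
#'
#' @param tmap A `tmap`.
#' @return A 3D array with t at eligible voxels and `NA` elsewhere.
#' @export
tmap_array <- function(tmap) {
  a <- array(NA_real_, dim = tmap$grid$shape)
  a[tmap$voxel] <- tmap$t
  a
}

#' Benjamini-Hochberg significance cutoff for a p-value vector
#'
#' With sorted p-values p(1) <= ... <= p(m), finds
#' k = max\{i : p(i) <= i q / m\}; all voxels with p <= p(k) are declared
#' significant (none if no such i exists).
#'
#' @param p Numeric vector of p-values.
#' @param q Target false discovery rate in (0, 1).
#' @return A list with `cutoff` (the p-value threshold, `NA` when there are no
#'   rejections), `n_significant`, and `significant` (logical vector).
#' @export
bh_threshold <- function(p, q = 0.05) {
  if (length(p) == 0) stop("empty p-value vector", call. = FALSE)
  if (q <= 0 || q >= 1) stop("q must be in (0,1)", call. = FALSE)
  adj <- stats::p.adjust(p, method = "BH")
  sig <- adj <= q
  cutoff <- if (any(sig)) max(p[sig]) else NA_real_
  list(cutoff = cutoff, n_significant = sum(sig), significant = sig)
}

#' FDR-threshold a t-map
#'
#' Applies the Benjamini-Hochberg procedure at level `q` over the p-values of
#' all eligible voxels (the eligibility mask defines the tested family) and
#' reports the equivalent t cutoff: the smallest t among significant voxels.
#'
#' @param tmap A `tmap` from [voxelwise_t()].
#' @param q False discovery rate, default 0.05.
#' @return An object of class `fdr_result` with the p cutoff, t cutoff,
#'   significant-voxel indices, a logical significance array, and counts.
#' @export
bh_fdr <- function(tmap, q = 0.05) {
  stopifnot(inherits(tmap, "tmap"))
  bh <- bh_threshold(tmap$p, q)
  sig_vox <- tmap$voxel[bh$significant]
  sig_mask <- array(FALSE, dim = tmap$grid$shape)
  sig_mask[sig_vox] <- TRUE
  structure(
    list(q = q, p_cutoff = bh$cutoff,
         t_cutoff = if (bh$n_significant > 0) min(tmap$t[bh$significant]) else NA_real_,
         n_significant = bh$n_significant, n_tested = length(tmap$p),
         voxel = sig_vox, mask = sig_mask,
         grid = tmap$grid, class = tmap$class, score = tmap$score,
         alternative = tmap$alternative),
    class = "fdr_result"
  )
}

#' @export
print.fdr_result <- function(x, ...) {
  cat(sprintf("<fdr_result> q = %g: %d of %d voxels significant", x$q,
              x$n_significant, x$n_tested))
  if (x$n_significant > 0)
    cat(sprintf(" (p <= %.3g, t >= %.2f)", x$p_cutoff, x$t_cutoff))
  cat("\n")
  invisible(x)
}

#' Label connected clusters of significant voxels
#'
#' Connected-component labelling of a binary 3D mask under 6- (faces), 18-
#' (faces+edges) or 26- (faces+edges+corners) connectivity.
#'
#' @param mask Logical/binary 3D array, or an `fdr_result` (its significance
#'   mask is used).
#' @param connectivity 6, 18 or 26 (default 26, the most permissive standard
#'   3D rule).
#' @return An object of class `cluster_labels`: integer label array
#'   (0 = background), tibble of cluster sizes, and the connectivity used.
#' @export
label_clusters <- function(mask, connectivity = 26) {
  if (inherits(mask, "fdr_result")) mask <- mask$mask
  if (length(dim(mask)) != 3) stop("mask must be a 3D array", call. = FALSE)
  if (!connectivity %in% c(6, 18, 26))
    stop("connectivity must be 6, 18 or 26", call. = FALSE)
  mask <- mask != 0
  d <- dim(mask)

  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  nz <- rowSums(offs != 0)
  keep <- switch(as.character(connectivity),
                 "6" = nz == 1, "18" = nz >= 1 & nz <= 2, "26" = nz >= 1)
  offs <- offs[keep, , drop = FALSE]
  lin_offs <- offs[, 1] + offs[, 2] * d[1] + offs[, 3] * d[1] * d[2]

  labels <- array(0L, dim = d)
  vox <- which(mask)
  next_label <- 0L
  queue <- integer(length(vox))
  for (v in vox) {
    if (labels[v] != 0L) next
    next_label <- next_label + 1L
    labels[v] <- next_label
    queue[1] <- v
    head <- 1L
    tail <- 1L
    while (head <= tail) {
      cur <- queue[head]
      head <- head + 1L
      k <- (cur - 1L) %/% (d[1] * d[2])
      rem <- (cur - 1L) %% (d[1] * d[2])
      j <- rem %/% d[1]
      i <- rem %% d[1]
      for (o in seq_along(lin_offs)) {
        ii <- i + offs[o, 1]; jj <- j + offs[o, 2]; kk <- k + offs[o, 3]
        if (ii < 0 || ii >= d[1] || jj < 0 || jj >= d[2] || kk < 0 || kk >= d[3]) next
        nb <- cur + lin_offs[o]
        if (mask[nb] && labels[nb] == 0L) {
          labels[nb] <- next_label
          tail <- tail + 1L
          queue[tail] <- nb
        }
      }
    }
  }

  sizes <- if (next_label > 0) {
    tab <- tabulate(labels[labels > 0L], nbins = next_label)
    tibble::tibble(cluster = seq_len(next_label), n_voxels = tab)
  } else {
    tibble::tibble(cluster = integer(0), n_voxels = integer(0))
  }
  structure(
    list(labels = labels, sizes = sizes, connectivity = connectivity,
         n_clusters = next_label),
    class = "cluster_labels"
  )
}

#' @export
print.cluster_labels <- function(x, ...) {
  cat(sprintf("<cluster_labels> %d cluster(s), connectivity %d", x$n_clusters,
              x$connectivity))
  if (x$n_clusters > 0)
    cat(sprintf(", largest %d voxels", max(x$sizes$n_voxels)))
  cat("\n")
  invisible(x)
}
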