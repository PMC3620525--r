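# ggplot2 displays for the main result types. Volumes are shown as axial
# slice montages (k indexed); statistical maps use a diverging palette.

slice_tibble <- function(arr, slices) {
  d <- dim(arr)
  purrr::map_dfr(slices, function(kk) {
    tibble::tibble(
      i = rep(seq_len(d[1]), d[2]),
      j = rep(seq_len(d[2]), each = d[1]),
      k = kk,
      value = as.vector(arr[, , kk])
    )
  })
}

default_slices <- function(arr, n = 6) {
  d <- dim(arr)[3]
  unique(round(seq(1, d, length.out = min(n, d))))
}

#' Plot axial slices of a lesion prevalence map
#'
#' @param object A [prevalence_map()].
#' @param slices Axial slice indices (default: an even spread).
#' @param min_count Hide voxels below this count (default 1).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.prevalence_map <- function(object, slices = NULL, min_count = 1, ...) {
  if (is.null(slices)) slices <- default_slices(object$counts)
  df <- slice_tibble(object$counts, slices)
  df$value[df$value < min_count] <- NA
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~k, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_viridis_c(na.value = "grey15",
                                  name = "patients\nwith lesion") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s prevalence (n = %d)",
                                  toupper(object$class), object$n_patients)) +
    ggplot2::theme_minimal()
}

#' Plot axial slices of a voxelwise t-map
#'
#' Optionally overlays the FDR threshold: voxels at or above the t cutoff are
#' the significant set.
#'
#' @param object A `tmap` from [voxelwise_t()].
#' @param fdr Optional `fdr_result`; its t cutoff is drawn as a fill midpoint.
#' @param slices Axial slice indices.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tmap <- function(object, fdr = NULL, slices = NULL, ...) {
  arr <- tmap_array(object)
  if (is.null(slices)) slices <- default_slices(arr)
  df <- slice_tibble(arr, slices)
  mid <- if (!is.null(fdr) && is.finite(fdr$t_cutoff)) fdr$t_cutoff else 0
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~k, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "palegreen",
                                  high = "red", midpoint = mid,
                                  na.value = "grey15", name = "t") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s t-map (%s)", toupper(object$class),
                                  object$score),
                  subtitle = if (!is.null(fdr) && is.finite(fdr$t_cutoff))
                    sprintf("FDR q = %g threshold: t = %.2f", fdr$q, fdr$t_cutoff)
                  else NULL) +
    ggplot2::theme_minimal()
}

#' Forest plot of the model-ladder coefficients
#'
#' Shows the unstandardized coefficient (with 95% CI) of the term each model
#' adds, in ladder order.
#'
#' @param object A `ladder_result` from [run_ladder()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ladder_result <- function(object, ...) {
  df <- tidy(object)
  df <- df[!is.na(df$B), ]
  df$label <- paste0(df$model, ": ", df$term)
  df$label <- factor(df$label, levels = rev(df$label))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$B, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf_low,
                                          xmax = .data$conf_high)) +
    ggplot2::labs(x = "B (z-score per unit, 95% CI)", y = NULL,
                  title = sprintf("Lesion-burden ladder: %s", attr(object, "domain"))) +
    ggplot2::theme_minimal()
}
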