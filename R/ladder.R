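#' Fit one linear model of the ladder
#'
#' Ordinary least squares of a cognitive outcome on named predictor columns,
#' with t-based 95% confidence intervals on the unstandardized coefficients.
#'
#' @param data Data frame containing the outcome and predictors (one row per
#'   patient).
#' @param outcome Name of the outcome column.
#' @param predictors Character vector of predictor column names (an intercept
#'   is always included).
#' @param conf_level Confidence level for the coefficient intervals.
#' @return An object of class `model_fit`.
#' @export
ols_fit <- function(data, outcome, predictors, conf_level = 0.95) {
  data <- as.data.frame(data)
  miss <- setdiff(c(outcome, predictors), names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  dat <- data[stats::complete.cases(data[, c(outcome, predictors)]), , drop = FALSE]
  n <- nrow(dat)
  if (n <= length(predictors) + 1)
    stop("too few observations for ", length(predictors), " predictors", call. = FALSE)
  f <- stats::reformulate(predictors, response = outcome)
  fit <- stats::lm(f, data = dat)
  if (fit$rank < length(predictors) + 1) {
    dep <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear columns: ",
         paste(dep, collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)
  ci <- stats::confint(fit, level = conf_level)
  coefs <- tibble::tibble(
    term = rownames(sm$coefficients),
    estimate = unname(sm$coefficients[, 1]),
    std_error = unname(sm$coefficients[, 2]),
    statistic = unname(sm$coefficients[, 3]),
    p_value = unname(sm$coefficients[, 4]),
    conf_low = unname(ci[, 1]),
    conf_high = unname(ci[, 2])
  )
  structure(
    list(fit = fit, outcome = outcome, predictors = predictors,
         coefficients = coefs, r_squared = sm$r.squared,
         n = n, df_residual = fit$df.residual, conf_level = conf_level),
    class = "model_fit"
  )
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("<model_fit> %s ~ %s\n  R^2 = %.3f, n = %d, residual df = %d\n",
              x$outcome, paste(x$predictors, collapse = " + "),
              x$r_squared, x$n, x$df_residual))
  invisible(x)
}

#' @export
tidy.model_fit <- function(x, ...) x$coefficients

#' @export
glance.model_fit <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, n = x$n, df_residual = x$df_residual)
}

#' Explained-variance increment between nested models
#'
#' Partial-F test of the increase in R-squared when `extended` adds predictors
#' to `base`: `F = (dR2 / k) / ((1 - R2_ext) / df_ext)` with `k` added
#' predictors, referred to the F distribution with `(k, df_ext)` degrees of
#' freedom.
#'
#' @param base,extended `model_fit` objects with the same outcome and
#'   patients; `extended`'s predictors must strictly contain `base`'s.
#' @return A tibble with `delta_r2`, `statistic` (F), `df1`, `df2`, `p_value`.
#' @export
delta_r2_test <- function(base, extended) {
  stopifnot(inherits(base, "model_fit"), inherits(extended, "model_fit"))
  if (!identical(base$outcome, extended$outcome))
    stop("models have different outcomes", call. = FALSE)
  if (!all(base$predictors %in% extended$predictors))
    stop("models are not nested", call. = FALSE)
  k <- length(setdiff(extended$predictors, base$predictors))
  if (k == 0) stop("extended model adds no predictors", call. = FALSE)
  if (base$n != extended$n)
    stop("models were fitted on different numbers of patients", call. = FALSE)
  d_r2 <- extended$r_squared - base$r_squared
  df2 <- extended$df_residual
  f <- max(d_r2, 0) / k / ((1 - extended$r_squared) / df2)
  tibble::tibble(
    delta_r2 = d_r2, statistic = f, df1 = k, df2 = df2,
    p_value = stats::pf(f, k, df2, lower.tail = FALSE)
  )
}

#' Fit the hierarchical lesion-burden model ladder
#'
#' Twelve nested linear models relating a cognitive-domain composite to
#' covariates, total lesion burden, and regional tract lesion volumes:
#'
#' * model 1: age + sex + education + reading test;
#' * 2a/2b/2c: model 1 plus LL presence (dichotomous), total WML volume, or
#'   both;
#' * 3a-3d: model 1 plus one regional volume (LL then WML, per tract);
#' * 4a-4d: model 2c plus one regional volume (LL then WML, per tract).
#'
#' The explained-variance increment of models 2a-2c and 3a-3d is tested
#' against model 1; that of 4a-4d against model 2c. Volumes enter in ml,
#' untransformed, so coefficients are in z-score per ml. Patients with any
#' missing variable are dropped listwise before all fits so every model uses
#' the same sample.
#'
#' @param scores Domain composites from [composite_scores()] (unadjusted;
#'   covariates enter the models directly).
#' @param covariates Data frame with `patient_id`, `age`, `sex`, `education`,
#'   `dart`.
#' @param totals Total-burden table from [lesion_volumes()].
#' @param regional Long regional-volume table from [regional_volumes()].
#' @param tracts Character vector of exactly two tract names (order fixes the
#'   a/c vs b/d labels).
#' @param domain Name of the domain column in `scores` to model.
#' @return An object of class `ladder_result`: a tibble with one row per
#'   model (label, predictors, r_squared, delta_r2, p_delta, added term and
#'   its B with CI) and the underlying `model_fit`s in attribute `fits`.
#' @export
#' @examples
#' sim <- simulate_cohort(sim_config(n_patients = 120, seed = 3))
#' scores <- composite_scores(sim$subtests)
#' masks <- binarize_atlas(sim$atlas, 0.1)
#' ladder <- run_ladder(scores, sim$covariates, lesion_volumes(sim$cohort),
#'                      regional_volumes(sim$cohort, masks),
#'                      tracts = c("tract_a", "tract_b"))
#' ladder
run_ladder <- function(scores, covariates, totals, regional,
                       tracts, domain = "executive") {
  stopifnot(length(tracts) == 2)
  scores <- tibble::as_tibble(scores)
  if (!domain %in% names(scores))
    stop("domain '", domain, "' not found in scores", call. = FALSE)
  missing_tracts <- setdiff(tracts, unique(regional$tract))
  if (length(missing_tracts))
    stop("tract(s) missing from the regional-volume table: ",
         paste(missing_tracts, collapse = ", "), call. = FALSE)

  reg <- dplyr::filter(regional, .data$tract %in% tracts)
  reg_wide <- tidyr::pivot_wider(reg, id_cols = "patient_id",
                                 names_from = c("class", "tract"),
                                 values_from = "volume_ml",
                                 names_glue = "{class}_volume_{tract}")
  dat <- scores[, c("patient_id", domain)] |>
    dplyr::inner_join(tibble::as_tibble(covariates), by = "patient_id") |>
    dplyr::inner_join(tibble::as_tibble(totals)[, c("patient_id", "wml_volume_ml", "ll_present")],
                      by = "patient_id") |>
    dplyr::inner_join(reg_wide, by = "patient_id")
  dat <- dat[stats::complete.cases(dat), ]

  cov_terms <- c("age", "sex", "education", "dart")
  t1 <- tracts[1]; t2 <- tracts[2]
  spec <- list(
    `1`  = list(pred = cov_terms, base = NA, add = NA),
    `2a` = list(pred = c(cov_terms, "ll_present"), base = "1", add = "ll_present"),
    `2b` = list(pred = c(cov_terms, "wml_volume_ml"), base = "1", add = "wml_volume_ml"),
    `2c` = list(pred = c(cov_terms, "ll_present", "wml_volume_ml"), base = "1", add = NA),
    `3a` = list(pred = c(cov_terms, paste0("ll_volume_", t1)), base = "1",
                add = paste0("ll_volume_", t1)),
    `3b` = list(pred = c(cov_terms, paste0("ll_volume_", t2)), base = "1",
                add = paste0("ll_volume_", t2)),
    `3c` = list(pred = c(cov_terms, paste0("wml_volume_", t1)), base = "1",
                add = paste0("wml_volume_", t1)),
    `3d` = list(pred = c(cov_terms, paste0("wml_volume_", t2)), base = "1",
                add = paste0("wml_volume_", t2)),
    `4a` = list(pred = c(cov_terms, "ll_present", "wml_volume_ml",
                         paste0("ll_volume_", t1)), base = "2c",
                add = paste0("ll_volume_", t1)),
    `4b` = list(pred = c(cov_terms, "ll_present", "wml_volume_ml",
                         paste0("ll_volume_", t2)), base = "2c",
                add = paste0("ll_volume_", t2)),
    `4c` = list(pred = c(cov_terms, "ll_present", "wml_volume_ml",
                         paste0("wml_volume_", t1)), base = "2c",
                add = paste0("wml_volume_", t1)),
    `4d` = list(pred = c(cov_terms, "ll_present", "wml_volume_ml",
                         paste0("wml_volume_", t2)), base = "2c",
                add = paste0("wml_volume_", t2))
  )

  # Terms that add no rank to their model's design (constant columns, or e.g.
  # a regional LL volume exactly collinear with the LL-presence indicator in
  # a near-LL-free cohort) cannot be estimated; such terms are dropped from
  # their models, whose increment over the base is then zero by construction
  # and reported with p = NA. Covariates come first in every design, so
  # pivoting drops the later (lesion) column of a collinear pair.
  degenerate_terms <- character(0)
  prune <- function(pred) {
    X <- cbind(1, as.matrix(dat[, pred, drop = FALSE]))
    if (qr(X)$rank == ncol(X)) return(pred)
    keep <- 1L                               # the intercept is always kept
    for (jcol in 2:ncol(X)) {
      if (qr(X[, c(keep, jcol), drop = FALSE])$rank == length(keep) + 1L)
        keep <- c(keep, jcol)
    }
    dropped <- pred[setdiff(2:ncol(X), keep) - 1L]
    degenerate_terms <<- union(degenerate_terms, dropped)
    setdiff(pred, dropped)
  }
  fits <- lapply(spec, function(s) ols_fit(dat, domain, prune(s$pred)))
  if (length(degenerate_terms))
    message("degenerate term(s) dropped from the ladder: ",
            paste(degenerate_terms, collapse = ", "))
  rows <- lapply(names(spec), function(lbl) {
    s <- spec[[lbl]]
    fit <- fits[[lbl]]
    if (is.na(s$base[1])) {
      d <- tibble::tibble(delta_r2 = NA_real_, p_value = NA_real_)
    } else if (length(setdiff(fit$predictors, fits[[s$base]]$predictors)) == 0) {
      d <- tibble::tibble(delta_r2 = 0, p_value = NA_real_)
    } else {
      d <- delta_r2_test(fits[[s$base]], fit)
    }
    if (!is.na(s$add) && s$add %in% fit$predictors) {
      co <- fit$coefficients[fit$coefficients$term == s$add, ]
      B <- co$estimate; lo <- co$conf_low; hi <- co$conf_high
    } else {
      B <- NA_real_; lo <- NA_real_; hi <- NA_real_
    }
    tibble::tibble(
      model = lbl,
      predictors = paste(s$pred, collapse = " + "),
      r_squared = fit$r_squared,
      delta_r2 = d$delta_r2[1],
      p_delta = if ("p_value" %in% names(d)) d$p_value[1] else NA_real_,
      term = if (is.na(s$add)) NA_character_ else s$add,
      B = B, conf_low = lo, conf_high = hi
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "fits") <- fits
  attr(out, "degenerate_terms") <- degenerate_terms
  attr(out, "domain") <- domain
  attr(out, "tracts") <- tracts
  attr(out, "n") <- nrow(dat)
  class(out) <- c("ladder_result", class(out))
  out
}

#' @export
print.ladder_result <- function(x, ...) {
  cat(sprintf("<ladder_result> domain '%s', n = %d, tracts %s\n",
              attr(x, "domain"), attr(x, "n"),
              paste(attr(x, "tracts"), collapse = ", ")))
  df <- as.data.frame(x)[, c("model", "r_squared", "delta_r2", "p_delta", "term", "B",
                             "conf_low", "conf_high")]
  print(format(df, digits = 3), row.names = FALSE)
  invisible(x)
}

#' Tidy a fitted model ladder
#'
#' @param x A `ladder_result`.
#' @param ... Unused.
#' @return The per-model summary tibble (label, predictors, R-squared,
#'   delta R-squared with its p-value, and the added coefficient with CI).
#' @export
tidy.ladder_result <- function(x, ...) {
  out <- x
  attr(out, "fits") <- NULL
  class(out) <- setdiff(class(out), "ladder_result")
  tibble::as_tibble(out)
}

#' @export
glance.ladder_result <- function(x, ...) {
  tibble::tibble(
    n = attr(x, "n"), domain = attr(x, "domain"),
    n_models = nrow(x),
    r_squared_covariates = x$r_squared[x$model == "1"],
    r_squared_max = max(x$r_squared)
  )
}
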