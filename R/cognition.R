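#' Default subtest-to-domain battery
#'
#' Maps each subtest to its cognitive domain and records its orientation.
#' Timed and error-count subtests (visual elevator, Brixton errors) are
#' lower-is-better and are sign-flipped before z-scoring so that lower
#' composite scores always mean poorer performance.
#'
#' @return A tibble with columns `subtest`, `domain`, `orientation`.
#' @export
default_battery <- function() {
  default_subtest_spec()[, c("subtest", "domain", "orientation")]
}

#' Composite cognitive-domain z-scores
#'
#' Lower-is-better subtests are negated, every subtest is z-scored against the
#' analysis sample itself (no external norms), and each domain composite is
#' the unweighted mean of its subtests' z-scores. Patients missing any subtest
#' of a domain get `NA` for that domain and are counted in the
#' `"n_incomplete"` attribute.
#'
#' @param subtests Data frame with `patient_id` and one numeric column per
#'   subtest.
#' @param battery Data frame with columns `subtest`, `domain`, `orientation`
#'   (`"higher_better"` / `"lower_better"`); defaults to [default_battery()].
#' @return A tibble with `patient_id` and one composite z column per domain;
#'   attribute `battery` records the mapping used.
#' @export
#' @examples
#' sim <- simulate_cohort(sim_config(n_patients = 30, seed = 2))
#' composite_scores(sim$subtests)
composite_scores <- function(subtests, battery = default_battery()) {
  subtests <- tibble::as_tibble(subtests)
  battery <- tibble::as_tibble(battery)
  if (nrow(subtests) < 2) stop("need at least 2 patients", call. = FALSE)
  stopifnot(all(c("subtest", "domain", "orientation") %in% names(battery)))
  if (anyDuplicated(battery$subtest))
    stop("each subtest must belong to exactly one domain", call. = FALSE)
  if (!all(battery$orientation %in% c("higher_better", "lower_better")))
    stop("orientation must be 'higher_better' or 'lower_better'", call. = FALSE)
  missing_cols <- setdiff(battery$subtest, names(subtests))
  if (length(missing_cols))
    stop("subtests missing from the table: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)

  z <- matrix(NA_real_, nrow(subtests), nrow(battery),
              dimnames = list(NULL, battery$subtest))
  for (r in seq_len(nrow(battery))) {
    x <- as.numeric(subtests[[battery$subtest[r]]])
    if (battery$orientation[r] == "lower_better") x <- -x
    mu <- mean(x, na.rm = TRUE)
    s <- stats::sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0)
      stop("subtest '", battery$subtest[r], "' has zero variance; cannot z-score",
           call. = FALSE)
    z[, r] <- (x - mu) / s
  }

  out <- tibble::tibble(patient_id = subtests$patient_id)
  n_incomplete <- integer(0)
  for (d in unique(battery$domain)) {
    cols <- battery$subtest[battery$domain == d]
    zd <- z[, cols, drop = FALSE]
    comp <- rowMeans(zd)            # NA if any subtest of the domain missing
    n_incomplete[d] <- sum(is.na(comp))
    out[[d]] <- comp
  }
  attr(out, "battery") <- battery
  attr(out, "n_incomplete") <- n_incomplete
  out
}

#' Residualize domain scores against covariates
#'
#' Ordinary least-squares residuals of each domain composite after linear
#' adjustment for age, sex, education (entered as a single numeric 1-8 term)
#' and reading-test score. Residuals are orthogonal to every covariate column
#' and to the constant.
#'
#' @param scores Output of [composite_scores()] (or any data frame with
#'   `patient_id` and numeric domain columns).
#' @param covariates Data frame with `patient_id` and the covariate columns.
#' @param covariate_cols Covariate column names forming the design (plus an
#'   intercept).
#' @return A tibble with `patient_id` and one residual column per domain;
#'   patients with a missing score or covariate are dropped. Attribute
#'   `covariates` records the adjustment set.
#' @export
residualize <- function(scores, covariates,
                        covariate_cols = c("age", "sex", "education", "dart")) {
  scores <- tibble::as_tibble(scores)
  covariates <- tibble::as_tibble(covariates)
  miss <- setdiff(covariate_cols, names(covariates))
  if (length(miss))
    stop("covariates missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  dat <- dplyr::inner_join(scores, covariates[, c("patient_id", covariate_cols)],
                           by = "patient_id")
  domains <- setdiff(names(scores), "patient_id")
  keep <- stats::complete.cases(dat[, c(domains, covariate_cols)])
  dat <- dat[keep, ]
  if (nrow(dat) <= length(covariate_cols) + 1)
    stop("too few complete cases to residualize", call. = FALSE)

  const <- covariate_cols[vapply(covariate_cols, function(cc) {
    stats::sd(as.numeric(dat[[cc]])) == 0
  }, logical(1))]
  if (length(const)) {
    message("dropping constant covariate column(s): ", paste(const, collapse = ", "))
    covariate_cols <- setdiff(covariate_cols, const)
  }
  X <- matrix(1, nrow(dat), 1, dimnames = list(NULL, "(Intercept)"))
  if (length(covariate_cols)) X <- cbind(X, as.matrix(dat[, covariate_cols]))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dep <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient covariate design; collinear columns: ",
         paste(dep, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(patient_id = dat$patient_id)
  for (d in domains) {
    out[[d]] <- qr.resid(qrX, as.numeric(dat[[d]]))
  }
  attr(out, "covariates") <- covariate_cols
  out
}
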