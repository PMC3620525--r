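sim_ladder_inputs <- function(n = 120, seed = 21) {
  sim <- simulate_cohort(tiny_config(n_patients = n, seed = seed))
  masks <- binarize_atlas(sim$atlas, 0.1)
  list(
    scores = composite_scores(sim$subtests),
    covariates = sim$covariates,
    totals = lesion_volumes(sim$cohort),
    regional = regional_volumes(sim$cohort, masks)
  )
}

test_that("a perfectly linear outcome is fitted exactly", {
  d <- data.frame(x = 1:20, z = rnorm(20))
  d$y <- 2 * d$x + 1
  fit <- suppressWarnings(ols_fit(d, "y", c("x", "z")))  # lm warns on exact fit
  co <- tidy(fit)
  expect_equal(co$estimate[co$term == "x"], 2, tolerance = 1e-10)
  expect_equal(co$estimate[co$term == "(Intercept)"], 1, tolerance = 1e-10)
  expect_equal(glance(fit)$r_squared, 1, tolerance = 1e-12)
})

test_that("coefficients, SEs and CIs match a normal-equations + t-quantile oracle", {
  withr::with_seed(22, {
    n <- 60; p <- 5
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
    y <- 1 + X %*% c(0.5, -1, 0, 2, 0.3) + rnorm(n)
    d <- data.frame(y = as.vector(y), X)
  })
  fit <- ols_fit(d, "y", paste0("x", 1:p))
  Xd <- cbind(1, X)
  XtXi <- solve(t(Xd) %*% Xd)
  beta <- XtXi %*% t(Xd) %*% y
  res <- y - Xd %*% beta
  s2 <- sum(res^2) / (n - p - 1)
  se <- sqrt(diag(XtXi) * s2)
  tq <- qt(0.975, n - p - 1)
  co <- tidy(fit)
  expect_equal(co$estimate, as.vector(beta), tolerance = 1e-8)
  expect_equal(co$std_error, as.vector(se), tolerance = 1e-8)
  expect_equal(co$conf_low, as.vector(beta - tq * se), tolerance = 1e-8)
  expect_equal(co$conf_high, as.vector(beta + tq * se), tolerance = 1e-8)
  ssr <- sum((Xd %*% beta - mean(y))^2)
  expect_equal(fit$r_squared, ssr / sum((y - mean(y))^2), tolerance = 1e-10)
})

test_that("rank-deficient designs are rejected naming the collinear column", {
  d <- data.frame(y = rnorm(20), x1 = 1:20)
  d$x2 <- 2 * d$x1
  expect_error(ols_fit(d, "y", c("x1", "x2")), "x2")
})

test_that("the partial-F formula reproduces the textbook example and edge cases", {
  base <- structure(list(outcome = "y", predictors = paste0("x", 1:4),
                         r_squared = 0.25, n = 100, df_residual = 95),
                    class = "model_fit")
  ext <- structure(list(outcome = "y", predictors = paste0("x", 1:5),
                        r_squared = 0.28, n = 100, df_residual = 94),
                   class = "model_fit")
  d <- delta_r2_test(base, ext)
  expect_equal(d$delta_r2, 0.03, tolerance = 1e-12)
  expect_equal(d$statistic, 0.03 / (0.72 / 94), tolerance = 1e-12)  # ~3.92
  expect_equal(d$df1, 1)
  expect_equal(d$p_value, pf(0.03 / (0.72 / 94), 1, 94, lower.tail = FALSE),
               tolerance = 1e-12)

  expect_error(delta_r2_test(base, base), "adds no predictors")
  swapped <- structure(list(outcome = "y", predictors = c("x9"),
                            r_squared = 0.1, n = 100, df_residual = 98),
                       class = "model_fit")
  expect_error(delta_r2_test(base, swapped), "not nested")

  ext0 <- ext; ext0$r_squared <- 0.25
  d0 <- delta_r2_test(base, ext0)
  expect_equal(d0$statistic, 0)
  expect_equal(d0$p_value, 1)
})

test_that("delta-R2 inference matches an independent anova() refit to 1e-10", {
  inp <- sim_ladder_inputs()
  lad <- run_ladder(inp$scores, inp$covariates, inp$totals, inp$regional,
                    c("tract_a", "tract_b"))
  fits <- attr(lad, "fits")
  base_of <- c(`2a` = "1", `2b` = "1", `2c` = "1", `3a` = "1", `3b` = "1",
               `3c` = "1", `3d` = "1", `4a` = "2c", `4b` = "2c", `4c` = "2c",
               `4d` = "2c")
  for (lbl in names(base_of)) {
    ref <- anova(fits[[base_of[lbl]]]$fit, fits[[lbl]]$fit)
    row <- lad[lad$model == lbl, ]
    expect_equal(row$p_delta, ref$`Pr(>F)`[2], tolerance = 1e-10)
    d_r2 <- fits[[lbl]]$r_squared - fits[[base_of[lbl]]]$r_squared
    expect_equal(row$delta_r2, d_r2, tolerance = 1e-12)
  }
})

test_that("the ladder emits the twelve labelled models with monotone nested R2", {
  inp <- sim_ladder_inputs()
  lad <- run_ladder(inp$scores, inp$covariates, inp$totals, inp$regional,
                    c("tract_a", "tract_b"))
  expect_equal(lad$model,
               c("1", "2a", "2b", "2c", "3a", "3b", "3c", "3d",
                 "4a", "4b", "4c", "4d"))
  r2 <- setNames(lad$r_squared, lad$model)
  for (lbl in c("2a", "2b", "2c", "3a", "3b", "3c", "3d"))
    expect_gte(r2[[lbl]], r2[["1"]])
  for (lbl in c("4a", "4b", "4c", "4d"))
    expect_gte(r2[[lbl]], r2[["2c"]])
  expect_gte(r2[["2c"]], r2[["2a"]])
  expect_gte(r2[["2c"]], r2[["2b"]])
  expect_true(all(lad$delta_r2[-1] >= -1e-12))
  expect_equal(glance(lad)$n_models, 12L)
})

test_that("LL presence enters as a 0/1 indicator regardless of lesion count", {
  inp <- sim_ladder_inputs()
  lad <- run_ladder(inp$scores, inp$covariates, inp$totals, inp$regional,
                    c("tract_a", "tract_b"))
  fit2a <- attr(lad, "fits")[["2a"]]
  x <- fit2a$fit$model$ll_present
  expect_true(all(x %in% c(0, 1)))
  # patients with several lacunes still carry indicator 1
  multi <- inp$totals$ll_volume_ml > 0.3
  expect_true(all(inp$totals$ll_present[multi] == 1))
})

test_that("a missing tract in the regional table is reported", {
  inp <- sim_ladder_inputs()
  expect_error(run_ladder(inp$scores, inp$covariates, inp$totals, inp$regional,
                          c("tract_a", "tract_z")), "tract_z")
})

test_that("lesion terms that add no rank are dropped per model, keeping the ladder runnable", {
  withr::with_seed(40, {
    n <- 30
    scores <- tibble::tibble(patient_id = sprintf("p%02d", 1:n), executive = rnorm(n))
    covariates <- tibble::tibble(patient_id = scores$patient_id,
                                 age = rnorm(n, 57, 9), sex = rbinom(n, 1, .8),
                                 education = sample(1:8, n, TRUE),
                                 dart = rnorm(n, 100, 12))
    # exactly one patient has a lacune, entirely inside tract a: the regional
    # LL volume is collinear with the presence indicator, and tract b's is 0
    pres <- c(1L, rep(0L, n - 1))
    totals <- tibble::tibble(patient_id = scores$patient_id,
                             wml_volume_ml = runif(n, 0, 5),
                             ll_volume_ml = 0.26 * pres, ll_present = pres)
    regional <- tidyr::expand_grid(patient_id = scores$patient_id,
                                   tract = c("tract_a", "tract_b"),
                                   class = c("wml", "ll"))
    regional$volume_ml <- ifelse(
      regional$class == "ll",
      ifelse(regional$tract == "tract_a", 0.26 * pres[match(regional$patient_id, scores$patient_id)], 0),
      runif(nrow(regional), 0, 1))
  })
  expect_message(
    lad <- run_ladder(scores, covariates, totals, regional, c("tract_a", "tract_b")),
    "degenerate"
  )
  expect_equal(nrow(lad), 12L)
  # model 3a (covariates only) can estimate the tract-a volume ...
  expect_false(is.na(lad$B[lad$model == "3a"]))
  # ... but model 4a cannot, since the term is collinear with LL presence
  r4a <- lad[lad$model == "4a", ]
  expect_true(is.na(r4a$B))
  expect_equal(r4a$delta_r2, 0)
  expect_true(is.na(r4a$p_delta))
  # tract b's LL volume is constant zero everywhere it appears
  expect_true(all(c("ll_volume_tract_b") %in% attr(lad, "degenerate_terms")))
})

test_that("under a global null the step-4 partial-F rejects at the nominal rate", {
  nrep <- 60
  rej <- logical(nrep)
  for (r in seq_len(nrep)) {
    cfg <- tiny_config(n_patients = 100, seed = 3000 + r,
                       effects = list(ll = c(tract_a = 0, tract_b = 0)))
    sim <- simulate_cohort(cfg)
    sc <- composite_scores(sim$subtests)
    masks <- binarize_atlas(sim$atlas, 0.1)
    lad <- run_ladder(sc, sim$covariates, lesion_volumes(sim$cohort),
                      regional_volumes(sim$cohort, masks), c("tract_a", "tract_b"))
    rej[r] <- lad$p_delta[lad$model == "4a"] < 0.05
  }
  # nominal 0.05 within 3 binomial SDs for 60 replicates
  expect_lte(mean(rej), 0.05 + 3 * sqrt(0.05 * 0.95 / nrep))
})
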