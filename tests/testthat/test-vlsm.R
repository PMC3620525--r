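cohort_one_voxel <- function(intact, lesioned) {
  grid <- voxel_grid(c(3, 3, 1))
  n <- length(intact) + length(lesioned)
  wml <- matrix(0L, n, 9)
  wml[(length(intact) + 1):n, 5] <- 1L
  cohort <- lesion_cohort(wml, matrix(0L, n, 9), sprintf("p%02d", 1:n), grid)
  scores <- tibble::tibble(patient_id = cohort$patient_ids,
                           executive = c(intact, lesioned))
  mask <- analysis_mask(prevalence_map(cohort, "wml"), length(lesioned))
  list(cohort = cohort, scores = scores, mask = mask)
}

test_that("the pooled two-sample t matches the hand-worked single-voxel case", {
  x <- cohort_one_voxel(intact = c(1, 2, 3), lesioned = c(-1, 0, 1))
  tm <- voxelwise_t(x$cohort, x$scores, x$mask, "wml")
  expect_equal(length(tm$t), 1L)
  expect_equal(tm$t, 2 / sqrt(2 / 3), tolerance = 1e-12)   # pooled SD 1, t = 2.449
  expect_equal(tm$df, 4)
  expect_equal(tm$p, pt(2 / sqrt(2 / 3), 4, lower.tail = FALSE), tolerance = 1e-12)
  # identical group means give t = 0
  x0 <- cohort_one_voxel(intact = c(-1, 0, 1), lesioned = c(-1, 0, 1))
  expect_equal(voxelwise_t(x0$cohort, x0$scores, x0$mask, "wml")$t, 0)
})

test_that("t, df and p agree with stats::t.test at every eligible voxel", {
  sim <- simulate_cohort(tiny_config(n_patients = 60, seed = 9))
  sc <- composite_scores(sim$subtests)
  r <- residualize(sc, sim$covariates)
  mask <- analysis_mask(prevalence_map(sim$cohort, "wml"), 5)
  tm <- voxelwise_t(sim$cohort, r[, c("patient_id", "executive")], mask, "wml")
  resid <- r$executive[match(sim$cohort$patient_ids, r$patient_id)]
  for (v in seq_along(tm$voxel)) {
    les <- sim$cohort$wml[, tm$voxel[v]] == 1
    ref <- t.test(resid[!les], resid[les], var.equal = TRUE,
                  alternative = "greater")
    expect_equal(tm$t[v], unname(ref$statistic), tolerance = 1e-10)
    expect_equal(tm$df[v], unname(ref$parameter), tolerance = 1e-10)
    expect_equal(tm$p[v], ref$p.value, tolerance = 1e-10)
  }
  # Welch variant against its reference
  tmw <- voxelwise_t(sim$cohort, r[, c("patient_id", "executive")], mask, "wml",
                     var_equal = FALSE)
  v <- which.max(abs(tmw$t))
  les <- sim$cohort$wml[, tmw$voxel[v]] == 1
  refw <- t.test(resid[!les], resid[les], var.equal = FALSE, alternative = "greater")
  expect_equal(tmw$t[v], unname(refw$statistic), tolerance = 1e-10)
  expect_equal(tmw$df[v], unname(refw$parameter), tolerance = 1e-10)
})

test_that("jointly permuting patients leaves the t-map unchanged", {
  sim <- simulate_cohort(tiny_config(n_patients = 40, seed = 10))
  sc <- composite_scores(sim$subtests)
  r <- residualize(sc, sim$covariates)
  mask <- analysis_mask(prevalence_map(sim$cohort, "wml"), 5)
  tm1 <- voxelwise_t(sim$cohort, r[, c("patient_id", "executive")], mask, "wml")
  perm <- withr::with_seed(1, sample(sim$cohort$n))
  cohort2 <- lesion_cohort(sim$cohort$wml[perm, ], sim$cohort$ll[perm, ],
                           sim$cohort$patient_ids[perm], sim$cohort$grid)
  tm2 <- voxelwise_t(cohort2, r[, c("patient_id", "executive")], mask, "wml")
  expect_equal(tm1$t, tm2$t, tolerance = 1e-12)
  expect_equal(tm1$voxel, tm2$voxel)
})

test_that("zero-variance voxels are dropped with a warning", {
  x <- cohort_one_voxel(intact = c(1, 1, 1), lesioned = c(1, 1, 1))
  expect_warning(tm <- voxelwise_t(x$cohort, x$scores, x$mask, "wml"),
                 "zero-variance")
  expect_equal(length(tm$t), 0L)
  expect_equal(tm$n_dropped_zero_variance, 1L)
})

test_that("the BH threshold reproduces the worked example and its edge branches", {
  p <- c(0.001, 0.008, 0.039, 0.041, 0.27, 0.60)
  bh <- bh_threshold(p, 0.05)
  expect_equal(bh$n_significant, 2L)                  # the two smallest only
  expect_identical(bh$significant, p <= 0.008)
  expect_equal(bh$cutoff, 0.008)

  all_small <- bh_threshold(rep(0.001, 100), 0.05)
  expect_equal(all_small$n_significant, 100L)

  none <- bh_threshold(c(0.2, 0.5, 0.9), 0.05)
  expect_equal(none$n_significant, 0L)
  expect_true(is.na(none$cutoff))
})

test_that("BH agrees exactly with the brute-force scan on random p-vectors", {
  withr::with_seed(11, {
    for (i in 1:100) {
      m <- sample(1:500, 1)
      p <- runif(m)^sample(1:3, 1)      # occasional enrichment in small p
      q <- runif(1, 0.01, 0.2)
      oracle <- bh_scan_oracle(p, q)
      got <- bh_threshold(p, q)
      expect_identical(got$significant, oracle$significant)
      expect_equal(got$n_significant, sum(oracle$significant))
    }
  })
})

test_that("significant voxels are exactly those at or above the derived t cutoff", {
  sim <- simulate_cohort(tiny_config(n_patients = 80, seed = 12))
  sc <- composite_scores(sim$subtests)
  r <- residualize(sc, sim$covariates)
  mask <- analysis_mask(prevalence_map(sim$cohort, "ll"), 5)
  tm <- voxelwise_t(sim$cohort, r[, c("patient_id", "executive")], mask, "ll")
  fdr <- bh_fdr(tm, 0.05)
  expect_true(fdr$n_significant > 0)    # planted effect should light up
  expect_true(all(fdr$mask[tm$voxel] == (tm$t >= fdr$t_cutoff)))
  expect_true(all(tm$p[fdr$mask[tm$voxel]] <= fdr$p_cutoff))
  expect_true(all(fdr$mask <= mask$mask))   # significance within eligibility
})

test_that("cluster labels match flood fill on singletons, corner cases and random masks", {
  d <- c(5, 5, 5)
  m <- array(FALSE, d); m[3, 3, 3] <- TRUE
  cl <- label_clusters(m, 26)
  expect_equal(cl$n_clusters, 1L)
  expect_equal(cl$sizes$n_voxels, 1L)

  # two voxels sharing only a corner
  m2 <- array(FALSE, d); m2[1, 1, 1] <- TRUE; m2[2, 2, 2] <- TRUE
  expect_equal(label_clusters(m2, 26)$n_clusters, 1L)
  expect_equal(label_clusters(m2, 6)$n_clusters, 2L)
  # edge-sharing pair: connected under 18 and 26, split under 6
  m3 <- array(FALSE, d); m3[1, 1, 1] <- TRUE; m3[2, 2, 1] <- TRUE
  expect_equal(label_clusters(m3, 18)$n_clusters, 1L)
  expect_equal(label_clusters(m3, 6)$n_clusters, 2L)

  withr::with_seed(13, {
    for (i in 1:10) {
      mask <- array(runif(16^3) < 0.08, c(16, 16, 16))
      for (conn in c(6, 18, 26)) {
        got <- label_clusters(mask, conn)
        expect_true(same_partition(got$labels, flood_fill_oracle(mask, conn)))
        expect_equal(sum(got$sizes$n_voxels), sum(mask))
      }
    }
  })
})

test_that("invalid connectivity codes are rejected", {
  expect_error(label_clusters(array(TRUE, c(2, 2, 2)), 10), "connectivity")
})
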