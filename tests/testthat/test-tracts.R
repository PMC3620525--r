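test_that("atlas thresholding is inclusive at the boundary and monotone", {
  grid <- voxel_grid(c(4, 4, 2))
  p <- array(0, grid$shape)
  p[1, 1, 1] <- 0.09; p[2, 1, 1] <- 0.10; p[3, 1, 1] <- 1.0
  atlas <- tract_atlas(list(t1 = p), grid)
  m <- binarize_atlas(atlas, 0.1)$masks$t1
  expect_false(m[1, 1, 1])      # 0.09 excluded
  expect_true(m[2, 1, 1])       # 0.10 included (>= convention)
  expect_true(m[3, 1, 1])
  for (thr in c(0.05, 0.2, 0.5, 0.9)) {
    lo <- binarize_atlas(atlas, thr)$masks$t1
    hi <- binarize_atlas(atlas, min(thr + 0.05, 0.95))$masks$t1
    expect_true(all(hi <= lo))  # raising the threshold never grows a mask
  }
  expect_error(binarize_atlas(atlas, 0), "threshold")
  expect_error(binarize_atlas(atlas, 1), "threshold")
})

test_that("percent-scaled atlas volumes are auto-rescaled with a warning", {
  grid <- voxel_grid(c(3, 3, 1))
  p <- array(0, grid$shape); p[2, 2, 1] <- 80
  expect_warning(atlas <- tract_atlas(list(t1 = p), grid), "percent")
  expect_equal(atlas$prob$t1[2, 2, 1], 0.8)
})

# a wide flat tract mask for constructing selection-rule edge cases
flat_tract <- function(grid) {
  p <- array(1, grid$shape)
  binarize_atlas(tract_atlas(list(t1 = p), grid), 0.1)
}

test_that("the selection rule applies strict inequalities on both branches", {
  grid <- voxel_grid(c(12, 12, 12))
  masks <- flat_tract(grid)

  scatter <- function(n_vox) {
    # n_vox isolated voxels on an every-other-voxel lattice (no adjacency)
    sig <- array(FALSE, grid$shape)
    co <- as.matrix(expand.grid(seq(1, 11, 2), seq(1, 11, 2), seq(1, 11, 2)))
    sig[co[seq_len(n_vox), , drop = FALSE]] <- TRUE
    sig
  }
  s51 <- tract_summary(scatter(51), NULL, masks, min_total = 50, min_cluster = 5)
  expect_true(s51$selected)                      # 51 > 50: count branch
  expect_equal(s51$n_sig_voxels, 51L)
  s50 <- tract_summary(scatter(50), NULL, masks, min_total = 50, min_cluster = 5)
  expect_false(s50$selected)                     # 50 is not more than 50

  bar <- function(len, origin) {
    sig <- array(FALSE, grid$shape)
    sig[origin[1] + seq_len(len) - 1, origin[2], origin[3]] <- TRUE
    sig
  }
  s6 <- tract_summary(bar(6, c(1, 1, 1)), NULL, masks, min_total = 50, min_cluster = 5)
  expect_true(s6$selected)                       # one 6-voxel cluster
  expect_equal(s6$largest_cluster, 6L)
  s5 <- tract_summary(bar(5, c(1, 1, 1)), NULL, masks, min_total = 50, min_cluster = 5)
  expect_false(s5$selected)                      # 5 is not more than 5

  # ten disjoint 5-voxel clusters: 50 voxels total, no qualifying cluster
  sig <- array(FALSE, grid$shape)
  for (k in 1:10) {
    sig[1:5, ((k - 1) %% 6) * 2 + 1, ((k - 1) %/% 6) * 2 + 1] <- TRUE
  }
  s10x5 <- tract_summary(sig, NULL, masks, min_total = 50, min_cluster = 5)
  expect_equal(s10x5$n_sig_voxels, 50L)
  expect_equal(s10x5$largest_cluster, 5L)
  expect_false(s10x5$selected)
})

test_that("tract counts and overlaps match brute-force intersection loops", {
  withr::with_seed(14, {
    grid <- voxel_grid(c(10, 10, 6))
    for (rep in 1:5) {
      sig <- array(runif(600) < 0.15, grid$shape)
      p1 <- array(runif(600), grid$shape)
      p2 <- array(runif(600), grid$shape)
      atlas <- tract_atlas(list(a = p1, b = p2), grid)
      masks <- binarize_atlas(atlas, 0.5)
      cl <- label_clusters(sig, 26)
      ts <- tract_summary(sig, cl, masks, min_total = 10, min_cluster = 3)
      for (nm in c("a", "b")) {
        tm <- masks$masks[[nm]]
        n_brute <- 0L
        for (v in which(sig)) if (tm[v]) n_brute <- n_brute + 1L
        expect_equal(ts$n_sig_voxels[ts$tract == nm], n_brute)
        # largest overlap of a single global cluster with the tract
        best <- 0L
        if (cl$n_clusters > 0) {
          for (lab in seq_len(cl$n_clusters)) {
            ov <- sum(cl$labels == lab & tm)
            if (ov > best) best <- ov
          }
        }
        expect_equal(ts$largest_cluster[ts$tract == nm], best)
        expect_equal(ts$selected[ts$tract == nm], n_brute > 10 || best > 3)
      }
    }
  })
})

test_that("regional volumes respect containment, unit arithmetic and additivity", {
  grid <- voxel_grid(c(10, 10, 4), voxel_size = c(2, 2, 2))
  V <- prod(grid$shape)
  wml <- matrix(0L, 2, V)
  wml[1, 1:10] <- 1L                       # 10 voxels fully inside tract a
  ll <- matrix(0L, 2, V)
  ll[1, 5:24] <- 1L
  cohort <- lesion_cohort(wml, ll, c("p1", "p2"), grid)

  pa <- array(0, grid$shape); pa[, , 1:2] <- 1     # lower half
  pb <- array(0, grid$shape); pb[, , 3:4] <- 1     # upper half (disjoint)
  whole <- array(1, grid$shape)
  masks <- binarize_atlas(tract_atlas(list(a = pa, b = pb, all = whole), grid), 0.5)
  rv <- regional_volumes(cohort, masks)

  expect_equal(rv$volume_ml[rv$patient_id == "p1" & rv$tract == "a" & rv$class == "wml"],
               10 * 8 / 1000)              # 0.08 ml
  expect_equal(rv$volume_ml[rv$patient_id == "p2" & rv$class == "wml"], rep(0, 3))

  totals <- lesion_volumes(cohort)
  for (cls in c("wml", "ll")) {
    all_vol <- rv$volume_ml[rv$tract == "all" & rv$class == cls]
    expect_equal(all_vol, totals[[paste0(cls, "_volume_ml")]])   # whole-grid = total
    # disjoint halves partition the grid, so they sum to the total
    a_vol <- rv$volume_ml[rv$tract == "a" & rv$class == cls]
    b_vol <- rv$volume_ml[rv$tract == "b" & rv$class == cls]
    expect_equal(a_vol + b_vol, all_vol)
    expect_true(all(a_vol <= all_vol + 1e-12))
  }
})

test_that("grid mismatches between cohort and atlas are rejected", {
  sim <- simulate_cohort(tiny_config(n_patients = 3))
  other <- voxel_grid(c(5, 5, 5))
  masks <- binarize_atlas(tract_atlas(list(t = array(1, other$shape)), other), 0.5)
  expect_error(regional_volumes(sim$cohort, masks), "grid")
})
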