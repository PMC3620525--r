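#' Describe a synthetic white-matter tract
#'
#' A tract is modelled as a geometric core (ellipsoid or cuboid, in voxel
#' coordinates) with peak membership probability inside the core and a
#' Gaussian falloff outside it, emulating one volume of a probabilistic
#' tract atlas.
#'
#' @param name Tract name (e.g. `"tract_a"`).
#' @param center Numeric length-3 voxel coordinates of the core centre.
#' @param radii Numeric length-3 core half-extents in voxels.
#' @param peak Peak probability inside the core, in (0, 1].
#' @param shape `"ellipsoid"` or `"cuboid"` core geometry.
#' @param falloff Gaussian falloff scale outside the core, in voxels;
#'   probabilities below 1e-6 are truncated to exactly 0.
#'
#' @return An object of class `tract_spec`.
#' @export
tract_spec <- function(name, center, radii, peak = 1, shape = c("ellipsoid", "cuboid"),
                       falloff = 1.5) {
  shape <- match.arg(shape)
  stopifnot(length(center) == 3, length(radii) == 3)
  if (any(radii <= 0)) stop("tract '", name, "': radii must be positive", call. = FALSE)
  if (peak <= 0 || peak > 1) stop("tract '", name, "': peak must be in (0,1]", call. = FALSE)
  structure(
    list(name = as.character(name), center = as.numeric(center),
         radii = as.numeric(radii), peak = peak, shape = shape, falloff = falloff),
    class = "tract_spec"
  )
}

# Probability volume for one tract spec on a grid. Distance outside the core is
# measured in voxels; inside the core the probability equals `peak`.
tract_probability_volume <- function(spec, grid) {
  lo <- spec$center - spec$radii
  hi <- spec$center + spec$radii
  if (any(lo < 1) || any(hi > grid$shape))
    stop("tract '", spec$name, "' does not fit inside the grid", call. = FALSE)
  ax <- lapply(1:3, function(a) seq_len(grid$shape[a]))
  # per-axis distance beyond the core interval (0 inside)
  d <- lapply(1:3, function(a) pmax(0, abs(ax[[a]] - spec$center[a]) - spec$radii[a]))
  if (spec$shape == "cuboid") {
    dist2 <- outer(outer(d[[1]]^2, d[[2]]^2, "+"), d[[3]]^2, "+")
  } else {
    # ellipsoid: normalized radial coordinate; distance outside the unit shell
    e <- lapply(1:3, function(a) ((ax[[a]] - spec$center[a]) / spec$radii[a])^2)
    r <- sqrt(outer(outer(e[[1]], e[[2]], "+"), e[[3]], "+"))
    dist2 <- (pmax(r - 1, 0) * mean(spec$radii))^2
  }
  p <- spec$peak * exp(-0.5 * dist2 / spec$falloff^2)
  p[p < 1e-6] <- 0
  p
}

#' Default neuropsychological battery emulated by the generator
#'
#' Nine subtests in three domains (memory, executive, speed/attention) with
#' realistic means and spreads. Timed/error subtests are emitted
#' lower-is-better (larger raw value = worse performance). Executive subtests
#' carry no subtest-level noise by default so that planted lesion effects are
#' expressed exactly in composite z units; all residual variance for that
#' domain lives in the latent noise term.
#'
#' @return A tibble with columns `subtest`, `domain`, `orientation`,
#'   `loading`, `noise_sd`, `center`, `scale`.
#' @export
default_subtest_spec <- function() {
  tibble::tribble(
    ~subtest,                  ~domain,           ~orientation,    ~loading, ~noise_sd, ~center, ~scale,
    "word_learning_immediate", "memory",          "higher_better", 1,        0.5,       40,      10,
    "word_learning_delayed",   "memory",          "higher_better", 1,        0.5,       8,       3,
    "figure_recall_delayed",   "memory",          "higher_better", 1,        0.5,       21,      6,
    "visual_elevator_time",    "executive",       "lower_better",  1,        0,         4.8,     2.4,
    "brixton_errors",          "executive",       "lower_better",  1,        0,         18,      7,
    "verbal_fluency",          "executive",       "higher_better", 1,        0,         11,      5,
    "digit_span_forward",      "speed_attention", "higher_better", 1,        0.5,       8,       2,
    "digit_span_backward",     "speed_attention", "higher_better", 1,        0.5,       6,       2,
    "symbol_substitution",     "speed_attention", "higher_better", 1,        0.5,       58,      15
  )
}

#' Configure a synthetic lesion-symptom cohort
#'
#' Bundles every parameter of the generator: grid, tract geometry, the
#' white-matter-lesion (WML) random-field model, the lacunar-lesion (LL)
#' placement model, covariate distributions, the generating linear model for
#' cognition with planted per-tract lesion effects, and the subtest battery.
#'
#' The defaults define the package's documented reference scenario: 200
#' patients on a 24 x 24 x 12 grid of 2 mm voxels, two disjoint tracts, a
#' planted lacunar-lesion effect of -3 z/ml in `tract_a` and no effect in
#' `tract_b`, and a latent executive score calibrated to approximately unit
#' variance so that planted coefficients are in composite z-score units.
#'
#' @param n_patients Number of patients.
#' @param grid A [voxel_grid()].
#' @param tracts Named list of [tract_spec()] objects.
#' @param wml WML field parameters: `base_prob` (per-voxel lesion probability),
#'   `smoothness` (Gaussian field scale, voxels), `burden_sdlog` (log-SD of the
#'   unit-mean lognormal per-patient burden multiplier), `profile`
#'   (`"central"` scales probability up towards the grid centre, `"flat"`
#'   keeps it homogeneous), `profile_peak` (central/peripheral probability
#'   ratio for the central profile).
#' @param ll LL parameters: `rate` (Poisson mean lesion count per patient),
#'   `radius` (sphere radius, voxels), `weights` (named placement weights over
#'   `"background"` and tract names), `dispersion` (placement Gaussian SD as a
#'   fraction of the tract radii), `wml_coupling` (exponent tying the LL rate
#'   to the WML burden multiplier; 0 = independent).
#' @param covariates Covariate distribution parameters (age mean/SD in years,
#'   male proportion, probabilities over the 8 ordinal education levels,
#'   reading-test mean/SD).
#' @param effects Generating-model coefficients: `domain` receiving lesion
#'   effects, named per-tract `ll` and `wml` coefficients (z-score per ml of
#'   regional lesion volume), covariate coefficients, `intercept`, `noise_sd`.
#' @param subtests Subtest battery, see [default_subtest_spec()].
#' @param atlas_threshold Probability threshold defining the tract masks used
#'   for the true regional volumes entering the generating model.
#' @param seed Integer master seed; all randomness derives from it.
#'
#' @return An object of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_patients = 20, seed = 7)
#' cohort <- simulate_lesions(cfg)
sim_config <- function(n_patients = 200,
                       grid = voxel_grid(c(24, 24, 12)),
                       tracts = list(
                         tract_a = tract_spec("tract_a", center = c(6, 12, 6),
                                              radii = c(3, 4, 3), falloff = 1),
                         tract_b = tract_spec("tract_b", center = c(18, 12, 6),
                                              radii = c(3, 4, 3), falloff = 1)
                       ),
                       wml = list(),
                       ll = list(),
                       covariates = list(),
                       effects = list(),
                       subtests = default_subtest_spec(),
                       atlas_threshold = 0.1,
                       seed = 1L) {
  wml <- utils::modifyList(list(
    base_prob = 0.03, smoothness = 1.5, burden_sdlog = 0.8,
    profile = "central", profile_peak = 4
  ), wml)
  ll <- utils::modifyList(list(
    rate = 0.8, radius = 2,
    weights = c(background = 0.40, tract_a = 0.45, tract_b = 0.15),
    dispersion = 0.5, wml_coupling = 0
  ), ll)
  covariates <- utils::modifyList(list(
    age_mean = 56.7, age_sd = 9.4, male_prop = 0.82,
    edu_probs = rep(1 / 8, 8), dart_mean = 100, dart_sd = 12
  ), covariates)
  effects <- utils::modifyList(list(
    domain = "executive",
    ll = c(tract_a = -3, tract_b = 0),
    wml = c(tract_a = 0, tract_b = 0),
    age = -0.025, sex = -0.1, education = 0.08, dart = 0.015,
    intercept = 0, noise_sd = 0.81
  ), effects)

  if (n_patients < 1) stop("n_patients must be >= 1", call. = FALSE)
  if (!inherits(grid, "voxel_grid")) stop("`grid` must be a voxel_grid", call. = FALSE)
  if (length(tracts) < 1) stop("at least one tract spec is required", call. = FALSE)
  if (is.null(names(tracts)) || any(names(tracts) == ""))
    stop("`tracts` must be a named list", call. = FALSE)
  for (nm in names(tracts)) tract_probability_volume(tracts[[nm]], grid) # validates fit
  if (wml$base_prob < 0 || wml$base_prob > 1)
    stop("wml$base_prob must be in [0,1]", call. = FALSE)
  if (!wml$profile %in% c("central", "flat"))
    stop("wml$profile must be 'central' or 'flat'", call. = FALSE)
  if (ll$rate < 0) stop("ll$rate must be >= 0", call. = FALSE)
  if (ll$radius < 0) stop("ll$radius must be >= 0", call. = FALSE)
  if (2 * ll$radius + 1 > min(grid$shape))
    stop("ll$radius exceeds the grid extent", call. = FALSE)
  if (ll$dispersion <= 0) stop("ll$dispersion must be > 0", call. = FALSE)
  bad_w <- setdiff(names(ll$weights), c("background", names(tracts)))
  if (length(bad_w))
    stop("ll$weights name unknown regions: ", paste(bad_w, collapse = ", "), call. = FALSE)
  if (any(ll$weights < 0) || sum(ll$weights) <= 0)
    stop("ll$weights must be non-negative and sum > 0", call. = FALSE)
  if (length(covariates$edu_probs) != 8 || abs(sum(covariates$edu_probs) - 1) > 1e-8)
    stop("covariates$edu_probs must be 8 probabilities summing to 1", call. = FALSE)
  for (cls in c("ll", "wml")) {
    bad <- setdiff(names(effects[[cls]]), names(tracts))
    if (length(bad))
      stop("effects$", cls, " names unknown tracts: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (effects$noise_sd < 0) stop("effects$noise_sd must be >= 0", call. = FALSE)
  if (!effects$domain %in% subtests$domain)
    stop("effects$domain has no subtests in the battery", call. = FALSE)
  stopifnot(all(subtests$orientation %in% c("higher_better", "lower_better")))

  structure(
    list(n_patients = as.integer(n_patients), grid = grid, tracts = tracts,
         wml = wml, ll = ll, covariates = covariates, effects = effects,
         subtests = subtests, atlas_threshold = atlas_threshold,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# deterministic per-stage / per-patient seed derivation from the master seed
derive_seed <- function(seed, stage, i = 0L) {
  (as.double(seed) * 48271 + stage * 1664525 + i * 22695477) %% 2147483629 + 1
}

#' Build the synthetic probabilistic tract atlas
#'
#' One probability volume per configured tract, on the configuration grid.
#' The atlas is a deterministic function of the configuration.
#'
#' @param config A [sim_config()].
#' @return An object of class `tract_atlas`: named list of probability volumes
#'   plus the grid.
#' @export
make_synthetic_atlas <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  prob <- lapply(config$tracts, tract_probability_volume, grid = config$grid)
  names(prob) <- names(config$tracts)
  tract_atlas(prob, config$grid)
}

#' Construct a tract atlas from probability volumes
#'
#' @param prob Named list of 3D arrays with values in \[0, 1\]. Values above 1
#'   are auto-detected as percent and divided by 100 with a warning.
#' @param grid The shared [voxel_grid()].
#' @return An object of class `tract_atlas`.
#' @export
tract_atlas <- function(prob, grid) {
  if (is.null(names(prob)) || any(names(prob) == ""))
    stop("atlas volumes must be named by tract", call. = FALSE)
  nms <- names(prob)
  prob <- lapply(nms, function(nm) {
    p <- prob[[nm]]
    if (is.null(dim(p)) || length(dim(p)) != 3 || !all(dim(p) == grid$shape))
      stop("atlas volume '", nm, "' does not match the grid", call. = FALSE)
    dim(p) <- grid$shape
    if (any(p > 1)) {
      warning("atlas volume '", nm, "' has values > 1; treating as percent and dividing by 100")
      p <- p / 100
    }
    if (any(p < 0 | p > 1)) stop("atlas volume '", nm, "' has probabilities outside [0,1]", call. = FALSE)
    p
  })
  names(prob) <- nms
  structure(list(prob = prob, grid = grid), class = "tract_atlas")
}

#' @export
print.tract_atlas <- function(x, ...) {
  cat("<tract_atlas>", length(x$prob), "tracts:", paste(names(x$prob), collapse = ", "), "\n")
  print(x$grid)
  invisible(x)
}

# LL placement density over the grid: uniform background mass plus per-tract
# mass concentrated around each tract centre with a Gaussian whose axis SDs
# are `dispersion` times the tract radii (lacunes cluster within a vascular
# territory rather than spreading over the whole tract).
ll_placement_density <- function(config, atlas) {
  w <- config$ll$weights
  shape <- config$grid$shape
  dens <- array(0, dim = shape)
  if (!is.na(w["background"]) && w["background"] > 0)
    dens <- dens + w[["background"]] / n_voxels(config$grid)
  disp <- config$ll$dispersion
  for (nm in intersect(names(w), names(config$tracts))) {
    sp <- config$tracts[[nm]]
    e <- lapply(1:3, function(a) {
      ((seq_len(shape[a]) - sp$center[a]) / (disp * sp$radii[a]))^2
    })
    g <- exp(-0.5 * outer(outer(e[[1]], e[[2]], "+"), e[[3]], "+"))
    dens <- dens + w[[nm]] * g / sum(g)
  }
  dens / sum(dens)
}

sphere_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- as.matrix(expand.grid(di = -r:r, dj = -r:r, dk = -r:r))
  g[rowSums(g^2) <= radius^2, , drop = FALSE]
}

#' Simulate a cohort of binary lesion maps
#'
#' WML maps are generated by thresholding a per-patient smooth Gaussian random
#' field at the level implied by the (spatially profiled) per-voxel lesion
#' probability times a lognormal per-patient burden multiplier; this yields
#' confluent, spatially correlated lesions with exact per-voxel marginal
#' prevalence. LL maps are unions of small spheres placed at locations drawn
#' from the configured placement density.
#'
#' @param config A [sim_config()].
#' @return A [lesion_cohort()] with patient ids `p001`, `p002`, ...
#' @export
simulate_lesions <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  grid <- config$grid
  n <- config$n_patients
  V <- n_voxels(grid)
  shape <- grid$shape

  kernels <- lapply(shape, gauss_kernel_matrix, sigma = config$wml$smoothness)
  sd_map <- smoothed_sd_map(shape, config$wml$smoothness, kernels)

  prof <- if (config$wml$profile == "flat") {
    array(1, dim = shape)
  } else {
    ctr <- (shape + 1) / 2
    ax <- lapply(1:3, function(a) ((seq_len(shape[a]) - ctr[a]) / (shape[a] / 2))^2)
    f <- exp(-0.5 * outer(outer(ax[[1]], ax[[2]], "+"), ax[[3]], "+") / 0.3^2)
    1 + (config$wml$profile_peak - 1) * f
  }
  q_base <- pmin(config$wml$base_prob * prof, 0.999)

  atlas <- make_synthetic_atlas(config)
  dens <- ll_placement_density(config, atlas)
  offs <- sphere_offsets(config$ll$radius)

  patient_seeds <- withr::with_seed(config$seed,
    sample.int(2147483646L, n, replace = FALSE)
  )

  wml <- matrix(0L, n, V)
  ll <- matrix(0L, n, V)
  for (i in seq_len(n)) {
    withr::with_seed(patient_seeds[i], {
      m_i <- if (config$wml$burden_sdlog > 0) {
        stats::rlnorm(1, meanlog = -config$wml$burden_sdlog^2 / 2,
                      sdlog = config$wml$burden_sdlog)
      } else 1
      if (config$wml$base_prob > 0) {
        z <- standard_random_field(shape, config$wml$smoothness, kernels, sd_map)
        thr <- stats::qnorm(pmin(q_base * m_i, 0.999), lower.tail = FALSE)
        wml[i, ] <- as.integer(z > thr)
      }
      rate_i <- config$ll$rate * m_i^config$ll$wml_coupling
      k <- if (rate_i > 0) stats::rpois(1, rate_i) else 0L
      if (k > 0) {
        centers <- sample.int(V, k, replace = TRUE, prob = dens)
        map <- array(FALSE, dim = shape)
        cc <- arrayInd(centers, .dim = shape)
        for (s in seq_len(k)) {
          vox <- sweep(offs, 2, cc[s, ], "+")
          ok <- vox[, 1] >= 1 & vox[, 1] <= shape[1] &
                vox[, 2] >= 1 & vox[, 2] <= shape[2] &
                vox[, 3] >= 1 & vox[, 3] <= shape[3]
          map[vox[ok, , drop = FALSE]] <- TRUE
        }
        ll[i, ] <- as.integer(map)
      }
    })
  }

  lesion_cohort(wml = wml, ll = ll,
                patient_ids = sprintf("p%03d", seq_len(n)), grid = grid)
}

#' Simulate covariates and raw neuropsychological subtest scores
#'
#' The latent score of each cognitive domain is a linear function of age, sex,
#' education, reading-test score, plus (for the configured effect domain) the
#' planted per-tract regional lesion-volume effects, plus Gaussian noise. Each
#' subtest is an affine transform of `loading * latent + subtest noise`, with
#' lower-is-better subtests emitted so that larger raw values mean worse
#' performance.
#'
#' @param config A [sim_config()].
#' @param cohort The [lesion_cohort()] generated from `config`.
#' @param atlas The [tract_atlas()] generated from `config`.
#' @return A list with tibbles `covariates` (patient_id, age, sex, education,
#'   dart) and `subtests` (patient_id plus one column per subtest).
#' @export
simulate_cognition <- function(config, cohort, atlas) {
  stopifnot(inherits(config, "sim_config"), inherits(cohort, "lesion_cohort"))
  if (cohort$n != config$n_patients)
    stop("cohort patient count does not match the configuration", call. = FALSE)
  stopifnot_same_grid(config$grid, cohort$grid, "config and cohort")
  stopifnot_same_grid(config$grid, atlas$grid, "config and atlas")
  n <- config$n_patients
  cv <- config$covariates
  ef <- config$effects

  masks <- binarize_atlas(atlas, config$atlas_threshold)
  regional <- regional_volumes(cohort, masks)
  reg_wide <- tidyr::pivot_wider(regional,
    names_from = c("class", "tract"), values_from = "volume_ml",
    names_glue = "{class}_{tract}")
  reg_wide <- reg_wide[match(cohort$patient_ids, reg_wide$patient_id), ]

  lesion_term <- rep(0, n)
  for (cls in c("ll", "wml")) {
    b <- ef[[cls]]
    for (nm in names(b)) {
      if (b[[nm]] != 0) lesion_term <- lesion_term + b[[nm]] * reg_wide[[paste0(cls, "_", nm)]]
    }
  }

  out <- withr::with_seed(derive_seed(config$seed, stage = 2L), {
    age <- stats::rnorm(n, cv$age_mean, cv$age_sd)
    sex <- stats::rbinom(n, 1, cv$male_prop)
    education <- sample.int(8L, n, replace = TRUE, prob = cv$edu_probs)
    dart <- stats::rnorm(n, cv$dart_mean, cv$dart_sd)
    cov_term <- ef$intercept + ef$age * age + ef$sex * sex +
      ef$education * education + ef$dart * dart

    domains <- unique(config$subtests$domain)
    latent <- lapply(domains, function(d) {
      lt <- cov_term + stats::rnorm(n, 0, ef$noise_sd)
      if (d == ef$domain) lt <- lt + lesion_term
      lt
    })
    names(latent) <- domains

    sub <- tibble::tibble(patient_id = cohort$patient_ids)
    for (r in seq_len(nrow(config$subtests))) {
      sp <- config$subtests[r, ]
      signal <- sp$loading * latent[[sp$domain]] +
        (if (sp$noise_sd > 0) stats::rnorm(n, 0, sp$noise_sd) else 0)
      sgn <- if (sp$orientation == "lower_better") -1 else 1
      sub[[sp$subtest]] <- sp$center + sp$scale * sgn * signal
    }
    list(
      covariates = tibble::tibble(patient_id = cohort$patient_ids,
                                  age = age, sex = sex,
                                  education = education, dart = dart),
      subtests = sub
    )
  })
  out
}

#' Planted parameters of a simulation configuration
#'
#' Echoes the generating-model coefficients so that downstream estimates can be
#' compared with the truth; when the cohort and atlas are supplied, the
#' per-patient true regional lesion volumes entering the generating model are
#' included.
#'
#' @param config A [sim_config()].
#' @param cohort,atlas Optionally, the generated cohort and atlas.
#' @return A list with `regional_effects` (tibble: tract, class, coefficient in
#'   z/ml), `covariate_effects`, `noise_sd`, `effect_domain`, and (when inputs
#'   are given) `true_regional_volumes`.
#' @export
ground_truth <- function(config, cohort = NULL, atlas = NULL) {
  stopifnot(inherits(config, "sim_config"))
  tr <- names(config$tracts)
  eff <- tibble::tibble(
    tract = rep(tr, 2),
    class = rep(c("ll", "wml"), each = length(tr)),
    coefficient = c(
      vapply(tr, function(nm) {
        b <- config$effects$ll[nm]; if (is.na(b)) 0 else unname(b)
      }, numeric(1), USE.NAMES = FALSE),
      vapply(tr, function(nm) {
        b <- config$effects$wml[nm]; if (is.na(b)) 0 else unname(b)
      }, numeric(1), USE.NAMES = FALSE)
    )
  )
  out <- list(
    regional_effects = eff,
    covariate_effects = config$effects[c("age", "sex", "education", "dart", "intercept")],
    noise_sd = config$effects$noise_sd,
    effect_domain = config$effects$domain
  )
  if (!is.null(cohort) && !is.null(atlas)) {
    masks <- binarize_atlas(atlas, config$atlas_threshold)
    out$true_regional_volumes <- regional_volumes(cohort, masks)
  }
  out
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper running [make_synthetic_atlas()], [simulate_lesions()]
#' and [simulate_cognition()] for one configuration.
#'
#' @param config A [sim_config()].
#' @return A list with elements `config`, `atlas`, `cohort`, `covariates`,
#'   `subtests`, `ground_truth`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  atlas <- make_synthetic_atlas(config)
  cohort <- simulate_lesions(config)
  cog <- simulate_cognition(config, cohort, atlas)
  list(config = config, atlas = atlas, cohort = cohort,
       covariates = cog$covariates, subtests = cog$subtests,
       ground_truth = ground_truth(config))
}
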