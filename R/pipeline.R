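#' Run the full lesion-symptom analysis pipeline
#'
#' Orchestrates the two-stage analysis end to end: cohort (simulated or
#' supplied) -> composite domain z-scores -> covariate residualization ->
#' per-class prevalence map, eligibility mask, voxelwise t-map, FDR
#' thresholding and clustering -> tract selection and regional volumetry ->
#' hierarchical model ladder.
#'
#' A lesion class whose eligibility mask is empty (no voxel affected in at
#' least `min_patients` patients) is skipped at the voxelwise stage with an
#' explicit notice in the log; the region-of-interest volumetry and the model
#' ladder still run for that class.
#'
#' @param input Either a [sim_config()] (synthetic mode) or a list with
#'   elements `cohort` ([lesion_cohort()]), `atlas` ([tract_atlas()]),
#'   `covariates` and `subtests` (file mode; see [read_cohort()]).
#' @param domain Cognitive domain analysed at the voxelwise stage and in the
#'   ladder.
#' @param classes Lesion classes to map voxelwise.
#' @param min_patients Voxel eligibility threshold (default 5).
#' @param q False discovery rate (default 0.05).
#' @param atlas_threshold Tract-atlas probability threshold (default 0.1).
#' @param min_total,min_cluster Tract-selection rule thresholds (default
#'   50 and 5, strict inequalities).
#' @param connectivity Cluster connectivity (6, 18 or 26).
#' @param alternative p-value sidedness for the voxelwise test.
#' @param tracts Tract pair for the ladder; defaults to the first two atlas
#'   tracts.
#' @param battery Subtest battery for [composite_scores()].
#' @param out_dir Optional directory; when given, maps (NIfTI), tables (TSV)
#'   and a JSON run manifest are written there.
#' @return An object of class `vlsm_pipeline`: a list with the scores,
#'   per-class VLSM results, tract summary, regional volumes, ladder, log of
#'   stage messages, and the parameter set used.
#' @export
#' @examples
#' res <- run_pipeline(sim_config(n_patients = 60, seed = 5))
#' res$tract_summary
run_pipeline <- function(input = sim_config(),
                         domain = "executive",
                         classes = c("wml", "ll"),
                         min_patients = 5,
                         q = 0.05,
                         atlas_threshold = 0.1,
                         min_total = 50,
                         min_cluster = 5,
                         connectivity = 26,
                         alternative = c("deficit", "two.sided"),
                         tracts = NULL,
                         battery = default_battery(),
                         out_dir = NULL) {
  alternative <- match.arg(alternative)
  classes <- match.arg(classes, c("wml", "ll"), several.ok = TRUE)
  log <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    message(msg)
  }

  if (inherits(input, "sim_config")) {
    note("simulating synthetic cohort: n = %d, seed = %d", input$n_patients, input$seed)
    sim <- simulate_cohort(input)
    cohort <- sim$cohort; atlas <- sim$atlas
    covariates <- sim$covariates; subtests <- sim$subtests
  } else {
    need <- c("cohort", "atlas", "covariates", "subtests")
    if (!all(need %in% names(input)))
      stop("file-mode input needs elements: ", paste(need, collapse = ", "), call. = FALSE)
    cohort <- input$cohort; atlas <- input$atlas
    covariates <- input$covariates; subtests <- input$subtests
    sim <- NULL
  }
  stopifnot_same_grid(cohort$grid, atlas$grid, "cohort and atlas")

  scores <- composite_scores(subtests, battery)
  resid <- residualize(scores, covariates)
  note("scores: %d patients with complete data in domain '%s'",
       sum(!is.na(resid[[domain]])), domain)

  vlsm <- list()
  for (cls in classes) {
    prev <- prevalence_map(cohort, cls)
    mask <- analysis_mask(prev, min_patients)
    n_elig <- sum(mask$mask)
    if (n_elig == 0) {
      note("VLSM skipped for %s: no voxel affected in at least %d patients",
           toupper(cls), min_patients)
      vlsm[[cls]] <- list(prevalence = prev, mask = mask, skipped = TRUE)
      next
    }
    tm <- voxelwise_t(cohort, resid[, c("patient_id", domain)], mask,
                      class = cls, alternative = alternative)
    fdr <- bh_fdr(tm, q)
    cl <- label_clusters(fdr$mask, connectivity)
    note("%s VLSM: %d eligible voxels, %d significant at q = %g, %d cluster(s)",
         toupper(cls), n_elig, fdr$n_significant, q, cl$n_clusters)
    vlsm[[cls]] <- list(prevalence = prev, mask = mask, tmap = tm, fdr = fdr,
                        clusters = cl, skipped = FALSE)
  }

  masks <- binarize_atlas(atlas, atlas_threshold)
  summaries <- list()
  for (cls in classes) {
    if (isTRUE(vlsm[[cls]]$skipped)) next
    summaries[[cls]] <- tract_summary(vlsm[[cls]]$fdr, vlsm[[cls]]$clusters,
                                      masks, min_total, min_cluster,
                                      connectivity)
    note("%s tract selection: %s", toupper(cls),
         if (any(summaries[[cls]]$selected)) {
           paste(summaries[[cls]]$tract[summaries[[cls]]$selected], collapse = ", ")
         } else "none")
  }
  summary_tbl <- dplyr::bind_rows(summaries, .id = "class")

  regional <- regional_volumes(cohort, masks)
  totals <- lesion_volumes(cohort)
  if (is.null(tracts)) tracts <- utils::head(names(masks$masks), 2)
  ladder <- run_ladder(scores, covariates, totals, regional, tracts, domain)
  note("ladder: %d models on %d patients", nrow(ladder), attr(ladder, "n"))

  params <- list(domain = domain, classes = classes, min_patients = min_patients,
                 q = q, atlas_threshold = atlas_threshold, min_total = min_total,
                 min_cluster = min_cluster, connectivity = connectivity,
                 alternative = alternative, tracts = tracts)
  res <- structure(
    list(cohort = cohort, atlas = atlas, covariates = covariates,
         scores = scores, residuals = resid, vlsm = vlsm,
         tract_summary = summary_tbl, regional_volumes = regional,
         totals = totals, ladder = ladder, params = params, log = log,
         sim = sim),
    class = "vlsm_pipeline"
  )
  if (!is.null(out_dir)) write_pipeline(res, out_dir)
  res
}

#' @export
print.vlsm_pipeline <- function(x, ...) {
  cat("<vlsm_pipeline>\n")
  for (msg in x$log) cat(" -", msg, "\n")
  invisible(x)
}

#' Write pipeline outputs to a directory
#'
#' Prevalence, eligibility, t, p, significance and cluster volumes as NIfTI;
#' tract summary, regional volumes and ladder report as tab-separated tables;
#' a JSON manifest echoing parameters, the log and package version.
#'
#' @param res A `vlsm_pipeline` result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_pipeline <- function(res, dir) {
  stopifnot(inherits(res, "vlsm_pipeline"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  grid <- res$cohort$grid
  for (cls in names(res$vlsm)) {
    v <- res$vlsm[[cls]]
    write_volume(v$prevalence$counts, grid,
                 file.path(dir, paste0(cls, "_prevalence.nii.gz")), "int16")
    write_volume(v$mask$mask, grid,
                 file.path(dir, paste0(cls, "_eligible.nii.gz")), "uint8")
    if (!isTRUE(v$skipped)) {
      ta <- tmap_array(v$tmap); ta[is.na(ta)] <- 0
      write_volume(ta, grid, file.path(dir, paste0(cls, "_tmap.nii.gz")), "float")
      pa <- array(0, grid$shape); pa[v$tmap$voxel] <- v$tmap$p
      write_volume(pa, grid, file.path(dir, paste0(cls, "_pmap.nii.gz")), "float")
      write_volume(v$fdr$mask, grid,
                   file.path(dir, paste0(cls, "_significant.nii.gz")), "uint8")
      write_volume(v$clusters$labels, grid,
                   file.path(dir, paste0(cls, "_clusters.nii.gz")), "int16")
    }
  }
  utils::write.table(res$tract_summary, file.path(dir, "tract_summary.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(res$regional_volumes, file.path(dir, "regional_volumes.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(tidy(res$ladder), file.path(dir, "ladder.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  fdr_info <- lapply(res$vlsm, function(v) {
    if (isTRUE(v$skipped)) return(list(skipped = TRUE))
    list(skipped = FALSE, n_eligible = sum(v$mask$mask),
         n_significant = v$fdr$n_significant, p_cutoff = v$fdr$p_cutoff,
         t_cutoff = v$fdr$t_cutoff, n_clusters = v$clusters$n_clusters)
  })
  manifest <- list(
    package_version = as.character(utils::packageVersion("tractvlsm")),
    n_patients = res$cohort$n, grid = res$cohort$grid[c("shape", "voxel_size")],
    params = res$params, vlsm = fdr_info, log = res$log
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
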