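#' Default end-to-end pipeline configuration
#'
#' Collects every stage parameter in one list: the synthetic cohort (or
#' paths to real inputs), BHM layout, permutation iterations, ROI size,
#' target-set size, and the k range for trajectory clustering. The master
#' seed propagates deterministic sub-seeds to every stochastic stage.
#'
#' @param cohort a [cohort_config()]; ignored when `volumes_csv` is given.
#' @param volumes_csv,tree_json,annotation_csv optional paths to real
#'   inputs (volume table CSV, anatomy tree JSON, anxiety annotation CSV).
#' @param wildtype wild-type strain label for `volumes_csv` input.
#' @param bhm a [bhm_spec()]; its seed is overridden from `seed`.
#' @param perm_iter permutation iterations.
#' @param roi_k ROI size (capped at the number of regions).
#' @param target_n target-set size (capped at the gene count).
#' @param n_genes,boost,term_size expression-atlas stage: gene count,
#'   enrichment boost of the planted term inside the ROI, planted-term size.
#' @param k_range candidate k for trajectory clustering.
#' @param hellinger_mode passed to [hellinger_matrix()].
#' @param allow_unconverged proceed past a non-converged BHM (default stop).
#' @param seed master seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            volumes_csv = NULL, tree_json = NULL,
                            annotation_csv = NULL, wildtype = "WT",
                            bhm = bhm_spec(),
                            perm_iter = 1e4, roi_k = 5, target_n = 400,
                            n_genes = 2000, boost = 3, term_size = 100,
                            k_range = 2:8,
                            hellinger_mode = "joint-diagonal",
                            allow_unconverged = FALSE, seed = 1L) {
  structure(list(cohort = cohort, volumes_csv = volumes_csv,
                 tree_json = tree_json, annotation_csv = annotation_csv,
                 wildtype = wildtype, bhm = bhm, perm_iter = perm_iter,
                 roi_k = roi_k, target_n = target_n, n_genes = n_genes,
                 boost = boost, term_size = term_size, k_range = k_range,
                 hellinger_mode = hellinger_mode,
                 allow_unconverged = allow_unconverged,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

pipeline_error <- function(stage, message) {
  stop(structure(class = c("pipeline_error", "error", "condition"),
                 list(message = paste0("[stage ", stage, "] ", message),
                      call = NULL, stage = stage)))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: simulate (or load) -> aggregate to bilateral regions
#' -> standardise -> frequentist per-structure tests -> BHM -> effect sizes
#' and susceptibility -> Hellinger distances, similarity network, anxiety
#' permutation test and eta-squared -> ROI -> expression atlas (synthetic,
#' with the planted term boosted in the true ROI) -> fold change, target
#' set, hypergeometric enrichment, KS comparison -> developmental trajectory
#' clustering. Outputs are written as tidy CSV/JSON files under `out_dir`,
#' and a manifest records the configuration, per-stage wall-clock time, and
#' an MD5 checksum of every written file; re-running with the same
#' configuration reproduces identical checksums.
#'
#' A non-converged BHM halts the pipeline (a typed `pipeline_error` naming
#' the stage) unless `allow_unconverged` is set in the configuration.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return the manifest (list of class `run_manifest`), invisibly; its
#'   `results` element holds the in-memory stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempdir(),
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- list()
  results <- list()
  files <- character(0)
  say <- function(...) if (!quiet) message(...)
  timed <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- tryCatch(expr, error = function(e) {
      if (inherits(e, "pipeline_error")) stop(e)
      pipeline_error(stage, conditionMessage(e))
    })
    stages[[stage]] <<- proc.time()[["elapsed"]] - t0
    say(sprintf("stage %-12s %6.1fs", stage, stages[[stage]]))
    val
  }
  emit <- function(name, writer) {
    path <- file.path(out_dir, name)
    writer(path)
    files <<- c(files, path)
    path
  }

  # -- input data -----------------------------------------------------------
  cohort <- timed("simulate", {
    if (!is.null(config$volumes_csv)) {
      if (!file.exists(config$volumes_csv))
        pipeline_error("simulate", "missing input file")
      list(volumes = read_volume_table(config$volumes_csv, config$wildtype),
           tree = read_anatomy_tree(config$tree_json),
           annotation = read_anxiety_annotation(config$annotation_csv),
           truth = NULL)
    } else {
      cc <- config$cohort
      cc$seed <- substream_seed(config$seed, 21)
      generate_cohort(cc)
    }
  })
  emit("volumes.csv", function(p) write_volume_table(cohort$volumes, p))
  emit("anatomy.json", function(p) write_anatomy_tree(cohort$tree, p))

  regions <- setdiff(
    unique(vapply(cohort$tree$children, function(n) n$name, character(1))),
    character(0))
  vt_regions <- timed("aggregate",
    aggregate_to_regions(cohort$volumes, cohort$tree, regions))
  sv <- timed("standardise", standardise_volumes(vt_regions))
  emit("standardised.csv", function(p) write_volume_table(sv, p))

  # -- frequentist ----------------------------------------------------------
  freq <- timed("freq", freq_analysis(sv))
  emit("f_tests.csv", function(p)
    utils::write.csv(freq$f_tests, p, row.names = FALSE))
  emit("t_tests.csv", function(p)
    utils::write.csv(freq$t_tests, p, row.names = FALSE))

  # -- Bayesian hierarchical model -----------------------------------------
  pd <- timed("bhm", {
    spec <- config$bhm
    spec$seed <- substream_seed(config$seed, 22)
    fit <- suppressWarnings(fit_bhm(sv, spec))
    if (!fit$converged && !config$allow_unconverged)
      pipeline_error("bhm", "model did not converge (set allow_unconverged)")
    fit
  })
  esd <- effect_size_draws(pd)
  summ <- prob_large_effect(esd)
  med <- apply(esd$d, c(2, 3, 4), stats::median)
  lo <- apply(esd$d, c(2, 3, 4), stats::quantile, probs = 0.025)
  hi <- apply(esd$d, c(2, 3, 4), stats::quantile, probs = 0.975)
  summ$d_median <- as.vector(med)
  summ$d_low95 <- as.vector(lo)
  summ$d_high95 <- as.vector(hi)
  emit("effect_sizes.csv", function(p)
    utils::write.csv(summ[, c("structure", "strain", "sex", "d_median",
                              "d_low95", "d_high95", "p_large")],
                     p, row.names = FALSE))
  susceptibility <- structure_susceptibility(esd)
  emit("susceptibility.csv", function(p)
    utils::write.csv(susceptibility, p, row.names = FALSE))

  # -- behaviour clustering -------------------------------------------------
  pp <- timed("distances", phenotype_posterior(pd))
  H <- hellinger_matrix(pp, mode = config$hellinger_mode)
  emit("hellinger.csv", function(p)
    utils::write.csv(as.data.frame(unclass(H)), p))
  net <- similarity_network(H)
  emit("network_edges.csv", function(p)
    utils::write.csv(attr(net, "edges"), p, row.names = FALSE))
  perm <- timed("permtest", {
    anxiety_permutation_test(H, anxiety_annotation(cohort$annotation$strain,
                                                   cohort$annotation$anxiety,
                                                   cohort$annotation$assumed,
                                                   cohort$annotation$source),
                             n_iter = config$perm_iter,
                             seed = substream_seed(config$seed, 23))
  })
  emit("permutation.json", function(p)
    jsonlite::write_json(list(delta_obs = perm$delta_obs, p = perm$p,
                              n_iterations = perm$n_iterations,
                              statistic = perm$statistic),
                         p, auto_unbox = TRUE, digits = NA))
  eta <- timed("eta", eta_squared_draws(
    pp, anxiety_annotation(cohort$annotation$strain,
                           cohort$annotation$anxiety)))
  emit("eta_squared.csv", function(p)
    utils::write.csv(eta$summary, p, row.names = FALSE))

  # -- expression enrichment ------------------------------------------------
  roi <- timed("roi", select_roi(susceptibility,
                                 k = min(config$roi_k, nrow(susceptibility))))
  emit("roi.json", function(p)
    jsonlite::write_json(list(structures = roi$structures, k = roi$k),
                         p, auto_unbox = TRUE, digits = NA))
  atlas <- timed("expression", {
    genes <- sprintf("gene%05d", seq_len(config$n_genes))
    planted <- list(planted_term = genes[seq_len(config$term_size)])
    generate_expression_atlas(
      n_genes = config$n_genes,
      structures = susceptibility$structure,
      roi_structures = roi$structures,
      enriched_term_genes = planted, boost = config$boost,
      seed = substream_seed(config$seed, 24))
  })
  enr <- timed("enrich", {
    fc <- fold_change(atlas$expression, roi)
    tgt <- target_set(fc, min(config$target_n, nrow(fc)))
    list(fc = fc,
         table = hypergeom_enrich(tgt, atlas$gene_sets, atlas$genes),
         ks = ks_compare(fc, atlas$gene_sets$planted_term))
  })
  emit("fold_change.csv", function(p)
    utils::write.csv(enr$fc, p, row.names = FALSE))
  emit("enrichment.csv", function(p)
    utils::write.csv(enr$table, p, row.names = FALSE))
  clust <- timed("cluster-dev", cluster_trajectories(
    atlas$development, genes = atlas$gene_sets$planted_term,
    k_range = config$k_range, seed = substream_seed(config$seed, 25)))
  emit("dev_clusters.csv", function(p)
    utils::write.csv(data.frame(gene = names(clust$cluster),
                                cluster = unname(clust$cluster)),
                     p, row.names = FALSE))

  manifest <- structure(list(
    config = config,
    stage_seconds = unlist(stages),
    checksums = tools::md5sum(files),
    convergence = list(converged = pd$converged,
                       max_rhat = max(pd$diagnostics$rhat),
                       min_ess = min(pd$diagnostics$ess)),
    versions = list(R = as.character(getRversion()),
                    phenoscape = as.character(utils::packageVersion("phenoscape"))),
    results = list(cohort = cohort, freq = freq, posterior = pd,
                   effect_sizes = esd, susceptibility = susceptibility,
                   hellinger = H, network = net, permutation = perm,
                   eta = eta, roi = roi, atlas = atlas, enrichment = enr,
                   clusters = clust)),
    class = "run_manifest")
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(list(stage_seconds = as.list(manifest$stage_seconds),
                            checksums = as.list(manifest$checksums),
                            convergence = manifest$convergence,
                            versions = manifest$versions,
                            seed = config$seed),
                       mpath, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
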