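#' Null calibration of the differential-expression screen
#'
#' Simulates a no-signal experiment (`deg_fraction = 0`), runs the full
#' screen, and reports the fraction of genes with p <= `level`. For a
#' calibrated test this fraction should sit near (for a conservative
#' exact test, somewhat below) `level`.
#'
#' @param n_genes,n_replicates,dispersion generator settings.
#' @param level nominal test level examined (default 0.05).
#' @param seed random seed.
#' @return List: `fraction` of genes with p <= level, `n_genes`.
#' @export
null_calibration_experiment <- function(n_genes = 2000,
                                        n_replicates = 3,
                                        dispersion = 0.05,
                                        level = 0.05, seed = 1) {
  cfg <- simulation_config(n_genes = n_genes,
                           n_replicates = n_replicates,
                           deg_fraction = 0, dispersion = dispersion,
                           n_modules = 0, seed = seed)
  gen <- generate_counts(cfg)
  degs <- call_degs(gen$cm)
  list(fraction = mean(degs$p_value <= level), n_genes = nrow(degs))
}

#' DEG and enrichment parameter recovery over repeated simulations
#'
#' For each seed: simulate `n_genes` genes with a planted DEG fraction
#' at |log2FC| = `lfc_magnitude`, run the screen at the default
#' thresholds, and score sensitivity and the realized false discovery
#' proportion against the planted truth; then build a gene-set
#' collection with `n_enriched` planted enriched sets and check whether
#' they occupy the top `n_enriched` positions of the Fisher enrichment
#' ranking of the called DEGs.
#'
#' @param n_seeds number of independent simulations.
#' @param base_seed seeds are `base_seed + 1 ... base_seed + n_seeds`.
#' @param n_genes,deg_fraction,lfc_magnitude,n_replicates,dispersion
#'   generator settings (defaults plant 200 DEGs at |log2FC| = 2 among
#'   2000 genes, n = 3 per condition).
#' @param n_sets,n_enriched gene-set collection settings.
#' @return List: `per_seed` data.frame (`seed`, `sensitivity`, `fdp`,
#'   `top_k_recovered`), plus means `sensitivity`, `fdp`, and
#'   `enrichment_top_k_fraction` (fraction of seeds where all planted
#'   sets ranked in the top k).
#' @export
deg_recovery_experiment <- function(n_seeds = 20, base_seed = 100,
                                    n_genes = 2000,
                                    deg_fraction = 0.1,
                                    lfc_magnitude = 2,
                                    n_replicates = 3,
                                    dispersion = 0.05, n_sets = 50,
                                    n_enriched = 3) {
  res <- vector("list", n_seeds)
  for (i in seq_len(n_seeds)) {
    seed <- base_seed + i
    cfg <- simulation_config(n_genes = n_genes,
                             n_replicates = n_replicates,
                             deg_fraction = deg_fraction,
                             lfc_magnitude = lfc_magnitude,
                             dispersion = dispersion, n_modules = 0,
                             seed = seed)
    gen <- generate_counts(cfg)
    degs <- call_degs(gen$cm)
    truth <- gen$truth
    true_deg <- c(truth$deg_ids_up, truth$deg_ids_down)
    called <- degs$gene[degs$call != "ns"]
    sens <- length(intersect(called, true_deg)) / length(true_deg)
    fdp <- if (length(called))
      length(setdiff(called, true_deg)) / length(called) else 0

    coll <- generate_genesets(truth, n_sets = n_sets,
                              n_enriched = n_enriched,
                              seed = seed)
    coll <- restrict_collection(coll, degs$gene)
    er <- fisher_enrich(intersect(called, coll$universe), coll,
                        direction = "up")
    top <- er$set_id[seq_len(n_enriched)]
    rec <- all(coll$enriched_set_ids %in% top)
    res[[i]] <- data.frame(seed = seed, sensitivity = sens,
                           fdp = fdp, top_k_recovered = rec)
  }
  per_seed <- do.call(rbind, res)
  list(per_seed = per_seed,
       sensitivity = mean(per_seed$sensitivity),
       fdp = mean(per_seed$fdp),
       enrichment_top_k_fraction = mean(per_seed$top_k_recovered))
}

#' Default generator settings for co-expression recovery studies
#'
#' Correlation-level structure is not estimable at the DEG screen's
#' n = 3: a |r| >= 0.9 edge rule needs enough replicates for the sample
#' correlation to concentrate. These settings — 30 replicates, low
#' dispersion (0.01), baseline means 10^2 to 10^3.5, one 15-gene module
#' with latent-factor sigma 0.8 — were fixed by an a-priori Fisher-z
#' power calculation (see the methods vignette) so that true module
#' correlations (~0.98) clear the 0.9 threshold with probability near
#' 1 while null pairs essentially never do.
#'
#' @param seed random seed.
#' @param n_genes,n_replicates,module_size,module_sigma,dispersion
#'   overrides of the study defaults.
#' @return A [simulation_config()].
#' @export
coexpression_study_config <- function(seed = 1, n_genes = 200,
                                      n_replicates = 30,
                                      module_size = 15,
                                      module_sigma = 0.8,
                                      dispersion = 0.01) {
  simulation_config(n_genes = n_genes, n_replicates = n_replicates,
                    deg_fraction = 0, dispersion = dispersion,
                    baseline_mean_log_range = c(2, 3.5),
                    n_modules = 1, module_size = module_size,
                    module_condition = "A",
                    module_sigma = module_sigma, seed = seed)
}

#' Planted condition-specific hub recovery
#'
#' For each seed: simulate one co-expression module active in condition
#' A only (each module gene has 14 planted partners, so degree ~14 and
#' core ~14 in network A, isolated in network B), build both condition
#' networks over all genes, and check whether the module's designated
#' hub is called a core regulatory factor (DifDegree >= 12 and
#' DifKcore >= 8).
#'
#' @param n_seeds number of independent simulations.
#' @param base_seed seeds are `base_seed + 1 ...`.
#' @param ... overrides passed to [coexpression_study_config()].
#' @return List: `per_seed` logical vector of hub calls, `fraction`
#'   recovered, and the last seed's `report` for inspection.
#' @export
hub_recovery_experiment <- function(n_seeds = 20, base_seed = 200,
                                    ...) {
  hits <- logical(n_seeds)
  report <- NULL
  for (i in seq_len(n_seeds)) {
    cfg <- coexpression_study_config(seed = base_seed + i, ...)
    gen <- generate_counts(cfg)
    nets <- coexpression_networks(gen$cm, gen$truth$universe)
    report <- differential_report(nets[[1]], nets[[2]])
    hub <- gen$truth$hub_ids[1]
    hits[i] <- hub %in% report$gene &&
      report$is_core_regulator[match(hub, report$gene)]
  }
  list(per_seed = hits, fraction = mean(hits), report = report)
}
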