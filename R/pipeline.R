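#' Pipeline configuration
#'
#' One object holding every stage threshold (defaulting to the analysis'
#' standard settings: |log2FC| >= 0.585 with FDR <= 0.05 for DEGs,
#' P <= 0.01 for GO-like terms, FDR <= 0.05 for pathway-like terms,
#' P <= 0.05 for network node inclusion, |r| >= 0.9 co-expression edges,
#' DifDegree >= 12 and DifKcore >= 8 core-regulator calls), the file
#' paths of user-supplied inputs, and the synthetic-mode generator
#' settings.
#'
#' @param mode `"synthetic"` (inputs are generated, ground truth and a
#'   recovery scorecard are written) or `"user-data"` (inputs read from
#'   the given paths).
#' @param out_dir run directory for all artifacts.
#' @param counts,conditions,go_gmt,pathway_gmt,gene_relations,pathway_relations
#'   input paths (user-data mode).
#' @param lfc_min,fdr_max,go_p_max,pathway_fdr_max,network_p_max,r_min,coexp_alpha,dif_degree_min,dif_kcore_min
#'   stage thresholds.
#' @param seed random seed driving every stochastic step.
#' @param sim a [simulation_config()] (synthetic mode); its seed is
#'   overridden by `seed`.
#' @param n_gene_relations,n_pathway_sets,n_enriched_sets,n_pathway_relations
#'   synthetic-mode sizes of the generated annotation files.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "user-data"),
                            out_dir = "difnet_run",
                            counts = NULL, conditions = NULL,
                            go_gmt = NULL, pathway_gmt = NULL,
                            gene_relations = NULL,
                            pathway_relations = NULL,
                            lfc_min = 0.585, fdr_max = 0.05,
                            go_p_max = 0.01, pathway_fdr_max = 0.05,
                            network_p_max = 0.05, r_min = 0.9,
                            coexp_alpha = 0.05, dif_degree_min = 12,
                            dif_kcore_min = 8, seed = 1,
                            sim = simulation_config(),
                            n_gene_relations = 3000,
                            n_pathway_sets = 50,
                            n_enriched_sets = 3,
                            n_pathway_relations = 120) {
  mode <- match.arg(mode)
  for (nm in c("fdr_max", "go_p_max", "pathway_fdr_max",
               "network_p_max", "r_min", "coexp_alpha"))
    assert_scalar_number(get(nm), nm, min = 0, max = 1)
  assert_scalar_number(lfc_min, "lfc_min", min = 0)
  assert_scalar_number(dif_degree_min, "dif_degree_min", min = 0)
  assert_scalar_number(dif_kcore_min, "dif_kcore_min", min = 0)
  assert_scalar_number(seed, "seed", integer = TRUE)
  structure(list(mode = mode, out_dir = out_dir, counts = counts,
                 conditions = conditions, go_gmt = go_gmt,
                 pathway_gmt = pathway_gmt,
                 gene_relations = gene_relations,
                 pathway_relations = pathway_relations,
                 lfc_min = lfc_min, fdr_max = fdr_max,
                 go_p_max = go_p_max,
                 pathway_fdr_max = pathway_fdr_max,
                 network_p_max = network_p_max, r_min = r_min,
                 coexp_alpha = coexp_alpha,
                 dif_degree_min = dif_degree_min,
                 dif_kcore_min = dif_kcore_min, seed = seed,
                 sim = sim, n_gene_relations = n_gene_relations,
                 n_pathway_sets = n_pathway_sets,
                 n_enriched_sets = n_enriched_sets,
                 n_pathway_relations = n_pathway_relations),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Scalar fields of the file override [pipeline_config()] defaults;
#' a `sim:` block overrides [simulation_config()] defaults.
#'
#' @param path YAML (`.yml`/`.yaml`, needs the yaml package) or JSON
#'   file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop2("reading YAML configs requires the yaml package")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  sim <- do.call(simulation_config, as.list(x$sim %||% list()))
  x$sim <- NULL
  do.call(pipeline_config, c(x, list(sim = sim)))
}

run_stage <- function(stage, out_dir, expr) {
  tryCatch(expr, error = function(e) {
    writeLines(c(paste("stage:", stage), conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop2("pipeline stage '", stage, "' failed: ",
          conditionMessage(e))
  })
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — input acquisition (generation in
#' synthetic mode), differential-expression screen, direction-split
#' GO-like and pathway-like enrichment, pathway and gene interaction
#' networks, per-condition co-expression networks with the differential
#' (DifDegree/DifKcore) report — and writes every table, network and a
#' provenance record under `config$out_dir`. In synthetic mode the
#' planted truth and a recovery scorecard (DEG sensitivity and false
#' discovery proportion, planted-enrichment top-k recovery, planted-hub
#' recovery) are written as well. Any stage failure leaves a `FAILED`
#' marker naming the stage; partial outputs are retained.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the main in-memory results (`degs`,
#'   `enrichment`, `networks`, `coexpression`, `report`, `provenance`,
#'   and in synthetic mode `truth` and `scorecard`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  if (file.exists(file.path(out, "FAILED")))
    unlink(file.path(out, "FAILED"))
  # out_dir is where provenance lives, not an analysis setting; keeping
  # it out makes equal-config runs byte-identical wherever they land
  cfg_rec <- config[setdiff(names(config), c("sim", "out_dir"))]
  cfg_rec$sim <- unclass(config$sim)
  prov <- list(config = cfg_rec,
               package_version =
                 as.character(utils::packageVersion("difnet")),
               warnings = list(), funnel = list())
  truth <- NULL

  # --- inputs -------------------------------------------------------
  if (config$mode == "synthetic") {
    run_stage("simulate", out, {
      sim <- config$sim
      sim$seed <- config$seed
      gen <- generate_counts(sim)
      cm <- gen$cm
      truth <- gen$truth
      go <- generate_genesets(truth, n_sets = config$n_pathway_sets,
                              n_enriched = config$n_enriched_sets,
                              kind = "go_like",
                              seed = config$seed + 1L)
      pw <- generate_genesets(truth, n_sets = config$n_pathway_sets,
                              n_enriched = config$n_enriched_sets,
                              kind = "pathway_like",
                              seed = config$seed + 2L)
      grel <- generate_relations(truth$universe,
                                 config$n_gene_relations,
                                 seed = config$seed + 3L)
      prel <- generate_relations(names(pw$sets),
                                 config$n_pathway_relations,
                                 seed = config$seed + 4L)
      truth$enriched_set_ids <- pw$enriched_set_ids
      dir.create(file.path(out, "inputs"), showWarnings = FALSE)
      write_count_matrix(cm, file.path(out, "inputs", "counts.tsv"),
                         file.path(out, "inputs", "conditions.tsv"))
      write_gmt(go, file.path(out, "inputs", "go_like.gmt"))
      write_gmt(pw, file.path(out, "inputs", "pathway_like.gmt"))
      write_relations(grel,
                      file.path(out, "inputs", "gene_relations.tsv"))
      write_relations(prel,
                      file.path(out, "inputs",
                                "pathway_relations.tsv"))
      write_truth(truth, file.path(out, "truth.json"))
    })
  } else {
    run_stage("load-inputs", out, {
      cm <- read_count_matrix(config$counts, config$conditions)
      go <- if (!is.null(config$go_gmt))
        read_gmt(config$go_gmt, kind = "go_like")
      pw <- if (!is.null(config$pathway_gmt))
        read_gmt(config$pathway_gmt, kind = "pathway_like")
      grel <- if (!is.null(config$gene_relations))
        read_relations(config$gene_relations)
      prel <- if (!is.null(config$pathway_relations))
        read_relations(config$pathway_relations)
    })
  }
  prov$funnel$genes_input <- nrow(cm$counts)

  # --- differential expression -------------------------------------
  degs <- run_stage("deg-calling", out, {
    d <- call_degs(cm, lfc_min = config$lfc_min,
                   fdr_max = config$fdr_max)
    write_deg_table(d, file.path(out, "degs.tsv"))
    d
  })
  split <- split_by_direction(degs)
  prov$funnel$genes_tested <- nrow(degs)
  prov$funnel$degs_up <- length(split$up)
  prov$funnel$degs_down <- length(split$down)
  prov$warnings$n_gaussian_fallback <-
    attr(degs, "metadata")$n_gaussian_fallback
  prov$warnings$genes_dropped_all_zero <-
    length(attr(degs, "dropped_genes"))

  # --- enrichment ---------------------------------------------------
  enr <- run_stage("enrichment", out, {
    res <- list()
    for (kind in c("go", "pathway")) {
      coll <- if (kind == "go") go else pw
      if (is.null(coll)) next
      coll <- restrict_collection(coll, degs$gene)
      for (dir in c("up", "down")) {
        r <- fisher_enrich(intersect(split[[dir]], coll$universe),
                           coll, direction = dir,
                           p_max = config$go_p_max,
                           fdr_max = config$pathway_fdr_max)
        nm <- paste0(kind, "_", dir)
        write_tsv(as.data.frame(r),
                  file.path(out, paste0("enrichment_", nm, ".tsv")))
        res[[nm]] <- r
      }
    }
    res
  })
  prov$funnel$enrichment_inputs <-
    list(up = length(split$up), down = length(split$down))

  # --- interaction networks ----------------------------------------
  nets <- run_stage("interaction-networks", out, {
    res <- list()
    if (!is.null(grel)) {
      sig <- data.frame(id = c(split$up, split$down),
                        direction = rep(c("up", "down"),
                                        c(length(split$up),
                                          length(split$down))))
      res$gene <- build_interaction_network(sig, grel,
                                            level = "gene")
      write_interaction_network(
        res$gene, file.path(out, "gene_network.graphml"),
        file.path(out, "gene_network_edges.tsv"),
        file.path(out, "gene_network_nodes.tsv"))
    }
    if (!is.null(prel) && length(enr)) {
      pwres <- rbind(as.data.frame(enr$pathway_up),
                     as.data.frame(enr$pathway_down))
      pwres <- pwres[pwres$significant, , drop = FALSE]
      pwres <- pwres[!duplicated(pwres$set_id), , drop = FALSE]
      sig <- data.frame(id = pwres$set_id,
                        direction = pwres$direction,
                        p_value = pwres$p_value)
      res$pathway <- build_interaction_network(
        sig, prel, p_threshold = config$network_p_max,
        level = "pathway")
      write_interaction_network(
        res$pathway, file.path(out, "pathway_network.graphml"),
        file.path(out, "pathway_network_edges.tsv"),
        file.path(out, "pathway_network_nodes.tsv"))
    }
    res
  })
  if (!is.null(nets$gene))
    prov$warnings$gene_relations_skipped <- nets$gene$skipped_edges
  if (!is.null(nets$pathway))
    prov$warnings$pathway_relations_skipped <-
      nets$pathway$skipped_edges

  # --- co-expression ------------------------------------------------
  coexp <- NULL
  report <- NULL
  run_stage("coexpression", out, {
    deg_ids <- c(split$up, split$down)
    if (length(deg_ids) >= 2) {
      coexp <- coexpression_networks(cm, deg_ids,
                                     r_min = config$r_min,
                                     alpha = config$coexp_alpha)
      for (l in names(coexp))
        write_coexpression_network(
          coexp[[l]],
          file.path(out, paste0("coexpression_", l, ".graphml")),
          file.path(out, paste0("coexpression_", l, "_edges.tsv")))
      report <- differential_report(
        coexp[[1]], coexp[[2]],
        dif_degree_min = config$dif_degree_min,
        dif_kcore_min = config$dif_kcore_min)
      write_tsv(as.data.frame(report),
                file.path(out, "differential_report.tsv"))
      write_json_file(attr(report, "summary"),
                      file.path(out, "coexpression_summary.json"))
    } else {
      # no DEGs: empty report, pipeline still completes
      write_tsv(data.frame(gene = character(0)),
                file.path(out, "differential_report.tsv"))
    }
  })
  if (!is.null(report))
    prov$funnel$coexpression <- attr(report, "summary")

  # --- scorecard & provenance --------------------------------------
  scorecard <- NULL
  if (config$mode == "synthetic") {
    scorecard <- run_stage("scorecard", out, {
      sc <- recovery_scorecard(degs, enr, report, truth,
                               n_enriched = config$n_enriched_sets)
      write_json_file(sc, file.path(out, "scorecard.json"))
      sc
    })
  }
  write_json_file(prov, file.path(out, "provenance.json"))
  invisible(list(degs = degs, enrichment = enr, networks = nets,
                 coexpression = coexp, report = report,
                 provenance = prov, truth = truth,
                 scorecard = scorecard))
}

#' Rebase a gene-set collection onto the tested genes
#'
#' Sets the background universe to the genes that actually entered the
#' differential-expression screen (the standard enrichment background),
#' intersecting every set with it and dropping sets left empty.
#'
#' @param collection a [geneset_collection()].
#' @param tested character vector of tested gene ids.
#' @return A [geneset_collection()] over the tested-gene universe.
#' @export
restrict_collection <- function(collection, tested) {
  universe <- tested
  sets <- lapply(collection$sets, intersect, universe)
  sets <- sets[lengths(sets) > 0]
  geneset_collection(sets, universe, kind = collection$kind,
                     enriched_set_ids = collection$enriched_set_ids)
}

#' Score a synthetic run against its planted truth
#'
#' @param degs a `deg_table`.
#' @param enr list of `enrichment_result`s from [run_pipeline()].
#' @param report a `differential_network_report` (or NULL).
#' @param truth the `planted_truth`.
#' @param n_enriched number of planted enriched sets.
#' @return List with DEG sensitivity / false discovery proportion /
#'   direction accuracy, planted-enrichment top-k recovery per
#'   collection, and planted-hub recovery.
#' @export
recovery_scorecard <- function(degs, enr, report, truth,
                               n_enriched = 3) {
  true_deg <- c(truth$deg_ids_up, truth$deg_ids_down)
  called <- degs$gene[degs$call != "ns"]
  sens <- if (length(true_deg))
    length(intersect(called, true_deg)) / length(true_deg) else NA
  fdp <- if (length(called))
    length(setdiff(called, true_deg)) / length(called) else 0
  dir_ok <- mean(c(
    degs$call[degs$gene %in% truth$deg_ids_up] == "up",
    degs$call[degs$gene %in% truth$deg_ids_down] == "down"))
  enr_rec <- lapply(enr, function(r) {
    top <- r$set_id[seq_len(min(n_enriched, nrow(r)))]
    planted <- intersect(truth$enriched_set_ids, r$set_id)
    if (!length(planted)) return(NA)
    length(intersect(top, planted)) / length(planted)
  })
  hub_rec <- NA
  if (!is.null(report) && length(truth$hub_ids)) {
    found <- intersect(truth$hub_ids, report$gene)
    hub_rec <- if (length(found))
      mean(report$is_core_regulator[match(found, report$gene)])
    else 0
  }
  list(deg_sensitivity = sens, deg_fdp = fdp,
       deg_direction_accuracy = dir_ok,
       enrichment_topk_recovery = enr_rec,
       planted_hub_recovery = hub_rec)
}
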