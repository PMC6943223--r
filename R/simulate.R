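#' Simulation configuration for the synthetic-data generator
#'
#' Describes a two-condition replicated RNA-seq experiment with planted
#' structure: a fraction of genes with a known log2 fold change, and
#' co-expression modules driven by a shared latent factor that is active
#' in one condition only. Counts are negative binomial with
#' `variance = mu + dispersion * mu^2`.
#'
#' @param n_genes number of genes.
#' @param n_replicates replicates per condition; the default 3 mirrors a
#'   typical adenovirus-overexpression RNA-seq design (n = 3 per group).
#' @param deg_fraction proportion of genes planted as differentially
#'   expressed; `round(deg_fraction * n_genes)` genes are planted.
#' @param lfc_magnitude absolute log2 fold change of planted DEGs; the
#'   planted set is split half up-, half down-regulated.
#' @param dispersion global NB dispersion alpha (>= 0); 0.05 is typical
#'   for isogenic cell-line replicates. 0 gives Poisson counts.
#' @param baseline_mean_log_range log10 bounds of the log-uniform
#'   baseline mean distribution; the default `c(0.5, 3.5)` spans the
#'   usual RNA-seq dynamic range (~3 to ~3000 mean counts).
#' @param n_modules number of planted co-expression modules.
#' @param module_size genes per module; modules are disjoint and drawn
#'   from non-DEG genes so that DEG and module ground truths stay
#'   independent. Default 15, so each module gene has 14 planted
#'   co-expression partners.
#' @param module_condition condition ("A"/"B") in which each module's
#'   latent factor is active; recycled to `n_modules`.
#' @param module_sigma log-scale s.d. of the per-sample lognormal latent
#'   factor shared by a module's genes (mean-centred so marginal means
#'   are unchanged).
#' @param per_gene_dispersion_sd optional lognormal spread of per-gene
#'   dispersion around `dispersion` (0 = single global value, the
#'   default, which keeps parameter-recovery tests interpretable).
#' @param seed integer random seed; all outputs are deterministic given
#'   the config.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 2000, n_replicates = 3,
                              deg_fraction = 0.1, lfc_magnitude = 1.0,
                              dispersion = 0.05,
                              baseline_mean_log_range = c(0.5, 3.5),
                              n_modules = 2, module_size = 15,
                              module_condition = c("A", "B"),
                              module_sigma = 0.5,
                              per_gene_dispersion_sd = 0,
                              seed = 1) {
  assert_scalar_number(n_genes, "n_genes", min = 1, integer = TRUE)
  assert_scalar_number(n_replicates, "n_replicates", min = 1,
                       integer = TRUE)
  assert_scalar_number(deg_fraction, "deg_fraction", min = 0, max = 1)
  assert_scalar_number(lfc_magnitude, "lfc_magnitude", min = 0)
  assert_scalar_number(dispersion, "dispersion", min = 0)
  if (!is.numeric(baseline_mean_log_range) ||
      length(baseline_mean_log_range) != 2L ||
      diff(baseline_mean_log_range) < 0)
    stop2("baseline_mean_log_range must be increasing log10 bounds")
  assert_scalar_number(n_modules, "n_modules", min = 0, integer = TRUE)
  assert_scalar_number(module_size, "module_size", min = 2,
                       integer = TRUE)
  assert_scalar_number(module_sigma, "module_sigma", min = 0)
  assert_scalar_number(per_gene_dispersion_sd, "per_gene_dispersion_sd",
                       min = 0)
  assert_scalar_number(seed, "seed", integer = TRUE)
  if (n_modules > 0) {
    module_condition <- rep_len(as.character(module_condition),
                                n_modules)
    if (!all(module_condition %in% c("A", "B")))
      stop2("module_condition labels must be 'A' or 'B'")
  } else module_condition <- character(0)
  n_deg <- round(deg_fraction * n_genes)
  if (n_deg + n_modules * module_size > n_genes)
    stop2("planted DEGs plus module genes exceed n_genes")
  structure(list(n_genes = n_genes, n_replicates = n_replicates,
                 deg_fraction = deg_fraction,
                 lfc_magnitude = lfc_magnitude, dispersion = dispersion,
                 baseline_mean_log_range = baseline_mean_log_range,
                 n_modules = n_modules, module_size = module_size,
                 module_condition = module_condition,
                 module_sigma = module_sigma,
                 per_gene_dispersion_sd = per_gene_dispersion_sd,
                 seed = seed),
            class = "simulation_config")
}

#' Generate a synthetic count matrix with planted ground truth
#'
#' Draws NB counts for 2 conditions x `n_replicates`. Planted DEGs have
#' condition-B mean equal to the condition-A mean times
#' `2^(+/- lfc_magnitude)`. Genes of a module share, in the module's
#' active condition only, a per-sample lognormal factor
#' `exp(sigma*Z - sigma^2/2)` multiplying their means, which induces
#' within-condition co-expression without shifting marginal means.
#'
#' @param config a [simulation_config()].
#' @return A list with elements `cm` (a [count_matrix()]) and `truth`
#'   (class `planted_truth`): `deg_ids_up`, `deg_ids_down`, `true_lfc`
#'   (named signed log2 fold changes, 0 for non-DEGs), `module_membership`
#'   (named integer, NA for genes outside modules), `module_condition`,
#'   `hub_ids` (one designated hub per module), and `universe` (all gene
#'   ids).
#' @export
generate_counts <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  ng <- config$n_genes; nr <- config$n_replicates
  genes <- sprintf("g%0*d", nchar(ng), seq_len(ng))
  samples <- c(paste0("A_", seq_len(nr)), paste0("B_", seq_len(nr)))
  cond <- rep(c("A", "B"), each = nr)

  rng <- config$baseline_mean_log_range
  mu0 <- 10^stats::runif(ng, rng[1], rng[2])

  n_deg <- round(config$deg_fraction * ng)
  n_up <- ceiling(n_deg / 2)
  deg_idx <- if (n_deg > 0) sample.int(ng, n_deg) else integer(0)
  up_idx <- deg_idx[seq_len(n_up)]
  down_idx <- setdiff(deg_idx, up_idx)
  lfc <- numeric(ng)
  lfc[up_idx] <- config$lfc_magnitude
  lfc[down_idx] <- -config$lfc_magnitude

  module <- rep(NA_integer_, ng)
  hub_idx <- integer(0)
  if (config$n_modules > 0) {
    pool <- setdiff(seq_len(ng), deg_idx)
    picked <- sample(pool, config$n_modules * config$module_size)
    module[picked] <- rep(seq_len(config$n_modules),
                          each = config$module_size)
    # first gene drawn for each module is its designated hub
    hub_idx <- picked[seq(1, length(picked), by = config$module_size)]
  }

  disp <- rep(config$dispersion, ng)
  if (config$per_gene_dispersion_sd > 0 && config$dispersion > 0)
    disp <- config$dispersion *
      stats::rlnorm(ng, -config$per_gene_dispersion_sd^2 / 2,
                    config$per_gene_dispersion_sd)

  # per-gene, per-sample expected counts
  mu <- matrix(mu0, ng, 2 * nr)
  mu[, cond == "B"] <- mu[, cond == "B"] * 2^lfc
  if (config$n_modules > 0 && config$module_sigma > 0) {
    s <- config$module_sigma
    for (m in seq_len(config$n_modules)) {
      active <- cond == config$module_condition[m]
      fac <- exp(s * stats::rnorm(sum(active)) - s^2 / 2)
      rows <- which(module == m)
      mu[rows, active] <- mu[rows, active] *
        matrix(fac, length(rows), sum(active), byrow = TRUE)
    }
  }

  counts <- matrix(0, ng, 2 * nr, dimnames = list(genes, samples))
  pois <- disp <= 0
  if (any(pois))
    counts[pois, ] <- stats::rpois(sum(pois) * 2 * nr, mu[pois, ])
  if (any(!pois))
    counts[!pois, ] <- stats::rnbinom(sum(!pois) * 2 * nr,
                                      mu = mu[!pois, ],
                                      size = 1 / disp[!pois])

  truth <- structure(list(
    deg_ids_up = genes[up_idx],
    deg_ids_down = genes[down_idx],
    true_lfc = stats::setNames(lfc, genes),
    module_membership = stats::setNames(module, genes),
    module_condition = config$module_condition,
    hub_ids = genes[hub_idx],
    enriched_set_ids = character(0),
    universe = genes), class = "planted_truth")
  list(cm = count_matrix(counts, cond), truth = truth)
}

#' Generate gene-set collections with planted enrichment
#'
#' Builds `n_sets` gene sets over the generator's gene universe.
#' `n_enriched` of them are planted enriched: at least `deg_member_frac`
#' of their members are drawn from the planted DEGs; the remaining sets
#' are uniform draws from the universe.
#'
#' @param truth a `planted_truth` from [generate_counts()].
#' @param n_sets total number of sets.
#' @param set_size_range integer bounds on set sizes.
#' @param n_enriched number of planted enriched sets (<= n_sets).
#' @param deg_member_frac minimum fraction of a planted set's members
#'   that are planted DEGs (default 0.5).
#' @param kind collection kind, `"go_like"` (significance on raw p) or
#'   `"pathway_like"` (significance on FDR).
#' @param seed random seed.
#' @return A [geneset_collection()] whose `enriched_set_ids` attribute
#'   names the planted sets (also copied into the returned object).
#' @export
generate_genesets <- function(truth, n_sets = 50,
                              set_size_range = c(10, 30),
                              n_enriched = 3, deg_member_frac = 0.5,
                              kind = "go_like", seed = 1) {
  stopifnot(inherits(truth, "planted_truth"))
  assert_scalar_number(n_sets, "n_sets", min = 1, integer = TRUE)
  assert_scalar_number(n_enriched, "n_enriched", min = 0,
                       integer = TRUE)
  if (n_enriched > n_sets)
    stop2("n_enriched must not exceed n_sets")
  universe <- truth$universe
  if (max(set_size_range) > length(universe))
    stop2("set size exceeds universe size")
  set.seed(seed)
  degs <- c(truth$deg_ids_up, truth$deg_ids_down)
  nondeg <- setdiff(universe, degs)
  sizes <- sample(seq(set_size_range[1], set_size_range[2]), n_sets,
                  replace = TRUE)
  sets <- vector("list", n_sets)
  names(sets) <- sprintf("set%03d", seq_len(n_sets))
  for (i in seq_len(n_sets)) {
    if (i <= n_enriched) {
      k <- min(ceiling(deg_member_frac * sizes[i]), length(degs))
      sets[[i]] <- sort(c(sample(degs, k),
                          sample(nondeg, sizes[i] - k)))
    } else {
      sets[[i]] <- sort(sample(universe, sizes[i]))
    }
  }
  geneset_collection(sets, universe, kind = kind,
                     enriched_set_ids = names(sets)[seq_len(n_enriched)])
}

#' Generate a typed relation table
#'
#' Samples `n_edges` unique (source, target, type) triples over the
#' given entities, with relation types drawn from the KEGG-style
#' vocabulary act / inh / bin / com / exp / dissociation according to
#' `type_weights`. Binding (`bin`) and compound (`com`) relations are
#' undirected; the rest are directed.
#'
#' @param entities character vector of node identifiers (genes or
#'   pathways).
#' @param n_edges number of relations to sample.
#' @param type_weights named numeric sampling weights over the relation
#'   vocabulary; names must be a subset of the six types.
#' @param seed random seed.
#' @return A [relation_table()].
#' @export
generate_relations <- function(entities, n_edges,
                               type_weights = c(act = 3, inh = 2,
                                                bin = 2, com = 1,
                                                exp = 2,
                                                dissociation = 0.5),
                               seed = 1) {
  assert_scalar_number(n_edges, "n_edges", min = 0, integer = TRUE)
  n <- length(entities)
  if (n_edges > n * (n - 1))
    stop2("n_edges exceeds the number of ordered entity pairs")
  bad <- setdiff(names(type_weights), relation_types())
  if (length(bad) || is.null(names(type_weights)))
    stop2("unknown relation type in weights: ",
          paste(bad, collapse = ", "))
  set.seed(seed)
  if (n_edges == 0)
    return(relation_table(data.frame(source = character(0),
                                     target = character(0),
                                     type = character(0))))
  types <- names(type_weights)[type_weights > 0]
  w <- type_weights[types]
  rows <- data.frame(source = character(0), target = character(0),
                     type = character(0))
  while (nrow(rows) < n_edges) {
    need <- n_edges - nrow(rows)
    src <- sample(entities, 2 * need, replace = TRUE)
    tgt <- sample(entities, 2 * need, replace = TRUE)
    ty <- sample(types, 2 * need, replace = TRUE, prob = w)
    cand <- data.frame(source = src, target = tgt, type = ty)
    cand <- cand[cand$source != cand$target, , drop = FALSE]
    rows <- unique(rbind(rows, cand))
    rows <- rows[seq_len(min(nrow(rows), n_edges)), , drop = FALSE]
  }
  relation_table(rows)
}

#' Write the planted truth as a JSON sidecar
#' @param truth a `planted_truth`.
#' @param path output path.
#' @export
write_truth <- function(truth, path) {
  x <- unclass(truth)
  x$module_membership <- as.list(
    x$module_membership[!is.na(x$module_membership)])
  x$true_lfc <- as.list(x$true_lfc[x$true_lfc != 0])
  write_json_file(x, path)
}
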