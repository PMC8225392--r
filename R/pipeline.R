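# End-to-end orchestration: load data, run the binomial family screen and
# NDGE, write result tables, volcano table, annotated GraphML and a JSON run
# summary. A config snapshot is written beside the outputs; re-running with
# the same config byte-reproduces all numeric outputs.

#' Assemble a run configuration
#'
#' @param neurons,chemical,electrical,contacts,expression input file paths
#'   (see [read_connectome], [read_contact_map], [read_expression]).
#' @param genes character vector of genes to screen; `NULL` means all genes
#'   in the expression table; `character(0)` runs nothing but still writes
#'   (empty) result tables.
#' @param exclusion_rule,pvalue_kind see [test_gene_family].
#' @param ndge list of [ndge_config] overrides (e.g.
#'   `list(n_rewires = 500)`), or `NULL` for defaults.
#' @param do_ndge run the NDGE stage (default `TRUE`).
#' @param fdr_level FDR level for the binomial screen's significance count.
#' @param out_dir output directory.
#' @param seed top-level seed; the NDGE rewiring substream is derived from it.
#' @return A list of class `run_config`, serializable to YAML.
#' @export
run_config <- function(neurons, chemical, electrical, contacts, expression,
                       genes = NULL,
                       exclusion_rule = "exclude_same_class",
                       pvalue_kind = "tail",
                       ndge = NULL, do_ndge = TRUE, fdr_level = 0.05,
                       out_dir, seed = 1L) {
  structure(list(neurons = neurons, chemical = chemical,
                 electrical = electrical, contacts = contacts,
                 expression = expression, genes = genes,
                 exclusion_rule = exclusion_rule, pvalue_kind = pvalue_kind,
                 ndge = ndge, do_ndge = do_ndge, fdr_level = fdr_level,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file whose keys match the arguments of [run_config].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

#' Run the full enrichment analysis
#'
#' Loads the connectome, contact map and expression atlas, restricts to
#' somatic neurons, runs the binomial pair-connectivity family screen and
#' (optionally) NDGE, and writes: `pair_enrichment.tsv`, `ndge.tsv`,
#' `volcano.tsv`, an annotated `network.graphml` (per-gene expression and
#' per-gene significance flags as node attributes), `summary.json`,
#' `config_snapshot.yaml` and `run.log`.
#'
#' @param config a [run_config], or the path to its YAML serialization.
#' @return Invisibly, the run summary list.
#' @export
run_full_analysis <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  for (f in c("neurons", "chemical", "electrical", "expression")) {
    if (!file.exists(config[[f]])) stop("input file missing: ", config[[f]])
  }
  if (config$do_ndge && !file.exists(config$contacts)) {
    stop("NDGE requested but contact file missing: ", config$contacts)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(config$out_dir, "run.log")
  loglines <- c("circuitenrich run",
                sprintf("seed=%d exclusion_rule=%s pvalue_kind=%s do_ndge=%s",
                        config$seed, config$exclusion_rule,
                        config$pvalue_kind, config$do_ndge))

  conn <- read_connectome(config$neurons, config$chemical, config$electrical)
  conn <- restrict_to_somatic(conn)
  expr <- read_expression(config$expression)
  ids <- neuron_ids(conn)
  miss_expr <- setdiff(ids, expr$neurons)
  contacts <- NULL
  miss_contact <- character(0)
  if (config$do_ndge) {
    contacts <- read_contact_map(config$contacts, union(ids, ids))
    miss_contact <- setdiff(ids, contacts$neuron_ids)
  }
  if (length(miss_expr) || length(miss_contact)) {
    stop("inconsistent neuron universes across inputs; missing from ",
         "expression: [", paste(miss_expr, collapse = ", "),
         "]; missing from contacts: [",
         paste(miss_contact, collapse = ", "), "]")
  }
  genes <- config$genes %||% expr$genes
  ndge_overrides <- config$ndge %||% list()
  ndge_overrides$seed <- derive_seed(config$seed, 11)
  ncfg <- do.call(ndge_config, ndge_overrides)
  loglines <- c(loglines,
                sprintf("ndge: n_rewires=%d include_electrical=%s mode=%s",
                        ncfg$n_rewires, ncfg$include_electrical,
                        ncfg$expression_mode),
                sprintf("neurons=%d genes=%d", length(ids), length(genes)))

  empty_pair <- data.frame(gene = character(), n_trials = integer(),
                           k_successes = integer(), p_success = numeric(),
                           pvalue_pmf = numeric(), pvalue_tail = numeric(),
                           qvalue = numeric(), testable = logical())
  pair_res <- if (length(genes)) {
    test_gene_family(conn, expr, genes, config$exclusion_rule,
                     config$pvalue_kind)
  } else empty_pair
  write_tsv(pair_res, file.path(config$out_dir, "pair_enrichment.tsv"))

  if (config$do_ndge) {
    ndge_res <- run_ndge(conn, contacts, expr, genes, ncfg)
  } else {
    ndge_res <- run_ndge(conn, contact_map(ids), expr, character(0), ncfg)
  }
  write_tsv(ndge_res, file.path(config$out_dir, "ndge.tsv"))
  write_tsv(volcano_table(ndge_res), file.path(config$out_dir, "volcano.tsv"))

  # annotated network: per-gene expression and significance as node attrs
  node_attrs <- data.frame(id = ids, stringsAsFactors = FALSE)
  if (length(genes)) {
    b <- expr_binary(expr)[genes, ids, drop = FALSE]
    for (g in genes) node_attrs[[paste0("expr_", g)]] <- as.integer(b[g, ])
    sig_b <- pair_res$gene[pair_res$testable &
                             pair_res$qvalue < config$fdr_level]
    sig_n <- ndge_res$gene[ndge_res$significant]
    node_attrs$n_sig_genes_expressed <-
      as.integer(colSums(b[unique(c(sig_b, sig_n)), ids, drop = FALSE]))
  }
  export_annotated_network(conn, node_attrs = node_attrs,
                           out_prefix = file.path(config$out_dir, "network"))

  pair_sig <- sum(pair_res$testable & pair_res$qvalue < config$fdr_level)
  summary <- list(
    n_neurons = length(ids),
    n_chemical_edges = nrow(conn$chemical),
    n_electrical_edges = nrow(conn$electrical),
    n_genes = length(genes),
    fdr_level = config$fdr_level,
    n_significant_pair_enrichment = pair_sig,
    n_significant_ndge = sum(ndge_res$significant),
    significant_pair_enrichment =
      pair_res$gene[pair_res$testable & pair_res$qvalue < config$fdr_level],
    significant_ndge = ndge_res$gene[ndge_res$significant],
    seed = config$seed)
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  snapshot <- unclass(config)
  snapshot$ndge <- unclass(ncfg)
  yaml::write_yaml(snapshot, file.path(config$out_dir, "config_snapshot.yaml"))
  writeLines(loglines, logf)
  invisible(summary)
}

#' Simulation study: power and false-discovery proportion of both tests
#'
#' For each condition, generates replicate synthetic datasets (one planted
#' circuit-organizer gene when `effect > 0`, none otherwise), runs the
#' binomial family screen and NDGE, and summarizes per condition: the power
#' to flag the planted gene, the proportion of replicates where it ranks
#' first by p-value, and the false-discovery proportion among background
#' genes at the configured FDR.
#'
#' @param conditions data.frame with columns `label`, `effect` (the planted
#'   within-circuit chemical edge probability; 0 = null condition) and
#'   optionally `n_circuit_classes` (default 5, i.e. 10 neurons).
#' @param n_replicates replicate datasets per condition.
#' @param base_config a [synthetic_config] supplying the background
#'   parameters (its `planted` and `seed` fields are overridden).
#' @param ndge list of [ndge_config] overrides (e.g. `list(n_rewires = 200)`).
#' @param fdr_level FDR level (default 0.05).
#' @param seed top-level seed; per-replicate seeds are derived from it.
#' @return data.frame with one row per condition: power, rank-1 proportion
#'   and FDP for each test, plus mean planted p-values. Attribute
#'   `"replicates"` holds the per-replicate records.
#' @export
run_simulation_study <- function(conditions, n_replicates,
                                 base_config = synthetic_config(),
                                 ndge = list(n_rewires = 200),
                                 fdr_level = 0.05, seed = 1L) {
  stopifnot(is.data.frame(conditions), all(c("label", "effect") %in%
                                             names(conditions)))
  if (n_replicates < 1) {
    warning("n_replicates = 0: returning an empty summary table")
    return(data.frame(label = character(), effect = numeric(),
                      n_replicates = integer(),
                      power_binomial = numeric(), power_ndge = numeric(),
                      rank1_binomial = numeric(),
                      fdp_binomial = numeric(), fdp_ndge = numeric()))
  }
  if (is.null(conditions$n_circuit_classes)) conditions$n_circuit_classes <- 5
  records <- list()
  for (ci in seq_len(nrow(conditions))) {
    cond <- conditions[ci, ]
    for (r in seq_len(n_replicates)) {
      rep_seed <- derive_seed(seed, ci * 100003 + r)
      cfg <- base_config
      cfg$seed <- rep_seed
      has_planted <- cond$effect > 0
      cfg$planted <- if (has_planted) {
        list(list(gene = "planted", n_classes_in_circuit =
                    cond$n_circuit_classes,
                  within_circuit_edge_prob = cond$effect))
      } else list()
      gen <- generate_connectome(cfg)
      expr <- generate_expression(cfg, gen$truth)
      ncfg_over <- ndge
      ncfg_over$seed <- derive_seed(rep_seed, 7)
      ncfg_over$fdr_level <- fdr_level
      ncfg <- do.call(ndge_config, ncfg_over)
      pair_res <- test_gene_family(gen$connectome, expr, expr$genes)
      ndge_res <- run_ndge(gen$connectome, gen$contacts, expr, config = ncfg)
      sig_b <- pair_res$gene[pair_res$testable & pair_res$qvalue < fdr_level]
      sig_n <- ndge_res$gene[ndge_res$significant]
      fdp <- function(sig) {
        fp <- sum(sig != "planted")
        if (length(sig)) fp / length(sig) else 0
      }
      planted_row <- which(pair_res$gene == "planted")
      records[[length(records) + 1]] <- data.frame(
        label = cond$label, effect = cond$effect, replicate = r,
        seed = rep_seed,
        planted_sig_binomial = has_planted && "planted" %in% sig_b,
        planted_sig_ndge = has_planted && "planted" %in% sig_n,
        planted_rank1_binomial = has_planted &&
          pair_res$pvalue_tail[planted_row] <
            min(pair_res$pvalue_tail[-planted_row]),
        planted_pvalue_binomial =
          if (has_planted) pair_res$pvalue_tail[planted_row] else NA_real_,
        planted_pvalue_ndge = if (has_planted)
          ndge_res$pvalue[ndge_res$gene == "planted"] else NA_real_,
        fdp_binomial = fdp(sig_b), fdp_ndge = fdp(sig_n),
        stringsAsFactors = FALSE)
    }
  }
  rec <- do.call(rbind, records)
  agg <- do.call(rbind, lapply(split(rec, rec$label), function(d) {
    data.frame(label = d$label[1], effect = d$effect[1],
               n_replicates = nrow(d),
               power_binomial = mean(d$planted_sig_binomial),
               power_ndge = mean(d$planted_sig_ndge),
               rank1_binomial = mean(d$planted_rank1_binomial),
               fdp_binomial = mean(d$fdp_binomial),
               fdp_ndge = mean(d$fdp_ndge),
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  attr(agg, "replicates") <- rec
  agg
}
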