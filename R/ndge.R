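# Network differential gene expression (NDGE).
#
# Compares "homomeric" paired multiplicative gene expression between
# synaptically linked neuron pairs and contact-adjacent but non-synaptic
# pairs, against a null in which the connectome is randomly rewired while
# preserving each neuron's per-type degrees and the membrane-contact mask.
# Expression is never permuted; only the synaptic/non-synaptic partition of
# contact pairs changes across null replicates.

#' NDGE configuration
#'
#' @param n_rewires number of rewired null replicates (default 1000).
#' @param swap_attempts_factor swap attempts per replicate as a multiple of
#'   the edge count (default 100). Contact-mask rejections make acceptance
#'   rates low (often < 10%), so substantially more proposals than edges are
#'   needed before every edge has moved several times; at the default each
#'   edge is typically swapped 10 or more times.
#' @param pseudocount additive constant inside the log-fold change, avoiding
#'   log(0) (default 1e-6).
#' @param logfc_threshold minimum log-fold change for significance (default
#'   6e-3; deliberately small because co-expression in both pair members is a
#'   combinatorially rare event).
#' @param fdr_level FDR level for the significance flag (default 0.05).
#' @param expression_mode `"binary"` (presence/absence atlas calls, default)
#'   or `"continuous"` (values are log1p-scaled before multiplication).
#' @param include_electrical count electrical edges as synaptic links
#'   (default `TRUE`).
#' @param alternative `"greater"` (upper tail: co-expression promotes
#'   synaptic linkage; default) or `"two.sided"` (twice the smaller tail).
#' @param seed integer seed for the rewiring ensemble.
#' @return A list of class `ndge_config`.
#' @export
ndge_config <- function(n_rewires = 1000, swap_attempts_factor = 100,
                        pseudocount = 1e-6, logfc_threshold = 6e-3,
                        fdr_level = 0.05,
                        expression_mode = c("binary", "continuous"),
                        include_electrical = TRUE,
                        alternative = c("greater", "two.sided"),
                        seed = 1L) {
  expression_mode <- match.arg(expression_mode)
  alternative <- match.arg(alternative)
  stopifnot(n_rewires >= 1, pseudocount > 0,
            fdr_level > 0, fdr_level < 1, swap_attempts_factor > 0)
  structure(list(n_rewires = as.integer(n_rewires),
                 swap_attempts_factor = swap_attempts_factor,
                 pseudocount = pseudocount,
                 logfc_threshold = logfc_threshold,
                 fdr_level = fdr_level,
                 expression_mode = expression_mode,
                 include_electrical = include_electrical,
                 alternative = alternative,
                 seed = as.integer(seed)),
            class = "ndge_config")
}

# unordered synaptic pair index matrix (i < j, integer indices into ids)
synaptic_pair_idx <- function(c, ids, include_electrical) {
  idx <- function(x) match(x, ids)
  pairs <- NULL
  if (nrow(c$chemical)) {
    pairs <- cbind(idx(c$chemical$pre), idx(c$chemical$post))
  }
  if (include_electrical && nrow(c$electrical)) {
    pairs <- rbind(pairs, cbind(idx(c$electrical$a), idx(c$electrical$b)))
  }
  if (is.null(pairs) || nrow(pairs) == 0) {
    return(matrix(integer(0), 0, 2))
  }
  pairs <- cbind(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
  pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]  # drop autapses
  unique(pairs)
}

pair_codes <- function(idx, V) (idx[, 1] - 1) * V + idx[, 2]

codes_to_idx <- function(codes, V) {
  i <- (codes - 1) %/% V + 1
  cbind(i, codes - (i - 1) * V)
}

#' Partition contact-adjacent pairs into synaptic and non-synaptic sets
#'
#' Synaptic: unordered pairs joined by at least one chemical edge (either
#' direction) or, if `include_electrical`, an electrical edge. Non-synaptic:
#' contact-adjacent pairs with no such edge. A synaptic pair lacking declared
#' contact stays synaptic, with a warning.
#'
#' @param c a [connectome] (somatic).
#' @param contacts a [contact_map] covering `c`'s neurons.
#' @param include_electrical logical, default `TRUE`.
#' @return List with character matrices `synaptic` and `nonsynaptic`
#'   (columns `i`, `j`, each row an unordered pair).
#' @export
pair_sets <- function(c, contacts, include_electrical = TRUE) {
  ids <- neuron_ids(c)
  missing <- setdiff(ids, contacts$neuron_ids)
  if (length(missing)) stop("contact map missing neuron '", missing[1], "'")
  adj <- contacts$adjacency[ids, ids]
  if (!any(adj)) stop("contact map declares no contacts over these neurons")
  V <- length(ids)
  syn <- synaptic_pair_idx(c, ids, include_electrical)
  no_contact <- if (nrow(syn)) which(!adj[syn]) else integer(0)
  if (length(no_contact)) {
    warning(length(no_contact),
            " synaptic pair(s) lack declared membrane contact; kept as synaptic")
  }
  contact_idx <- which(upper.tri(adj) & adj, arr.ind = TRUE)
  non_codes <- setdiff(pair_codes(contact_idx, V), pair_codes(syn, V))
  non <- codes_to_idx(non_codes, V)
  to_ids <- function(m) {
    out <- cbind(i = ids[m[, 1]], j = ids[m[, 2]])
    out[order(out[, 1], out[, 2]), , drop = FALSE]
  }
  list(synaptic = to_ids(syn), nonsynaptic = to_ids(non))
}

# expression values in the mode used by the statistic, genes x neurons
expression_view <- function(expr, mode) {
  if (mode == "binary") 1 * expr_binary(expr) else log1p(expr$values)
}

#' Mean homomeric (paired multiplicative) expression over a pair set
#'
#' For each pair (i, j), the product of the gene's expression in both
#' members; returns the mean over pairs. In binary mode this is the fraction
#' of pairs whose two neurons both express the gene.
#'
#' @param expr an [expression_matrix].
#' @param gene gene id.
#' @param pairs two-column matrix of neuron ids (one row per pair).
#' @param mode `"binary"` or `"continuous"`.
#' @return A single number (in `[0, 1]` for binary mode).
#' @export
homomeric_mean <- function(expr, gene, pairs, mode = c("binary", "continuous")) {
  mode <- match.arg(mode)
  if (is.null(pairs) || nrow(pairs) == 0) stop("empty pair set")
  x <- expression_view(expr, mode)[gene, ]
  mean(x[pairs[, 1]] * x[pairs[, 2]])
}

#' NDGE log-fold co-expression statistic
#'
#' `log(homomeric_mean(synaptic) + eps) - log(homomeric_mean(nonsynaptic) + eps)`
#' (natural log). Positive values mean the gene is co-expressed in synaptic
#' partners more than in contact-adjacent non-partners.
#'
#' @inheritParams homomeric_mean
#' @param synaptic,nonsynaptic two-column pair matrices (see [pair_sets]).
#' @param pseudocount additive constant, `> 0`.
#' @return A single number.
#' @export
ndge_statistic <- function(expr, gene, synaptic, nonsynaptic,
                           pseudocount = 1e-6,
                           mode = c("binary", "continuous")) {
  mode <- match.arg(mode)
  log(homomeric_mean(expr, gene, synaptic, mode) + pseudocount) -
    log(homomeric_mean(expr, gene, nonsynaptic, mode) + pseudocount)
}

#' Rewire a connectome preserving degrees and membrane contact
#'
#' Contact-constrained double-edge-swap chain. Chemical and electrical edges
#' are rewired as separate pools (types never mix), so each neuron's chemical
#' in-/out-degree and electrical degree are preserved exactly. Proposals
#' creating self-loops, duplicate edges, or edges between non-contact-adjacent
#' neurons are rejected. Autapses are left untouched. Deterministic given
#' `seed`.
#'
#' @param c a [connectome].
#' @param contacts a [contact_map] covering `c`'s neurons.
#' @param attempts total number of swap proposals (each proposal picks a pool
#'   with probability proportional to its edge count).
#' @param seed integer seed.
#' @return A rewired [connectome]; attribute `"accepted_swaps"` holds the
#'   accepted counts per pool.
#' @export
rewire_connectome <- function(c, contacts, attempts, seed) {
  stopifnot(attempts >= 1)
  ids <- neuron_ids(c)
  missing <- setdiff(ids, contacts$neuron_ids)
  if (length(missing)) stop("contact map missing neuron '", missing[1], "'")
  adj <- contacts$adjacency[ids, ids]
  chem <- c$chemical[c$chemical$pre != c$chemical$post, , drop = FALSE]
  chem_auto <- c$chemical[c$chemical$pre == c$chemical$post, , drop = FALSE]
  elec <- c$electrical[c$electrical$a != c$electrical$b, , drop = FALSE]
  elec_auto <- c$electrical[c$electrical$a == c$electrical$b, , drop = FALSE]
  cm <- cbind(match(chem$pre, ids), match(chem$post, ids)) - 1L
  em <- cbind(match(elec$a, ids), match(elec$b, ids)) - 1L
  storage.mode(cm) <- "integer"; storage.mode(em) <- "integer"
  if (nrow(cm) == 0) cm <- matrix(integer(0), 0, 2)
  if (nrow(em) == 0) em <- matrix(integer(0), 0, 2)
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  res <- rewire_edges_cpp(cm, em, adj, as.integer(attempts))
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  chem_new <- data.frame(pre = ids[res$chemical[, 1] + 1],
                         post = ids[res$chemical[, 2] + 1],
                         weight = chem$weight, stringsAsFactors = FALSE)
  elec_new <- data.frame(a = ids[res$electrical[, 1] + 1],
                         b = ids[res$electrical[, 2] + 1],
                         weight = elec$weight, stringsAsFactors = FALSE)
  out <- connectome(c$neurons, rbind(chem_new, chem_auto[, c("pre", "post", "weight")]),
                    rbind(elec_new, elec_auto[, c("a", "b", "weight")]))
  attr(out, "accepted_swaps") <- c(chemical = res$accepted_chemical,
                                   electrical = res$accepted_electrical)
  out
}

#' Build the rewired-connectome null ensemble
#'
#' Generates `config$n_rewires` independently seeded rewired replicates of
#' the connectome and stores each replicate's synaptic pair set.
#'
#' @param c a [connectome] (somatic).
#' @param contacts a [contact_map].
#' @param config an [ndge_config].
#' @return An object of class `rewired_ensemble`: list with `replicates`
#'   (list of integer pair-index matrices), `accepted` (2-column matrix of
#'   accepted swap counts), `ids`, `seed`.
#' @export
build_null_ensemble <- function(c, contacts, config) {
  stopifnot(inherits(config, "ndge_config"))
  ids <- neuron_ids(c)
  n_edges <- sum(c$chemical$pre != c$chemical$post) +
    sum(c$electrical$a != c$electrical$b)
  attempts <- max(1L, ceiling(config$swap_attempts_factor * n_edges))
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(config$seed)
  rep_seeds <- sample.int(2147483646L, config$n_rewires)
  replicates <- vector("list", config$n_rewires)
  accepted <- matrix(0L, config$n_rewires, 2,
                     dimnames = list(NULL, c("chemical", "electrical")))
  # call the swap kernel on integer index matrices directly; rebuilding a
  # validated connectome per replicate would dominate the runtime
  adj <- contacts$adjacency[ids, ids]
  chem <- c$chemical[c$chemical$pre != c$chemical$post, , drop = FALSE]
  elec <- c$electrical[c$electrical$a != c$electrical$b, , drop = FALSE]
  cm <- cbind(match(chem$pre, ids), match(chem$post, ids)) - 1L
  em <- cbind(match(elec$a, ids), match(elec$b, ids)) - 1L
  storage.mode(cm) <- "integer"; storage.mode(em) <- "integer"
  for (r in seq_len(config$n_rewires)) {
    set.seed(rep_seeds[r])
    res <- rewire_edges_cpp(cm, em, adj, as.integer(attempts))
    pairs <- res$chemical + 1L
    if (config$include_electrical) pairs <- rbind(pairs, res$electrical + 1L)
    pairs <- cbind(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
    replicates[[r]] <- unique(pairs)
    accepted[r, ] <- c(res$accepted_chemical, res$accepted_electrical)
  }
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  structure(list(replicates = replicates, accepted = accepted, ids = ids,
                 seed = config$seed),
            class = "rewired_ensemble")
}

#' Empirical upper-tail p-value
#'
#' `(1 + #\{null >= observed\}) / (1 + R)`; never 0, minimum `1/(R+1)`.
#'
#' @param observed observed statistic.
#' @param null_values vector of null statistics.
#' @return A number in `(0, 1]`.
#' @export
empirical_pvalue <- function(observed, null_values) {
  if (length(null_values) == 0) stop("empty null distribution")
  (1 + sum(null_values >= observed)) / (1 + length(null_values))
}

# log-fold statistic for all genes at once given index pair matrices
stat_matrix <- function(X, syn_idx, non_idx, eps) {
  hm <- function(idx) {
    if (nrow(idx) == 0) return(rep(0, nrow(X)))
    rowMeans(X[, idx[, 1], drop = FALSE] * X[, idx[, 2], drop = FALSE])
  }
  log(hm(syn_idx) + eps) - log(hm(non_idx) + eps)
}

# Per-replicate statistics share the fixed contact-pair universe, so the
# gene-by-contact-pair co-expression products are computed once; each
# replicate then only subsets columns for its synaptic pairs. Synaptic pairs
# outside the contact mask (possible in observed data) are handled apart.
make_stat_engine <- function(X, contact_idx, contact_code, V, eps) {
  CO <- X[, contact_idx[, 1], drop = FALSE] * X[, contact_idx[, 2], drop = FALSE]
  TOT <- rowSums(CO)
  M <- length(contact_code)
  function(syn_idx) {
    pos <- match(pair_codes(syn_idx, V), contact_code)
    extra <- syn_idx[is.na(pos), , drop = FALSE]
    pos <- pos[!is.na(pos)]
    S1 <- if (length(pos)) rowSums(CO[, pos, drop = FALSE]) else
      numeric(nrow(X))
    extraS <- if (nrow(extra)) {
      rowSums(X[, extra[, 1], drop = FALSE] * X[, extra[, 2], drop = FALSE])
    } else numeric(nrow(X))
    nS <- length(pos) + nrow(extra)
    nN <- M - length(pos)
    meanS <- if (nS > 0) (S1 + extraS) / nS else numeric(nrow(X))
    meanNS <- if (nN > 0) (TOT - S1) / nN else numeric(nrow(X))
    log(meanS + eps) - log(meanNS + eps)
  }
}

#' Run the NDGE analysis
#'
#' Computes the observed log-fold co-expression statistic for every gene,
#' recomputes it on each rewired replicate's synaptic/non-synaptic partition
#' of the contact pairs, derives empirical p-values, adjusts them by
#' Benjamini-Hochberg, and flags genes with `qvalue < fdr_level` and
#' `logfc > logfc_threshold`. Bitwise reproducible given the inputs and
#' `config$seed`.
#'
#' @param c a [connectome] (somatic).
#' @param contacts a [contact_map] covering `c`'s neurons.
#' @param expr an [expression_matrix] covering `c`'s neurons.
#' @param genes genes to test (default: all genes in `expr`).
#' @param config an [ndge_config].
#' @param ensemble optional precomputed [build_null_ensemble] result (reused
#'   across gene sets).
#' @return data.frame with columns `gene`, `logfc`, `pvalue`, `qvalue`,
#'   `n_synaptic_pairs`, `n_nonsynaptic_pairs`, `significant`; attribute
#'   `"volcano"` holds the volcano table (`gene`, `logfc`, `neg_log10_p`,
#'   `significant`).
#' @export
run_ndge <- function(c, contacts, expr, genes = NULL, config = ndge_config(),
                     ensemble = NULL) {
  stopifnot(inherits(config, "ndge_config"))
  if (is.null(genes)) genes <- expr$genes
  empty <- data.frame(gene = character(), logfc = numeric(),
                      pvalue = numeric(), qvalue = numeric(),
                      n_synaptic_pairs = integer(),
                      n_nonsynaptic_pairs = integer(),
                      significant = logical(), stringsAsFactors = FALSE)
  if (length(genes) == 0) {
    attr(empty, "volcano") <- data.frame(gene = character(), logfc = numeric(),
                                         neg_log10_p = numeric(),
                                         significant = logical())
    return(empty)
  }
  missing <- setdiff(genes, expr$genes)
  if (length(missing)) stop("gene '", missing[1], "' absent from expression matrix")
  ids <- neuron_ids(c)
  if (!all(ids %in% expr$neurons)) {
    stop("expression matrix missing neuron(s): ",
         paste(utils::head(setdiff(ids, expr$neurons), 3), collapse = ", "))
  }
  missing_c <- setdiff(ids, contacts$neuron_ids)
  if (length(missing_c)) stop("contact map missing neuron '", missing_c[1], "'")
  adj <- contacts$adjacency[ids, ids]
  if (!any(adj)) stop("contact map declares no contacts over these neurons")
  V <- length(ids)
  contact_idx <- which(upper.tri(adj) & adj, arr.ind = TRUE)
  contact_code <- pair_codes(contact_idx, V)

  syn_idx <- synaptic_pair_idx(c, ids, config$include_electrical)
  non_codes <- setdiff(contact_code, pair_codes(syn_idx, V))
  if (length(non_codes) == 0) {
    stop("every contact-adjacent pair is synaptic: the non-synaptic ",
         "comparison group is empty")
  }
  non_idx <- codes_to_idx(non_codes, V)

  X <- expression_view(expr, config$expression_mode)[genes, ids, drop = FALSE]
  eps <- config$pseudocount
  engine <- make_stat_engine(X, contact_idx, contact_code, V, eps)
  observed <- engine(syn_idx)

  if (is.null(ensemble)) ensemble <- build_null_ensemble(c, contacts, config)
  R <- length(ensemble$replicates)
  null_mat <- matrix(0, length(genes), R)
  for (r in seq_len(R)) {
    null_mat[, r] <- engine(ensemble$replicates[[r]])
  }
  p_up <- (1 + rowSums(null_mat >= observed)) / (1 + R)
  if (config$alternative == "two.sided") {
    p_lo <- (1 + rowSums(null_mat <= observed)) / (1 + R)
    pvalue <- pmin(1, 2 * pmin(p_up, p_lo))
  } else {
    pvalue <- p_up
  }
  qvalue <- bh_fdr(pvalue)
  res <- data.frame(gene = genes, logfc = observed, pvalue = pvalue,
                    qvalue = qvalue,
                    n_synaptic_pairs = nrow(syn_idx),
                    n_nonsynaptic_pairs = nrow(non_idx),
                    significant = qvalue < config$fdr_level &
                      observed > config$logfc_threshold,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "volcano") <- volcano_table(res)
  attr(res, "config") <- config
  res
}

#' Volcano table from an NDGE result
#'
#' @param res a [run_ndge] result.
#' @return data.frame with `gene`, `logfc`, `neg_log10_p`, `significant`.
#' @export
volcano_table <- function(res) {
  data.frame(gene = res$gene, logfc = res$logfc,
             neg_log10_p = -log10(res$pvalue),
             significant = res$significant, stringsAsFactors = FALSE)
}
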