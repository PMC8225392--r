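# Binomial pair-connectivity enrichment test.
#
# The unit of observation is an ordered neuron pair (i, j), i != j. By default
# pairs whose members belong to the same neuron class (bilateral/radial
# homologs) are excluded from every universe. A pair is a "success" when a
# chemical synapse runs i -> j or an electrical synapse joins {i, j};
# electrical edges therefore register for both orderings while chemical edges
# count in their direction only (the double-counting convention).

EXCLUSION_RULES <- c("exclude_same_class", "none")

# directed "connected" adjacency over the connectome's neurons, diag FALSE
connected_adjacency <- function(c) {
  ids <- neuron_ids(c)
  n <- length(ids)
  chem <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  if (nrow(c$chemical)) chem[cbind(c$chemical$pre, c$chemical$post)] <- TRUE
  elec <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  if (nrow(c$electrical)) {
    elec[cbind(c$electrical$a, c$electrical$b)] <- TRUE
    elec[cbind(c$electrical$b, c$electrical$a)] <- TRUE
  }
  conn <- chem | elec
  diag(conn) <- FALSE    # autapses never contribute to pair statistics
  conn
}

# logical mask of ordered pairs in the universe over the given ids
universe_mask <- function(ids, classes, exclusion_rule) {
  n <- length(ids)
  mask <- matrix(TRUE, n, n)
  diag(mask) <- FALSE
  if (exclusion_rule == "exclude_same_class") {
    mask <- mask & outer(classes, classes, "!=")
  }
  mask
}

#' Build the ordered-pair universe for the enrichment test
#'
#' All ordered pairs (i, j) with i != j over the given neurons; under
#' `exclude_same_class`, pairs whose neurons share a class are removed.
#'
#' @param ids character vector of neuron ids.
#' @param classes named character vector mapping every id to its class.
#' @param exclusion_rule `"exclude_same_class"` (default) or `"none"`.
#' @return An object of class `pair_universe` with elements `pairs`
#'   (data.frame `i`, `j`), `exclusion_rule`, `n`.
#' @export
build_pair_universe <- function(ids, classes,
                                exclusion_rule = c("exclude_same_class", "none")) {
  exclusion_rule <- match.arg(exclusion_rule)
  ids <- as.character(ids)
  if (!all(ids %in% names(classes))) {
    stop("neuron without a class: ", setdiff(ids, names(classes))[1])
  }
  cl <- as.character(classes[ids])
  mask <- universe_mask(ids, cl, exclusion_rule)
  idx <- which(mask, arr.ind = TRUE)
  pairs <- data.frame(i = ids[idx[, 1]], j = ids[idx[, 2]],
                      stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$i, pairs$j), ]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, exclusion_rule = exclusion_rule,
                 n = nrow(pairs)),
            class = "pair_universe")
}

#' Is an ordered neuron pair synaptically connected?
#'
#' `TRUE` iff a chemical edge runs `i -> j` or an electrical edge joins
#' `{i, j}`. Vectorized over `i`, `j`.
#'
#' @param c a [connectome].
#' @param i,j neuron ids, `i != j` elementwise.
#' @return Logical vector.
#' @export
is_connected <- function(c, i, j) {
  ids <- neuron_ids(c)
  unknown <- setdiff(c(i, j), ids)
  if (length(unknown)) stop("unknown neuron id '", unknown[1], "'")
  if (any(i == j)) stop("is_connected is undefined for self-pairs")
  conn <- connected_adjacency(c)
  conn[cbind(i, j)]
}

#' Global connection probability ("probability of success", p)
#'
#' The fraction of ordered pairs in the universe that are connected by a
#' chemical and/or electrical synapse. Computed as an exact ratio
#' `k_total / n_total`.
#'
#' @param c a [connectome] (already restricted to somatic neurons).
#' @param universe a [build_pair_universe] result over `c`'s neurons.
#' @return A number in `[0, 1]`.
#' @export
connection_probability <- function(c, universe) {
  if (universe$n == 0) stop("empty pair universe")
  conn <- connected_adjacency(c)
  k <- sum(conn[cbind(universe$pairs$i, universe$pairs$j)])
  k / universe$n
}

#' Binomial probability mass Pr(X = k)
#'
#' Exact binomial mass for `k` successes in `n` trials with success
#' probability `p`, numerically stable for large `n`.
#'
#' @param k,n nonnegative integers, `k <= n` (vectorized over `k`).
#' @param p success probability in `[0, 1]`.
#' @return `Pr(X = k)`.
#' @export
binomial_pmf <- function(k, n, p) {
  stopifnot(n >= 0, p >= 0, p <= 1, k >= 0)
  if (any(k > n)) stop("k > n in binomial_pmf")
  dbinom(k, n, p)
}

#' Binomial upper tail Pr(X >= k)
#'
#' @inheritParams binomial_pmf
#' @return `Pr(X >= k)`; 1 when `k = 0`.
#' @export
binomial_upper_tail <- function(k, n, p) {
  stopifnot(n >= 0, p >= 0, p <= 1, k >= 0)
  if (any(k > n)) stop("k > n in binomial_upper_tail")
  pbinom(k - 1, n, p, lower.tail = FALSE)
}

#' Binomial pair-connectivity enrichment test for one gene
#'
#' Builds the ordered-pair universe over the neurons expressing `gene`
#' (n trials), counts connected pairs among them (k successes), and evaluates
#' both the point mass `Pr(X = k)` and the enrichment tail `Pr(X >= k)` under
#' the global connection probability `p`. Genes expressed in fewer than two
#' neurons (or only within one class under the default exclusion rule) have
#' an empty universe and are flagged untestable.
#'
#' @param c a [connectome], restricted to somatic neurons.
#' @param expr an [expression_matrix] covering `c`'s neurons.
#' @param gene gene id present in `expr`.
#' @param exclusion_rule see [build_pair_universe].
#' @param p_success optional precomputed global connection probability;
#'   computed from `c` under the same `exclusion_rule` when `NULL`.
#' @return One-row data.frame: `gene`, `n_trials`, `k_successes`, `p_success`,
#'   `pvalue_pmf`, `pvalue_tail`, `qvalue` (`NA`, filled by
#'   [test_gene_family]), `testable`.
#' @export
tf_connectivity_test <- function(c, expr, gene,
                                 exclusion_rule = c("exclude_same_class", "none"),
                                 p_success = NULL) {
  exclusion_rule <- match.arg(exclusion_rule)
  if (!(gene %in% expr$genes)) stop("gene '", gene, "' absent from expression matrix")
  ids <- neuron_ids(c)
  if (!all(ids %in% expr$neurons)) {
    stop("expression matrix missing neuron(s): ",
         paste(utils::head(setdiff(ids, expr$neurons), 3), collapse = ", "))
  }
  cls <- class_map(c)
  conn <- connected_adjacency(c)
  if (is.null(p_success)) {
    gmask <- universe_mask(ids, cls[ids], exclusion_rule)
    p_success <- sum(conn & gmask) / sum(gmask)
  }
  on <- ids[expr_binary(expr)[gene, ids]]
  if (length(on) >= 2) {
    mask <- universe_mask(on, cls[on], exclusion_rule)
    n <- sum(mask)
    k <- sum(conn[on, on, drop = FALSE] & mask)
  } else {
    n <- 0L; k <- 0L
  }
  testable <- n > 0
  data.frame(gene = gene, n_trials = as.integer(n), k_successes = as.integer(k),
             p_success = p_success,
             pvalue_pmf = if (testable) binomial_pmf(k, n, p_success) else 1,
             pvalue_tail = if (testable) binomial_upper_tail(k, n, p_success) else 1,
             qvalue = NA_real_, testable = testable,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, returned in the input order.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return Adjusted q-values, each `>= ` its p-value.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Family-wide binomial enrichment screen
#'
#' Runs [tf_connectivity_test] for every gene in `genes` with one shared
#' global `p_success`, then adjusts the chosen p-value across testable genes
#' by Benjamini-Hochberg. Untestable genes receive `qvalue = 1`.
#'
#' @inheritParams tf_connectivity_test
#' @param genes character vector of genes to screen (must all be in `expr`).
#' @param pvalue_kind which p-value feeds the FDR adjustment: `"tail"`
#'   (`Pr(X >= k)`, default) or `"pmf"` (`Pr(X = k)`, the as-published form).
#' @return data.frame with one row per gene (see [tf_connectivity_test]).
#' @export
test_gene_family <- function(c, expr, genes,
                             exclusion_rule = c("exclude_same_class", "none"),
                             pvalue_kind = c("tail", "pmf")) {
  exclusion_rule <- match.arg(exclusion_rule)
  pvalue_kind <- match.arg(pvalue_kind)
  if (length(genes) == 0) stop("empty gene list")
  missing <- setdiff(genes, expr$genes)
  if (length(missing)) stop("gene '", missing[1], "' absent from expression matrix")
  ids <- neuron_ids(c)
  cls <- class_map(c)
  conn <- connected_adjacency(c)
  gmask <- universe_mask(ids, cls[ids], exclusion_rule)
  if (sum(gmask) == 0) stop("empty global pair universe")
  p_success <- sum(conn & gmask) / sum(gmask)
  res <- do.call(rbind, lapply(genes, function(g) {
    tf_connectivity_test(c, expr, g, exclusion_rule, p_success = p_success)
  }))
  pcol <- if (pvalue_kind == "tail") "pvalue_tail" else "pvalue_pmf"
  res$qvalue <- 1
  if (any(res$testable)) {
    res$qvalue[res$testable] <- bh_fdr(res[[pcol]][res$testable])
  }
  attr(res, "pvalue_kind") <- pvalue_kind
  attr(res, "p_success") <- p_success
  res
}
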