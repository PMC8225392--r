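# Hypergeometric binding-site enrichment over per-gene motif-presence calls.
#
# The genome universe is the set of annotated coding genes; a gene "carries"
# a motif when it has at least one predicted binding site. The foreground is
# a neuron-class reporter gene set. Motif scanning itself is upstream; only
# boolean presence calls are consumed here.

#' Construct a motif-presence table
#'
#' @param presence logical (or 0/1) matrix, genes in rows (rownames = gene
#'   ids, the genome universe), motifs in columns (colnames).
#' @return An object of class `motif_presence_table`.
#' @export
motif_presence_table <- function(presence) {
  stopifnot(is.matrix(presence), !is.null(rownames(presence)),
            !is.null(colnames(presence)))
  if (anyDuplicated(rownames(presence))) stop("duplicate gene id")
  if (nrow(presence) < 1) stop("empty gene universe")
  mode(presence) <- "logical"
  structure(list(gene_ids = rownames(presence),
                 motif_ids = colnames(presence),
                 presence = presence),
            class = "motif_presence_table")
}

#' @export
print.motif_presence_table <- function(x, ...) {
  cat(sprintf("motif_presence_table: %d genes x %d motifs\n",
              length(x$gene_ids), length(x$motif_ids)))
  invisible(x)
}

#' Read a gene-by-motif presence table
#'
#' Wide TSV: first column `gene`, one 0/1 column per motif. The rows define
#' the genome universe.
#'
#' @param path input path.
#' @return A [motif_presence_table].
#' @export
read_motif_table <- function(path) {
  df <- read_table_auto(path)
  m <- as.matrix(df[, -1, drop = FALSE]) > 0
  rownames(m) <- as.character(df[[1]])
  motif_presence_table(m)
}

#' Read per-neuron-class reporter gene lists
#'
#' Two-column TSV (`class`, `gene`).
#'
#' @param path input path.
#' @return Named list of character vectors, one per class.
#' @export
read_reporter_sets <- function(path) {
  df <- read_table_auto(path)
  stopifnot(all(c("class", "gene") %in% names(df)))
  split(as.character(df$gene), df$class)
}

#' Hypergeometric upper tail P(X >= x)
#'
#' Drawing `n` genes without replacement from a universe of `N` genes of
#' which `K` carry the motif; probability of observing at least `x` carriers.
#'
#' @param x observed carrier count, `0 <= x <= min(n, K)`.
#' @param N universe size; `K` carriers in the universe; `n` draws.
#' @param K,n see above.
#' @return `P(X >= x)`, in `(0, 1]` for consistent counts.
#' @export
hypergeom_upper_tail <- function(x, N, K, n) {
  if (any(c(x, N, K, n) < 0) || K > N || n > N || any(x > pmin(n, K))) {
    stop("inconsistent hypergeometric counts (need 0 <= x <= min(n, K), K <= N, n <= N)")
  }
  phyper(x - 1, K, N - K, n, lower.tail = FALSE)
}

#' Binding-site enrichment in a reporter gene set
#'
#' Tests whether reporter genes of a neuron class carry a motif more often
#' than expected from its genome-wide frequency, by the hypergeometric upper
#' tail.
#'
#' @param table a [motif_presence_table].
#' @param motif motif id.
#' @param reporter_genes character vector of foreground genes (subset of the
#'   genome universe, nonempty).
#' @param label neuron-class label for the output row.
#' @return One-row data.frame: `label`, `motifs`, `N`, `K_expected`,
#'   `n_reporters`, `x_observed`, `pvalue`.
#' @export
site_enrichment <- function(table, motif, reporter_genes, label = "") {
  stopifnot(inherits(table, "motif_presence_table"))
  if (!(motif %in% table$motif_ids)) stop("unknown motif '", motif, "'")
  if (length(reporter_genes) == 0) stop("empty reporter gene set")
  outside <- setdiff(reporter_genes, table$gene_ids)
  if (length(outside)) {
    stop("reporter gene '", outside[1], "' is outside the genome universe")
  }
  has <- table$presence[, motif]
  N <- length(table$gene_ids)
  K <- sum(has)
  n <- length(unique(reporter_genes))
  x <- sum(has[unique(reporter_genes)])
  data.frame(label = label, motifs = motif, N = N, K_expected = as.integer(K),
             n_reporters = n, x_observed = as.integer(x),
             pvalue = hypergeom_upper_tail(x, N, K, n),
             stringsAsFactors = FALSE)
}

#' Cofactor binding-site co-enrichment
#'
#' Tests whether reporter genes carry at least one site for EACH of two
#' motifs more often than expected. Under `expectation = "product"` the
#' expected carrier count is `N * (K_a/N) * (K_b/N)` (the product of the two
#' genome-wide proportions, rounded to the nearest integer) and feeds a
#' hypergeometric tail; under `expectation = "joint"` the expected count is
#' the observed number of genome genes carrying both motifs. A binomial-tail
#' variant (`test = "binomial"`, success probability = the product of
#' proportions) is exposed for sensitivity checks, since a rounded product
#' expectation is an approximation.
#'
#' @inheritParams site_enrichment
#' @param motif_a,motif_b motif ids.
#' @param expectation `"product"` (default) or `"joint"`.
#' @param test `"hypergeometric"` (default) or `"binomial"`.
#' @return One-row data.frame as in [site_enrichment] (`motifs` is
#'   `"a+b"`).
#' @export
cofactor_coenrichment <- function(table, motif_a, motif_b, reporter_genes,
                                  label = "",
                                  expectation = c("product", "joint"),
                                  test = c("hypergeometric", "binomial")) {
  expectation <- match.arg(expectation)
  test <- match.arg(test)
  stopifnot(inherits(table, "motif_presence_table"))
  for (m in c(motif_a, motif_b)) {
    if (!(m %in% table$motif_ids)) stop("unknown motif '", m, "'")
  }
  if (length(reporter_genes) == 0) stop("empty reporter gene set")
  outside <- setdiff(reporter_genes, table$gene_ids)
  if (length(outside)) {
    stop("reporter gene '", outside[1], "' is outside the genome universe")
  }
  reporter_genes <- unique(reporter_genes)
  both <- table$presence[, motif_a] & table$presence[, motif_b]
  N <- length(table$gene_ids)
  n <- length(reporter_genes)
  x <- sum(both[reporter_genes])
  Ka <- sum(table$presence[, motif_a])
  Kb <- sum(table$presence[, motif_b])
  p_both <- (Ka / N) * (Kb / N)
  K_exp <- if (expectation == "product") as.integer(round(N * p_both)) else
    as.integer(sum(both))
  if (test == "binomial") {
    pv <- binomial_upper_tail(x, n, p_both)
  } else if (K_exp == 0 && x > 0) {
    warning("expected carrier count is 0 with x > 0; reporting the 1/choose(N, n) lower bound")
    pv <- 1 / choose(N, n)
  } else if (x > K_exp) {
    warning("observed count exceeds the rounded expected carrier count; ",
            "p-value is the tail at x = K_expected (a lower bound)")
    pv <- hypergeom_upper_tail(K_exp, N, K_exp, n)
  } else {
    pv <- hypergeom_upper_tail(x, N, K_exp, n)
  }
  data.frame(label = label, motifs = paste(motif_a, motif_b, sep = "+"),
             N = N, K_expected = K_exp, n_reporters = n,
             x_observed = as.integer(x), pvalue = pv,
             stringsAsFactors = FALSE)
}

#' Motif enrichment screen across neuron classes
#'
#' Convenience wrapper applying [site_enrichment] (one motif) or
#' [cofactor_coenrichment] (two motifs) to each reporter set.
#'
#' @param table a [motif_presence_table].
#' @param motifs character vector of one or two motif ids.
#' @param reporter_sets named list of reporter gene vectors (one per class).
#' @param ... forwarded to [cofactor_coenrichment].
#' @return data.frame, one row per class.
#' @export
motif_screen <- function(table, motifs, reporter_sets, ...) {
  stopifnot(length(motifs) %in% 1:2, length(reporter_sets) > 0)
  do.call(rbind, lapply(names(reporter_sets), function(cl) {
    if (length(motifs) == 1) {
      site_enrichment(table, motifs, reporter_sets[[cl]], label = cl)
    } else {
      cofactor_coenrichment(table, motifs[1], motifs[2],
                            reporter_sets[[cl]], label = cl, ...)
    }
  }))
}
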