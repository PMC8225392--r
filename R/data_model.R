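# Domain containers: connectome, contact map, expression matrix.
# Conventions: TSV with a header, UTF-8, '#' starts a comment line.

VALID_CATEGORIES <- c("sensory", "inter", "motor", "other")

#' Construct a validated connectome
#'
#' A connectome holds neuron metadata plus a directed weighted chemical-synapse
#' edge list and an undirected weighted electrical-synapse (gap junction) edge
#' list. Weights are EM weights (serial-section counts); duplicate parallel
#' edges are summed because section counts are additive. Electrical edges are
#' stored canonically with `a <= b` (lexicographic). Autapses (self edges) are
#' kept in storage but excluded from every pair statistic.
#'
#' @param neurons data.frame with columns `id`, `class`, and optionally
#'   `category` (one of sensory/inter/motor/other, default "other") and
#'   `pharyngeal` (logical, default `FALSE`).
#' @param chemical data.frame with columns `pre`, `post`, `weight`
#'   (positive integers). May be `NULL`/empty.
#' @param electrical data.frame with columns `a`, `b`, `weight`. May be
#'   `NULL`/empty.
#' @return An object of class `connectome`.
#' @export
connectome <- function(neurons, chemical = NULL, electrical = NULL) {
  stopifnot(is.data.frame(neurons))
  if (!all(c("id", "class") %in% names(neurons))) {
    stop("neuron table must have columns 'id' and 'class'")
  }
  neurons$id <- as.character(neurons$id)
  neurons$class <- as.character(neurons$class)
  if (anyDuplicated(neurons$id)) {
    stop("duplicate neuron id: ", neurons$id[duplicated(neurons$id)][1])
  }
  if (any(!nzchar(neurons$class))) stop("empty neuron class label")
  if (is.null(neurons$category)) neurons$category <- "other"
  neurons$category <- as.character(neurons$category)
  bad <- setdiff(unique(neurons$category), VALID_CATEGORIES)
  if (length(bad)) stop("unknown neuron category: ", bad[1])
  if (is.null(neurons$pharyngeal)) neurons$pharyngeal <- FALSE
  neurons$pharyngeal <- parse_logical(neurons$pharyngeal, "pharyngeal")
  neurons <- neurons[, c("id", "class", "category", "pharyngeal")]
  rownames(neurons) <- NULL

  chemical <- canonical_edges(chemical, c("pre", "post"), neurons$id,
                              directed = TRUE, kind = "chemical")
  electrical <- canonical_edges(electrical, c("a", "b"), neurons$id,
                                directed = FALSE, kind = "electrical")

  structure(list(neurons = neurons, chemical = chemical,
                 electrical = electrical),
            class = "connectome")
}

parse_logical <- function(x, what) {
  if (is.logical(x)) return(x)
  s <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(s))
  out[s %in% c("true", "t", "1", "yes")] <- TRUE
  out[s %in% c("false", "f", "0", "no")] <- FALSE
  if (anyNA(out)) stop("cannot parse ", what, " value: ", s[is.na(out)][1])
  out
}

canonical_edges <- function(edges, cols, ids, directed, kind) {
  empty <- setNames(data.frame(character(), character(), integer(),
                               stringsAsFactors = FALSE),
                    c(cols, "weight"))
  if (is.null(edges) || nrow(edges) == 0) return(empty)
  stopifnot(is.data.frame(edges))
  if (!all(c(cols, "weight") %in% names(edges))) {
    stop(kind, " edge table must have columns ",
         paste(c(cols, "weight"), collapse = ", "))
  }
  e <- data.frame(from = as.character(edges[[cols[1]]]),
                  to = as.character(edges[[cols[2]]]),
                  weight = edges$weight, stringsAsFactors = FALSE)
  w <- suppressWarnings(as.numeric(e$weight))
  bad <- which(is.na(w) | w <= 0 | w != floor(w))
  if (length(bad)) {
    stop(sprintf("%s edge row %d (%s, %s): weight '%s' is not a positive integer",
                 kind, bad[1], e$from[bad[1]], e$to[bad[1]],
                 as.character(edges$weight[bad[1]])))
  }
  e$weight <- as.integer(w)
  unknown <- which(!(e$from %in% ids) | !(e$to %in% ids))
  if (length(unknown)) {
    i <- unknown[1]
    offender <- if (e$from[i] %in% ids) e$to[i] else e$from[i]
    stop(sprintf("%s edge row %d references unknown neuron '%s'",
                 kind, i, offender))
  }
  if (!directed) {
    flip <- e$from > e$to
    tmp <- e$from[flip]; e$from[flip] <- e$to[flip]; e$to[flip] <- tmp
  }
  # parallel edge rows are summed (EM series splits); weight is additive
  e <- aggregate(weight ~ from + to, data = e, FUN = sum)
  e <- e[order(e$from, e$to), ]
  names(e) <- c(cols, "weight")
  rownames(e) <- NULL
  e
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("connectome: %d neurons (%d classes), %d chemical, %d electrical edges\n",
              nrow(x$neurons), length(unique(x$neurons$class)),
              nrow(x$chemical), nrow(x$electrical)))
  invisible(x)
}

neuron_ids <- function(c) c$neurons$id
class_map <- function(c) setNames(c$neurons$class, c$neurons$id)

read_table_auto <- function(path) {
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE)) read.csv else read.delim
  reader(path, header = TRUE, comment.char = "#",
         stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a connectome from neuron and edge tables
#'
#' Reads the tabular format used by wormwiring-style connectome exports:
#' a neuron table (`neuron`, `class`, `category`, `pharyngeal`), a directed
#' chemical edge list (`pre`, `post`, `weight`) and an undirected electrical
#' edge list (`a`, `b`, `weight`). TSV or CSV by file extension; column order
#' immaterial; parallel edge rows are summed.
#'
#' @param neuron_table_path,chemical_edges_path,electrical_edges_path paths.
#' @return A [connectome].
#' @export
read_connectome <- function(neuron_table_path, chemical_edges_path,
                            electrical_edges_path) {
  nt <- read_table_auto(neuron_table_path)
  id_col <- intersect(c("neuron", "id"), names(nt))[1]
  if (is.na(id_col)) stop("neuron table needs a 'neuron' (or 'id') column")
  neurons <- data.frame(id = nt[[id_col]], class = nt$class,
                        stringsAsFactors = FALSE)
  if (!is.null(nt$category)) neurons$category <- nt$category
  if (!is.null(nt$pharyngeal)) neurons$pharyngeal <- nt$pharyngeal
  connectome(neurons,
             chemical = read_table_auto(chemical_edges_path),
             electrical = read_table_auto(electrical_edges_path))
}

#' Write a connectome to three TSV files
#'
#' Inverse of [read_connectome].
#'
#' @param c a [connectome].
#' @param neuron_table_path,chemical_edges_path,electrical_edges_path output paths.
#' @export
write_connectome <- function(c, neuron_table_path, chemical_edges_path,
                             electrical_edges_path) {
  nt <- c$neurons
  names(nt)[names(nt) == "id"] <- "neuron"
  write_tsv(nt, neuron_table_path)
  write_tsv(c$chemical, chemical_edges_path)
  write_tsv(c$electrical, electrical_edges_path)
  invisible(c(neuron_table_path, chemical_edges_path, electrical_edges_path))
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Restrict a connectome to somatic (non-pharyngeal) neurons
#'
#' Drops pharyngeal neurons and every edge incident to them (the induced
#' subgraph on somatic neurons). Idempotent.
#'
#' @param c a [connectome].
#' @return A [connectome] containing only neurons with `pharyngeal = FALSE`.
#' @export
restrict_to_somatic <- function(c) {
  keep <- c$neurons$id[!c$neurons$pharyngeal]
  chem <- c$chemical[c$chemical$pre %in% keep & c$chemical$post %in% keep, ]
  elec <- c$electrical[c$electrical$a %in% keep & c$electrical$b %in% keep, ]
  connectome(c$neurons[!c$neurons$pharyngeal, , drop = FALSE], chem, elec)
}

#' Construct a membrane-contact map
#'
#' Symmetric boolean neuron-by-neuron membrane adjacency; the diagonal is
#' forced `FALSE`. Numeric input (contact areas) is binarized at `> 0`.
#'
#' @param ids character vector of neuron ids.
#' @param adjacency square matrix (logical or nonnegative numeric) in `ids`
#'   order, or `NULL` for an all-`FALSE` map.
#' @return An object of class `contact_map`.
#' @export
contact_map <- function(ids, adjacency = NULL) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("duplicate neuron id in contact map")
  n <- length(ids)
  if (is.null(adjacency)) {
    adjacency <- matrix(FALSE, n, n)
  }
  if (!is.matrix(adjacency) || nrow(adjacency) != n || ncol(adjacency) != n) {
    stop("adjacency must be a square matrix over the declared neuron ids")
  }
  adjacency <- adjacency > 0
  if (!isTRUE(all(adjacency == t(adjacency)))) {
    stop("contact map adjacency is not symmetric")
  }
  diag(adjacency) <- FALSE
  dimnames(adjacency) <- list(ids, ids)
  structure(list(neuron_ids = ids, adjacency = adjacency),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("contact_map: %d neurons, %d contact pairs\n",
              length(x$neuron_ids), sum(x$adjacency) / 2))
  invisible(x)
}

#' Read a membrane-contact map
#'
#' Accepts either a labelled square matrix (first column = row labels) or a
#' two-column contact edge list with columns `a`, `b` (an optional
#' `weight`/`area` column is binarized at `> 0`). Both dialects produce
#' identical objects for equivalent content. An empty file yields an
#' all-`FALSE` map over `neuron_ids`.
#'
#' @param path input path.
#' @param neuron_ids the declared neuron universe (must be a superset of any
#'   connectome the map is paired with).
#' @return A [contact_map].
#' @export
read_contact_map <- function(path, neuron_ids) {
  neuron_ids <- as.character(neuron_ids)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) <= 1) {               # empty or header-only
    return(contact_map(neuron_ids))
  }
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (all(c("a", "b") %in% header)) {
    df <- read.delim(text = paste(lines, collapse = "\n"),
                     stringsAsFactors = FALSE, check.names = FALSE)
    unknown <- setdiff(c(df$a, df$b), neuron_ids)
    if (length(unknown)) {
      stop("contact declared for unknown neuron '", unknown[1], "'")
    }
    keep <- rep(TRUE, nrow(df))
    wcol <- intersect(c("weight", "area"), names(df))
    if (length(wcol)) keep <- df[[wcol[1]]] > 0
    m <- matrix(FALSE, length(neuron_ids), length(neuron_ids),
                dimnames = list(neuron_ids, neuron_ids))
    a <- df$a[keep]; b <- df$b[keep]
    m[cbind(a, b)] <- TRUE
    m[cbind(b, a)] <- TRUE
    contact_map(neuron_ids, m)
  } else {
    m <- as.matrix(read.delim(text = paste(lines, collapse = "\n"),
                              row.names = 1, check.names = FALSE))
    if (!isTRUE(all(abs(m - t(m)) < 1e-12))) {
      stop("contact map matrix input is asymmetric")
    }
    unknown <- setdiff(rownames(m), neuron_ids)
    if (length(unknown)) {
      stop("contact declared for unknown neuron '", unknown[1], "'")
    }
    full <- matrix(FALSE, length(neuron_ids), length(neuron_ids),
                   dimnames = list(neuron_ids, neuron_ids))
    full[rownames(m), colnames(m)] <- m > 0
    contact_map(neuron_ids, full)
  }
}

#' Write a contact map
#'
#' @param map a [contact_map].
#' @param path output path.
#' @param dialect `"matrix"` for a labelled 0/1 matrix or `"edges"` for an
#'   `a`/`b` contact pair list.
#' @export
write_contact_map <- function(map, path, dialect = c("matrix", "edges")) {
  dialect <- match.arg(dialect)
  if (dialect == "matrix") {
    df <- data.frame(neuron = map$neuron_ids,
                     1L * map$adjacency, check.names = FALSE)
    names(df) <- c("neuron", map$neuron_ids)
    write_tsv(df, path)
  } else {
    idx <- which(upper.tri(map$adjacency) & map$adjacency, arr.ind = TRUE)
    write_tsv(data.frame(a = map$neuron_ids[idx[, 1]],
                         b = map$neuron_ids[idx[, 2]]), path)
  }
  invisible(path)
}

#' Construct an expression matrix
#'
#' Gene-by-neuron nonnegative values with a binary "expressed" view
#' (`value > binary_threshold`). The homeobox atlas use case is binary 0/1;
#' continuous values (e.g. scRNA-seq) are supported by the same container.
#'
#' @param values numeric matrix, genes in rows (rownames), neurons in columns
#'   (colnames); all values `>= 0`.
#' @param binary_threshold threshold defining "expressed"; default 0.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, binary_threshold = 0) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  if (anyDuplicated(rownames(values))) stop("duplicate gene label")
  if (anyDuplicated(colnames(values))) stop("duplicate neuron label")
  if (any(values < 0)) stop("expression values must be nonnegative")
  structure(list(genes = rownames(values), neurons = colnames(values),
                 values = values, binary_threshold = binary_threshold),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d neurons (threshold %g)\n",
              length(x$genes), length(x$neurons), x$binary_threshold))
  invisible(x)
}

#' Binary expressed/not-expressed view of an expression matrix
#'
#' @param expr an [expression_matrix].
#' @return Logical gene-by-neuron matrix (`value > binary_threshold`).
#' @export
expr_binary <- function(expr) {
  expr$values > expr$binary_threshold
}

#' Read a gene-by-neuron expression table
#'
#' Wide format (first column `gene`, remaining columns one per neuron) or
#' long format (columns `gene`, `neuron`, `value`; missing cells are 0).
#'
#' @param path input path.
#' @param binary_threshold forwarded to [expression_matrix].
#' @return An [expression_matrix].
#' @export
read_expression <- function(path, binary_threshold = 0) {
  df <- read_table_auto(path)
  if (all(c("gene", "neuron", "value") %in% names(df)) && ncol(df) == 3) {
    df$value <- as.numeric(df$value)
    if (any(df$value < 0)) {
      stop("negative expression value for gene '",
           df$gene[which(df$value < 0)[1]], "'")
    }
    key <- paste(df$gene, df$neuron, sep = "\r")
    if (anyDuplicated(key)) {
      d <- df[duplicated(key), ][1, ]
      stop(sprintf("duplicate (gene, neuron) entry: (%s, %s)", d$gene, d$neuron))
    }
    genes <- unique(df$gene); cells <- unique(df$neuron)
    m <- matrix(0, length(genes), length(cells),
                dimnames = list(genes, cells))
    m[cbind(df$gene, df$neuron)] <- df$value
  } else {
    genes <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    if (any(m < 0)) stop("negative expression value in row '",
                         genes[which(rowSums(m < 0) > 0)[1]], "'")
    rownames(m) <- genes
  }
  expression_matrix(m, binary_threshold = binary_threshold)
}

#' Write an expression matrix as a wide TSV
#'
#' @param expr an [expression_matrix].
#' @param path output path.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene = expr$genes, expr$values, check.names = FALSE)
  names(df) <- c("gene", expr$neurons)
  write_tsv(df, path)
  invisible(path)
}

#' Convert a connectome to an igraph graph
#'
#' A single directed graph: chemical edges keep their direction; each
#' electrical edge is stored once in canonical `a -> b` orientation with edge
#' attribute `type = "electrical"`.
#'
#' @param c a [connectome].
#' @return An igraph graph with node attributes `class`, `category`,
#'   `pharyngeal` and edge attributes `type`, `weight`.
#' @export
as_igraph <- function(c) {
  edges <- rbind(
    data.frame(from = c$chemical$pre, to = c$chemical$post,
               weight = c$chemical$weight, type = "chemical",
               stringsAsFactors = FALSE),
    data.frame(from = c$electrical$a, to = c$electrical$b,
               weight = c$electrical$weight, type = "electrical",
               stringsAsFactors = FALSE))
  vertices <- c$neurons
  names(vertices)[1] <- "name"
  igraph::graph_from_data_frame(edges, directed = TRUE, vertices = vertices)
}

#' Rebuild a connectome from an annotated igraph graph
#'
#' Inverse of [as_igraph] (and of the GraphML files written by
#' [export_annotated_network]).
#'
#' @param g an igraph graph with the attributes written by [as_igraph].
#' @return A [connectome].
#' @export
connectome_from_igraph <- function(g) {
  vt <- igraph::as_data_frame(g, what = "vertices")
  neurons <- data.frame(id = vt$name, class = vt$class,
                        category = vt$category,
                        pharyngeal = parse_logical(vt$pharyngeal, "pharyngeal"),
                        stringsAsFactors = FALSE)
  ed <- igraph::as_data_frame(g, what = "edges")
  chem <- ed[ed$type == "chemical", c("from", "to", "weight")]
  names(chem) <- c("pre", "post", "weight")
  elec <- ed[ed$type == "electrical", c("from", "to", "weight")]
  names(elec) <- c("a", "b", "weight")
  connectome(neurons, chem, elec)
}

#' Export an annotated network for visualization tools
#'
#' Writes a GraphML file plus node/edge attribute TSVs (Cytoscape-importable).
#' Edge width in downstream display is conventionally proportional to the EM
#' weight, which is carried on every edge. Attributes for unknown nodes or
#' edges are dropped with a warning; attribute keys for electrical edges are
#' matched after canonicalizing the endpoint order.
#'
#' @param c a [connectome].
#' @param node_attrs optional data.frame keyed by column `id`.
#' @param edge_attrs optional data.frame keyed by columns `from`, `to`.
#' @param out_prefix output path prefix; writes `<prefix>.graphml`,
#'   `<prefix>_nodes.tsv`, `<prefix>_edges.tsv`.
#' @return Invisibly, the paths written.
#' @export
export_annotated_network <- function(c, node_attrs = NULL, edge_attrs = NULL,
                                     out_prefix) {
  g <- as_igraph(c)
  if (!is.null(node_attrs)) {
    stopifnot("id" %in% names(node_attrs))
    unknown <- setdiff(node_attrs$id, neuron_ids(c))
    if (length(unknown)) {
      warning("dropping attributes for unknown node(s): ",
              paste(unknown, collapse = ", "))
      node_attrs <- node_attrs[!(node_attrs$id %in% unknown), , drop = FALSE]
    }
    idx <- match(igraph::V(g)$name, node_attrs$id)
    for (col in setdiff(names(node_attrs), "id")) {
      g <- igraph::set_vertex_attr(g, col, value = node_attrs[[col]][idx])
    }
  }
  if (!is.null(edge_attrs)) {
    stopifnot(all(c("from", "to") %in% names(edge_attrs)))
    ed <- igraph::as_data_frame(g, what = "edges")
    ekey <- ifelse(ed$type == "electrical",
                   paste(pmin(ed$from, ed$to), pmax(ed$from, ed$to)),
                   paste(ed$from, ed$to))
    # try ordered key first, then canonical (covers electrical given as (b, a))
    akey_ord <- paste(edge_attrs$from, edge_attrs$to)
    akey_can <- paste(pmin(edge_attrs$from, edge_attrs$to),
                      pmax(edge_attrs$from, edge_attrs$to))
    pos <- match(akey_ord, paste(ed$from, ed$to))
    pos[is.na(pos)] <- match(akey_can[is.na(pos)], ekey)
    if (anyNA(pos)) {
      miss <- which(is.na(pos))[1]
      warning(sprintf("dropping attributes for unknown edge (%s, %s)",
                      edge_attrs$from[miss], edge_attrs$to[miss]))
    }
    keep <- !is.na(pos)
    for (col in setdiff(names(edge_attrs), c("from", "to"))) {
      v <- rep(NA, nrow(ed))
      v[pos[keep]] <- edge_attrs[[col]][keep]
      g <- igraph::set_edge_attr(g, col, value = v)
    }
  }
  graphml <- paste0(out_prefix, ".graphml")
  igraph::write_graph(g, graphml, format = "graphml")
  nodes_tsv <- paste0(out_prefix, "_nodes.tsv")
  edges_tsv <- paste0(out_prefix, "_edges.tsv")
  vt <- igraph::as_data_frame(g, what = "vertices")
  names(vt)[1] <- "id"
  write_tsv(vt, nodes_tsv)
  write_tsv(igraph::as_data_frame(g, what = "edges"), edges_tsv)
  invisible(c(graphml = graphml, nodes = nodes_tsv, edges = edges_tsv))
}
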