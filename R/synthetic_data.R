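# Synthetic connectomes, contact maps, expression atlases and motif tables
# with planted ground truth.
#
# The generator emulates the structure the statistical modules interrogate:
# bilateral neuron classes, a sparse symmetric membrane-contact mask, sparse
# directed chemical and undirected electrical synapses drawn only on
# contact-adjacent pairs, and binary class-coherent gene expression with
# optional planted "circuit organizer" genes whose expression sets are
# densely interconnected.

#' Synthetic dataset configuration
#'
#' Defaults describe a 100-neuron nervous system of 50 bilateral classes with
#' a sparse contact mask and sparse synapses; background genes are expressed
#' class-coherently at low frequency.
#'
#' @param n_classes number of neuron classes (default 50).
#' @param class_size neurons per class (default 2, bilateral L/R pairs).
#' @param p_contact probability that an unordered neuron pair is in membrane
#'   contact (default 0.3).
#' @param p_chem_given_contact probability of a chemical synapse on each
#'   ordered contact-adjacent pair (default 0.05).
#' @param p_elec_given_contact probability of an electrical synapse on each
#'   unordered contact-adjacent pair (default 0.02).
#' @param planted list of planted circuit-organizer genes, each a list with
#'   `gene`, `n_classes_in_circuit`, `within_circuit_edge_prob`.
#' @param n_background_genes number of background genes (default 50).
#' @param background_expression_prob per-class expression probability for
#'   background genes (default 0.1).
#' @param per_neuron_noise probability that an individual neuron's call is
#'   flipped after the class-level draw (default 0, fully class-coherent).
#' @param seed integer seed; all draws are deterministic given it.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_classes = 50, class_size = 2,
                             p_contact = 0.3,
                             p_chem_given_contact = 0.05,
                             p_elec_given_contact = 0.02,
                             planted = list(),
                             n_background_genes = 50,
                             background_expression_prob = 0.1,
                             per_neuron_noise = 0,
                             seed = 1L) {
  probs <- c(p_contact, p_chem_given_contact, p_elec_given_contact,
             background_expression_prob, per_neuron_noise)
  stopifnot(all(probs >= 0 & probs <= 1), n_classes >= 2, class_size >= 1)
  for (pl in planted) {
    stopifnot(all(c("gene", "n_classes_in_circuit",
                    "within_circuit_edge_prob") %in% names(pl)))
    if (pl$n_classes_in_circuit > n_classes) {
      stop("planted circuit size exceeds the number of classes")
    }
    stopifnot(pl$within_circuit_edge_prob >= 0,
              pl$within_circuit_edge_prob <= 1)
  }
  structure(list(n_classes = n_classes, class_size = class_size,
                 p_contact = p_contact,
                 p_chem_given_contact = p_chem_given_contact,
                 p_elec_given_contact = p_elec_given_contact,
                 planted = planted,
                 n_background_genes = n_background_genes,
                 background_expression_prob = background_expression_prob,
                 per_neuron_noise = per_neuron_noise,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

synthetic_neuron_table <- function(config, with_categories = FALSE) {
  classes <- sprintf("C%03d", seq_len(config$n_classes))
  suffix <- if (config$class_size == 1) "" else
    if (config$class_size == 2) c("L", "R") else
      as.character(seq_len(config$class_size))
  ids <- as.vector(t(outer(classes, suffix, paste0)))
  category <- "other"
  if (with_categories) {   # draws from the current RNG stream
    category <- rep(sample(c("sensory", "inter", "motor"),
                           config$n_classes, replace = TRUE),
                    each = config$class_size)
  }
  data.frame(id = ids, class = rep(classes, each = config$class_size),
             category = category, pharyngeal = FALSE,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic connectome with planted circuits
#'
#' Samples a symmetric contact mask, then chemical (directed) and electrical
#' (undirected) synapses only on contact-adjacent pairs. Each planted gene
#' picks `n_classes_in_circuit` classes at random; ordered cross-class pairs
#' inside the circuit receive chemical edges at `within_circuit_edge_prob`
#' instead of the background rate, and all internal circuit pairs are forced
#' contact-adjacent (circuit neurons share a neuropil). Edge weights are
#' `geometric(0.5) + 1` EM-style section counts; weights never affect any
#' statistic. Deterministic given `config$seed`.
#'
#' @param config a [synthetic_config].
#' @return List with elements `connectome` ([connectome]), `contacts`
#'   ([contact_map]) and `truth` (planted gene -> neuron sets plus all
#'   generator parameters and seed).
#' @export
generate_connectome <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(derive_seed(config$seed, 1))
  neurons <- synthetic_neuron_table(config, with_categories = TRUE)
  ids <- neurons$id
  V <- length(ids)
  cls <- neurons$class

  adj <- matrix(FALSE, V, V, dimnames = list(ids, ids))
  up <- which(upper.tri(adj), arr.ind = TRUE)
  hit <- rbinom(nrow(up), 1, config$p_contact) == 1
  adj[up[hit, , drop = FALSE]] <- TRUE

  # planted circuits: choose whole classes, force internal contact. The
  # within-circuit probability applies per unordered internal cross-class
  # pair, with the edge direction drawn at random: circuits are densely but
  # not reciprocally wired, matching how real microcircuits look. Drawing
  # both directions independently would build a reciprocal mesh whose
  # distinct-pair count a degree-preserving null can nearly reproduce.
  planted_truth <- list()
  planted_edges <- NULL
  for (pl in config$planted) {
    circ_classes <- sample(unique(cls), pl$n_classes_in_circuit)
    members <- which(cls %in% circ_classes)
    adj[members, members] <- TRUE
    cross <- which(outer(cls[members], cls[members], "!=") &
                     upper.tri(matrix(0, length(members), length(members))),
                   arr.ind = TRUE)
    on <- rbinom(nrow(cross), 1, pl$within_circuit_edge_prob) == 1
    dir_flip <- rbinom(nrow(cross), 1, 0.5) == 1
    i <- members[cross[, 1]]; j <- members[cross[, 2]]
    pre <- ifelse(dir_flip, j, i); post <- ifelse(dir_flip, i, j)
    planted_edges <- rbind(planted_edges,
                           cbind(pre[on], post[on]))
    planted_truth[[pl$gene]] <- list(classes = circ_classes,
                                     neurons = ids[members],
                                     within_circuit_edge_prob =
                                       pl$within_circuit_edge_prob)
  }
  diag(adj) <- FALSE
  adj <- adj | t(adj)

  # background chemical edges on ordered contact-adjacent pairs
  pchem <- matrix(config$p_chem_given_contact, V, V)
  pchem[!adj] <- 0
  diag(pchem) <- 0
  draw <- matrix(rbinom(V * V, 1, as.vector(pchem)), V, V) == 1
  chem_idx <- which(draw, arr.ind = TRUE)
  if (!is.null(planted_edges)) chem_idx <- rbind(chem_idx, planted_edges)
  chem_idx <- unique(chem_idx)
  chemical <- data.frame(pre = ids[chem_idx[, 1]], post = ids[chem_idx[, 2]],
                         weight = rgeom(nrow(chem_idx), 0.5) + 1L,
                         stringsAsFactors = FALSE)

  # electrical edges on unordered contact-adjacent pairs
  up_ok <- up[adj[up], , drop = FALSE]
  ehit <- rbinom(nrow(up_ok), 1, config$p_elec_given_contact) == 1
  elec_idx <- up_ok[ehit, , drop = FALSE]
  electrical <- data.frame(a = ids[elec_idx[, 1]], b = ids[elec_idx[, 2]],
                           weight = rgeom(nrow(elec_idx), 0.5) + 1L,
                           stringsAsFactors = FALSE)

  truth <- structure(list(planted = planted_truth, config = config,
                          seed = config$seed),
                     class = "synthetic_truth")
  list(connectome = connectome(neurons, chemical, electrical),
       contacts = contact_map(ids, adj),
       truth = truth)
}

#' Generate a synthetic binary expression atlas
#'
#' Planted genes are expressed in exactly their planted class unions.
#' Background genes are expressed per class independently at
#' `background_expression_prob`; both members of a class share every call
#' (class-coherent, as atlas expression is reported per class) unless
#' `per_neuron_noise > 0` flips individual neurons.
#'
#' @param config the [synthetic_config] used for [generate_connectome].
#' @param truth the `truth` element returned by [generate_connectome].
#' @return An [expression_matrix] (binary 0/1 values).
#' @export
generate_expression <- function(config, truth) {
  stopifnot(inherits(config, "synthetic_config"),
            inherits(truth, "synthetic_truth"))
  set.seed(derive_seed(config$seed, 2))
  neurons <- synthetic_neuron_table(config)  # same seed-independent layout
  ids <- neurons$id
  cls <- neurons$class
  classes <- unique(cls)
  bg_genes <- if (config$n_background_genes > 0)
    sprintf("bg%03d", seq_len(config$n_background_genes)) else character(0)
  genes <- c(names(truth$planted), bg_genes)
  m <- matrix(0, length(genes), length(ids), dimnames = list(genes, ids))
  for (g in names(truth$planted)) {
    m[g, truth$planted[[g]]$neurons] <- 1
  }
  for (g in bg_genes) {
    on_classes <- classes[rbinom(length(classes), 1,
                                 config$background_expression_prob) == 1]
    m[g, cls %in% on_classes] <- 1
  }
  if (config$per_neuron_noise > 0) {
    flip <- matrix(rbinom(length(m), 1, config$per_neuron_noise), nrow(m)) == 1
    m[flip] <- 1 - m[flip]
  }
  expression_matrix(m)
}

#' Generate a synthetic genome motif table with enriched reporter sets
#'
#' Genome-wide motif presence is sampled independently per motif at the given
#' probabilities. For each motif, a reporter gene set of size `n_reporters`
#' is drawn without replacement, oversampling motif-carrying genes at odds
#' `planted_reporter_effect` (1 = no enrichment; `Inf` = carriers only).
#'
#' @param n_genes genome universe size.
#' @param motif_probs named numeric vector of per-motif presence
#'   probabilities.
#' @param planted_reporter_effect odds ratio favouring carriers in the
#'   reporter draw.
#' @param n_reporters reporter set size (default 20).
#' @param seed integer seed.
#' @return List with `table` ([motif_presence_table]), `reporters` (named
#'   list, one set per motif) and `truth` (the parameters).
#' @export
generate_motif_tables <- function(n_genes, motif_probs,
                                  planted_reporter_effect = 1,
                                  n_reporters = 20, seed = 1L) {
  stopifnot(all(motif_probs >= 0 & motif_probs <= 1),
            planted_reporter_effect >= 0, n_reporters >= 1,
            n_reporters <= n_genes)
  if (is.null(names(motif_probs))) {
    names(motif_probs) <- sprintf("motif%d", seq_along(motif_probs))
  }
  set.seed(derive_seed(seed, 3))
  genes <- sprintf("g%05d", seq_len(n_genes))
  presence <- sapply(motif_probs, function(p) rbinom(n_genes, 1, p) == 1)
  rownames(presence) <- genes
  tab <- motif_presence_table(presence)
  reporters <- lapply(names(motif_probs), function(m) {
    has <- presence[, m]
    if (is.infinite(planted_reporter_effect)) {
      carriers <- genes[has]
      if (length(carriers) < n_reporters) {
        stop("not enough motif-carrying genes for an all-carrier reporter set")
      }
      sample(carriers, n_reporters)
    } else {
      w <- ifelse(has, planted_reporter_effect, 1)
      sample(genes, n_reporters, prob = w)
    }
  })
  names(reporters) <- names(motif_probs)
  list(table = tab, reporters = reporters,
       truth = list(motif_probs = motif_probs,
                    planted_reporter_effect = planted_reporter_effect,
                    n_reporters = n_reporters, seed = seed))
}

#' Write a complete synthetic dataset to standard-format files
#'
#' Generates a connectome, contact map and expression atlas and writes the
#' TSV files consumed by [run_full_analysis].
#'
#' @param config a [synthetic_config].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a named vector of the paths written.
#' @export
write_synthetic_dataset <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gen <- generate_connectome(config)
  expr <- generate_expression(config, gen$truth)
  paths <- c(neurons = file.path(out_dir, "neurons.tsv"),
             chemical = file.path(out_dir, "chemical_edges.tsv"),
             electrical = file.path(out_dir, "electrical_edges.tsv"),
             contacts = file.path(out_dir, "contacts.tsv"),
             expression = file.path(out_dir, "expression.tsv"))
  write_connectome(gen$connectome, paths["neurons"], paths["chemical"],
                   paths["electrical"])
  write_contact_map(gen$contacts, paths["contacts"], dialect = "edges")
  write_expression(expr, paths["expression"])
  yaml::write_yaml(list(planted = lapply(gen$truth$planted, function(x)
    list(classes = x$classes, neurons = x$neurons)),
    seed = config$seed), file.path(out_dir, "truth.yaml"))
  invisible(paths)
}
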