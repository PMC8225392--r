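# In-code fixtures shared across test files.

# four neurons in four classes; chemical A->B, B->C; electrical C-D
toy4 <- function() {
  connectome(
    data.frame(id = c("A", "B", "C", "D"),
               class = c("cA", "cB", "cC", "cD")),
    chemical = data.frame(pre = c("A", "B"), post = c("B", "C"),
                          weight = c(2L, 1L)),
    electrical = data.frame(a = "C", b = "D", weight = 1L))
}

# bilateral pair AVA + single-class ASH example used for universe counting
ava_ash_classes <- c(AVAL = "AVA", AVAR = "AVA", ASHL = "ASH")

full_contact <- function(ids) {
  m <- matrix(TRUE, length(ids), length(ids))
  contact_map(ids, m)
}

toy_expression <- function(genes, neurons, on) {
  m <- matrix(0, length(genes), length(neurons),
              dimnames = list(genes, neurons))
  for (g in names(on)) m[g, on[[g]]] <- 1
  expression_matrix(m)
}

# planted-circuit dataset for pipeline/NDGE tests. Few genes keep the NDGE
# minimum attainable q-value below the 5% FDR at modest rewire counts; the
# circuit must stay small relative to its members' contact neighborhoods or
# the degree-preserving null cannot move edges out of it
small_planted_config <- function(seed = 101) {
  synthetic_config(n_classes = 50, class_size = 2, p_contact = 0.3,
                   p_chem_given_contact = 0.05, p_elec_given_contact = 0.02,
                   planted = list(list(gene = "planted",
                                       n_classes_in_circuit = 4,
                                       within_circuit_edge_prob = 0.9)),
                   n_background_genes = 10,
                   background_expression_prob = 0.1, seed = seed)
}

extdata <- function(f) {
  system.file("extdata", f, package = "circuitenrich", mustWork = TRUE)
}
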