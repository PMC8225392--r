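Package: circuitenrich
Title: Enrichment Statistics Linking Gene Expression to Synaptic Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistical tests for asking whether a transcription factor is
    expressed in a set of synaptically interconnected neurons. Implements a
    binomial pair-connectivity enrichment test over ordered cross-class
    neuron pairs, network differential gene expression (NDGE) with a
    degree- and membrane-contact-preserving connectome rewiring null and
    empirical p-values, hypergeometric binding-site (co-)enrichment tests,
    Benjamini-Hochberg FDR control, synthetic connectome and expression
    generators with planted circuit-organizer genes, and a reproducible
    end-to-end pipeline with annotated GraphML network export.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
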