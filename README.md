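# circuitenrich

Statistical tests for asking whether a gene — typically a terminal-selector
transcription factor — is expressed in a set of **synaptically
interconnected** neurons of a connectome, rather than in a random
collection of cells. Written for systems neuroscientists working with
C. elegans–style datasets: a neuron table with class labels, a directed
weighted chemical-synapse edge list, an undirected electrical-synapse edge
list, a membrane-contact adjacency map, and a gene × neuron expression
atlas.

Two complementary tests are implemented:

1. **Binomial pair-connectivity enrichment.** Over all ordered cross-class
   neuron pairs, the global connection probability *p* is the fraction of
   pairs joined by a chemical synapse (in that direction) and/or an
   electrical synapse (either direction). For a gene expressed in *m*
   neurons, its *n* ordered cross-class pairs yield *k* connected pairs, and
   enrichment is scored with the binomial law Pr(X ≥ k) (the point mass
   Pr(X = k) is also reported), followed by Benjamini–Hochberg FDR across a
   gene family.
2. **Network differential gene expression (NDGE).** Contact-adjacent
   unordered pairs are split into synaptic and non-synaptic groups; each
   gene's homomeric co-expression (mean of x_i·x_j) is compared between the
   groups as log(mean_syn + ε) − log(mean_non + ε). Significance comes from
   an empirical null in which the connectome is rewired by a
   contact-constrained double-edge-swap chain preserving every neuron's
   per-type degrees, with FDR control and a log-fold-change gate
   (defaults: 5% FDR, logFC > 6e-3).

The package also provides hypergeometric binding-site enrichment and
cofactor co-enrichment over gene × motif presence tables, synthetic
connectome/expression/motif generators with planted ground truth, annotated
GraphML export, and a one-call pipeline.

## Worked example

```r
library(circuitenrich)

# synthetic nervous system: 50 bilateral classes (100 neurons), one planted
# circuit-organizer gene expressed in 5 densely interconnected classes
cfg <- synthetic_config(
  planted = list(list(gene = "tf1", n_classes_in_circuit = 5,
                      within_circuit_edge_prob = 0.8)),
  seed = 42)
gen  <- generate_connectome(cfg)
expr <- generate_expression(cfg, gen$truth)

screen <- test_gene_family(gen$connectome, expr, expr$genes)
head(screen[order(screen$qvalue), ], 3)
#>     gene n_trials k_successes  p_success   pvalue_pmf  pvalue_tail       qvalue testable
#>      tf1       80          37 0.02367347 2.163335e-38 2.224282e-38 1.067655e-36     TRUE
#>    bg016       48           6 0.02367347 7.897022e-04 9.205664e-04 1.472906e-02     TRUE
#>    bg031       80           8 0.02367347 5.095105e-04 6.284044e-04 1.472906e-02     TRUE

# 2000 rewires: empirical p-values have resolution 1/(R+1), and a lone
# discovery among 51 genes can only clear 5% FDR when R + 1 > 51/0.05
ndge <- run_ndge(gen$connectome, gen$contacts, expr,
                 config = ndge_config(n_rewires = 2000, seed = 7))
head(ndge[order(ndge$pvalue), c("gene", "logfc", "pvalue", "qvalue", "significant")], 2)
#>     gene   logfc     pvalue    qvalue significant
#>      tf1 3.10055 0.00049975 0.0254873        TRUE
#>    bg020 1.33699 0.00299850 0.0764618       FALSE
```

The planted gene tops both rankings: its 80 ordered cross-class pairs
contain 37 connected pairs against a global connection probability of
0.024 (binomial tail ~2e-38), and its synaptic-versus-nonsynaptic
co-expression log-fold change of 3.1 exceeds every rewired-null replicate
(empirical p = 1/2001). `bg016`/`bg031` illustrate that background genes
whose expression happens to overlap the planted circuit inherit real
signal.

`run_full_analysis()` runs both screens from files (TSV connectome tables,
contact map, expression matrix), writing result TSVs, a volcano table, an
annotated GraphML network, and a JSON summary; `inst/scripts/circuit-enrich.R`
is a thin command-line wrapper with `run`, `synth` and `simstudy`
subcommands.

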