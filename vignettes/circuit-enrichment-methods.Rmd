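---
title: "Statistical methods for linking gene expression to synaptic connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for linking gene expression to synaptic connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circuitenrich)
```

## The question

Terminal-selector transcription factors specify neuron identities. Some of
them appear to be expressed not in arbitrary collections of neurons but in
sets of neurons that are *synaptically interconnected* — candidate "circuit
organizers". `circuitenrich` provides two complementary statistical tests of
that hypothesis on a connectome (directed weighted chemical synapses plus
undirected electrical synapses over named, classed neurons), together with
the data containers, a membrane-contact-aware null model, synthetic data
generators with planted ground truth, and hypergeometric binding-site
enrichment for downstream cis-regulatory analysis.

## The binomial pair-connectivity test

The unit of observation is an **ordered neuron pair** $(i, j)$, $i \ne j$.
Pairs whose members belong to the same neuron class (bilateral or radial
homologs such as AVAL/AVAR) are excluded by default: homologous pairs are
developmentally coupled and would trivially inflate any expression-based
statistic. The global success probability

$$p = \frac{\#\{\text{connected ordered pairs}\}}{\#\{\text{ordered pairs}\}}$$

is computed over the somatic (non-pharyngeal) connectome. An ordered pair is
*connected* when a chemical synapse runs $i \to j$ or an electrical synapse
joins $\{i, j\}$; electrical synapses therefore register for both orderings
while chemical synapses count only in their own direction (the
double-counting convention). For a gene expressed in $m$ neurons, the same
universe restricted to those neurons gives $n$ trials and $k$ connected
pairs, and the enrichment is scored with the binomial law
$\Pr(X = k) = \binom{n}{k} p^k (1-p)^{n-k}$.

Two p-values are reported. `pvalue_pmf` is the point mass $\Pr(X = k)$, the
quantity the original procedure computed; `pvalue_tail` is
$\Pr(X \ge k)$ and is the package default, because a point probability is
not a valid tail test — it can be small for *depleted* as well as enriched
genes and does not decrease monotonically with enrichment. Both are exposed
so either convention can be screened and FDR-adjusted
(Benjamini–Hochberg, over testable genes only; genes expressed in fewer
than two neurons, or only within one class, have an empty universe and are
flagged untestable with $q = 1$).

## Network differential gene expression (NDGE)

The binomial test ignores physical opportunity: neurons that never touch
cannot form synapses. NDGE conditions on a **membrane-contact map**. All
unordered contact-adjacent pairs are partitioned into synaptically linked
pairs and non-linked pairs, and for each gene the *homomeric* (paired
multiplicative) expression $x_i x_j$ is averaged over both groups. The
statistic is a log-fold change

$$\mathrm{logFC} =
\log\!\big(\overline{x_i x_j}^{\,\text{syn}} + \varepsilon\big) -
\log\!\big(\overline{x_i x_j}^{\,\text{non-syn}} + \varepsilon\big),$$

with natural logs and pseudocount $\varepsilon = 10^{-6}$ guarding the
zero-co-expression case. Expression is binarized by default (atlas
presence/absence calls); continuous values are log1p-scaled before
multiplication.

Significance comes from an empirical null: the connectome is rewired by a
contact-constrained double-edge-swap Markov chain that preserves every
neuron's chemical in- and out-degree and electrical degree exactly, forbids
self-loops and duplicate edges, and only places edges between
contact-adjacent neurons. Chemical and electrical edges are swapped as
separate pools. Expression is never permuted; only the synaptic/non-synaptic
partition changes across the `n_rewires` replicates, each driven by an
independently derived seed. The upper-tail empirical p-value is
$(1 + \#\{\text{null} \ge \text{obs}\}) / (1 + R)$, never zero, followed by
Benjamini–Hochberg adjustment. A gene is flagged significant when
$q < $ `fdr_level` (default 0.05) *and* $\mathrm{logFC} > $
`logfc_threshold` (default $6 \times 10^{-3}$ — deliberately tiny, because
requiring a gene in *both* members of a pair makes co-expression a
combinatorially rare event, so informative fold changes are much smaller
than in ordinary differential expression).

### Tunable parameters

| parameter | default | why |
|---|---|---|
| `n_rewires` | 1000 | null resolution; p-values cannot go below $1/(R+1)$ |
| `swap_attempts_factor` | 100 | proposals per replicate as a multiple of the edge count |
| `pseudocount` | 1e-6 | floor for $\log$ of a zero co-expression mean |
| `logfc_threshold` | 6e-3 | effect-size gate on the significance flag |
| `fdr_level` | 0.05 | Benjamini–Hochberg level |
| `include_electrical` | TRUE | electrical edges count as synaptic links, matching the binomial test's success rule |

Two numerical points deserve emphasis.

**Mixing.** Contact-mask rejections make swap acceptance rates low (under
10% at typical contact densities), so the chain needs many more proposals
than edges: at the default factor of 100 each edge is typically swapped ten
or more times. At a factor of 10 we observed replicates that still carried
recognizable clumps of the original topology, which inflates the null's
upper tail and costs power.

**Granularity.** Empirical p-values live on the grid $k/(R+1)$. With $G$
genes, a lone gene at the minimum attainable p-value has BH-adjusted
$q = G/(R+1)$; for any lone discovery to clear FDR level $\alpha$ one needs
$R + 1 > G/\alpha$. Screens of ~50 genes at FDR 5% therefore need
$R \ge 1000$, and the parameter-recovery study in the test-suite uses
$R = 2000$.

## Synthetic data and what passing tests mean

`generate_connectome()` builds a nervous system of `n_classes` bilateral
classes (default 50 classes × 2 members = 100 neurons), samples a symmetric
membrane-contact mask at `p_contact = 0.3`, then draws directed chemical
synapses on contact-adjacent ordered pairs at 0.05 and undirected electrical
synapses at 0.02. A planted "circuit organizer" picks whole classes; each
internal cross-class unordered pair becomes a chemical edge with probability
`within_circuit_edge_prob` (0.8 in the recovery studies) in a uniformly
random direction, and internal pairs are forced into contact, reflecting
that circuit neurons share a neuropil. The direction draw matters: wiring
both directions independently would build a reciprocally saturated mesh
whose distinct-synaptic-pair count a degree-preserving null can nearly
reproduce, hiding the circuit from the unordered homomeric statistic — and
real microcircuits are not reciprocally saturated.
Expression is class-coherent (both class members share every call, as
atlases report expression per class): planted genes cover exactly their
circuit classes, background genes switch on per class at probability 0.1 —
roughly the breadth of a selectively expressed homeobox gene. Edge weights
are geometric section counts that exercise the weighted exports but never
enter any statistic.

What the generator deliberately does **not** emulate: the real degree
distribution (no hubs beyond sampling noise), spatial ganglion structure,
correlated expression programs across genes, left/right asymmetric wiring,
and expression-annotation noise (available behind `per_neuron_noise` but off
by default). Recovery of planted circuits therefore demonstrates that the
statistics detect the *targeted* signal under controlled conditions, not
that real connectomes meet the tests' assumptions.

The problem sizes used by the shipped test-suite — 100-neuron connectomes,
50 background genes, $R = 200$ for calibration and $R = 2000$ for recovery,
50 replicate datasets or seeds per study — were chosen as the smallest
designs at which the studied properties are stable across seeds.

## Design decisions

- **Same-class exclusion.** "Excluding pairs within a neuron class" is the
  interpretation adopted for the universe; excluding *cross*-class pairs
  would leave nothing to test. The rule is configurable (`"none"`).
- **Tail versus point mass.** Default `pvalue_kind = "tail"`; `"pmf"`
  reproduces the as-published behaviour.
- **Separate swap pools.** Chemical and electrical edges never exchange
  type, so each type's degree sequence is preserved exactly; autapses are
  stored but excluded from the swap pool and from every pair statistic.
- **Cofactor expectation.** The cofactor co-enrichment test converts the
  product of two genome-wide motif proportions into an expected carrier
  count; that count is rounded to the nearest integer before the
  hypergeometric tail. The observed joint genome count (`expectation =
  "joint"`) and a binomial tail on the product probability (`test =
  "binomial"`) are both exposed because the rounding is an approximation;
  when the observed foreground count exceeds the rounded expectation the
  reported tail is evaluated at the expectation and is a lower bound
  (with a warning).
- **Ties and degenerate genes.** Null values exactly equal to the observed
  statistic count against the gene (`>=` in the tail), making p-values
  conservative under ties; genes with no expressing neuron pair keep
  $\mathrm{logFC} = 0$ and can never be flagged.

## Known limitations

- The electrical double-counting convention makes the two orderings of a
  gap-junction pair perfectly correlated, so the binomial independence
  assumption is mildly violated and tail p-values are slightly
  anticonservative (the effect disappears with chemical synapses only).
  The convention is retained because it is the field's counting rule;
  treat binomial q-values near the threshold with care. The acceptance
  script reports the realized null false-discovery proportion.
- Sparsely expressed genes often have *zero* co-expression across synaptic
  pairs; their statistic sits on the pseudocount floor and their empirical
  p-values cluster near 1 (conservative, superuniform). Calibration checks
  therefore use genes expressed in a random half of the classes, which keep
  the statistic off the floor.
- A planted circuit that saturates its members' contact neighborhoods
  leaves the degree-preserving null no room to move edges away, and the
  unordered pair statistic can even favour the null (reciprocal edges
  collapse to one pair in the observed graph but spread out in rewired
  ones). Detection requires circuits small relative to their members'
  contact neighborhoods — which is also the biologically interesting
  regime.
- The rewiring null conditions on the exact degree sequences; it answers
  "is co-expression aligned with *which* pairs are wired, given how wired
  every neuron is", not whether the gene's neurons are unusually active
  overall.

## A worked example

```{r example, eval = FALSE}
cfg <- synthetic_config(
  planted = list(list(gene = "tf1", n_classes_in_circuit = 5,
                      within_circuit_edge_prob = 0.8)),
  seed = 42)
gen  <- generate_connectome(cfg)
expr <- generate_expression(cfg, gen$truth)

screen <- test_gene_family(gen$connectome, expr, expr$genes)
ndge   <- run_ndge(gen$connectome, gen$contacts, expr,
                   config = ndge_config(n_rewires = 2000, seed = 7))

head(screen[order(screen$qvalue), ])
head(ndge[order(ndge$pvalue), ])
```

The planted gene is expected first in both rankings; `run_full_analysis()`
wraps the same computations around file input/output, GraphML export and a
JSON run summary.
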