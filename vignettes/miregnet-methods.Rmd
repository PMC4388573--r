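---
title: "Methods: disease-specific miRNA-target network construction and ranking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disease-specific miRNA-target network construction and ranking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miregnet)
```

## The problem

MicroRNAs (miRNAs) repress mRNAs post-transcriptionally, typically by
binding the 3'-UTR. Sequence-based target predictors return hundreds of
predicted targets per miRNA, most of them irrelevant in any given disease
context. `miregnet` prioritises miRNA-target interactions and genes for a
specific pathology by demanding converging evidence from four independent
sources: the literature, sequence-based predictions, paired expression
profiles, and protein-protein interactions (PPI), and then ranking genes by
the functional coherence of the regulatory neighbourhood they sit in rather
than in isolation.

## Step 1 — seeding the network from literature and expression

**Literature disease score.** For a corpus of `m` publications that carry
gene information, of which `n` belong to the disease query, a gene with `j`
publications, `k` of them disease-related, gets the upper-tail probability

$$H(m, n, j, k) = \sum_{i=k}^{\min(n,j)}
  \frac{\binom{m-j}{n-i}\binom{j}{i}}{\binom{m}{n}},
  \qquad ds = -\log_{10} H .$$

Genes with `ds` strictly greater than 4 (tail below $10^{-4}$) form the
disease gene set. The score is computed in log space (`phyper(log.p =
TRUE)`), so heavily studied genes can legitimately receive scores in the
hundreds without underflow; `DS_CAP = 320` is returned only for a tail that
is exactly zero (an empty sum). `m` and `n` are always derived from the
supplied corpus, never taken as external constants, which keeps small
fixtures self-consistent.

**Anticorrelation filter.** A predicted pair (miRNA `m`, target `t`) with
paired expression over the same samples is retained iff its Pearson
correlation is negative and significant:

$$RC = \{(m, t) \mid m \in P(t),\ t \in GS(D),\
  |\rho_{mt}| \ge min\_corr,\ \rho_{mt} < 0\},$$

where `min_corr` is the smallest absolute correlation whose two-sided
t-test p-value (df = n − 2) reaches `alpha_corr = 0.05` at the sample size
at hand — `min_significant_corr(111) = `
`r round(min_significant_corr(111), 4)` at 111 samples, for example. The
two-sided reading is the conservative choice given the additional sign
constraint. Ties at the threshold are retained (the predicate is `>=`).
Pairs with a zero-variance profile have no defined correlation and simply
fail the filter; features absent from the expression matrices are skipped
and counted in the run log, since the predicate is only defined where a
correlation exists.

## Step 2 — functional background and guilt-by-association extension

**Background functions.** Each GO term annotating at least one
disease-set gene is tested for enrichment; p-values are BH-adjusted across
the tested terms and terms with adjusted p ≤ 0.05 are kept. Restricting BH
to terms that touch the query is deliberate: including untouched terms only
dilutes the correction. Two p-value modes exist:

* `mode = "paper"` (default) evaluates the closed form
  $\binom{k+j}{k}\binom{n-k+m-j}{n-k} / \binom{n+m}{n}$ literally on the
  counts (k, j, n, m). This contingency layout double-counts — `j`
  includes the `k` query hits and `m` includes the query — so it is *not*
  a standard Fisher exact test; it is retained as the default for fidelity
  to the published procedure, evaluated in log space with out-of-range
  results clamped to 1.
* `mode = "standard"` is the conventional one-sided Fisher exact test
  (hypergeometric upper tail on the corrected 2×2 table), provided because
  the original description is ambiguous about which computation was meant.

Annotations are used exactly as given; no GO-DAG ancestor propagation is
performed.

**PPI extension and target addition.** The target set is closed over the
PPI graph breadth-first (unlimited depth by default, i.e. the connected
component — the natural stopping point when no further interactor can be
imported), recording each imported gene's depth. Only genes at depth
exactly 1 — direct interactors of a miRNA target — are candidates, and
only if they carry at least one background function. A candidate is
admitted iff (a) it is predicted for at least one miRNA already in the
network and (b) it is anticorrelated with at least one of those miRNAs at
p ≤ 0.01; it is then connected to *every* miRNA of its qualifying set M.
Deeper imports are never candidates; they only feed the closure
bookkeeping. The procedure runs exactly once — a second invocation on an
extended network raises an error — because recursive application would
accumulate weak, indirect links.

## Step 3 — triangle subnetworks, centralities, ranking

**Subnetwork extraction.** The analysis graph contains the miRNAs and
their direct targets after target addition: one directed arc per
regulatory edge and both directions of every PPI edge between in-network
targets (interactions between an admitted and a base target are included —
both are direct targets). For a seed `s` with neighbourhood `N(s)` (the
undirected view, since triangle membership is symmetric), each neighbour
`u` contributes the intersection `N(s) ∩ (N(u) \ {s})`; the subnetwork
keeps `s` plus every neighbour participating in at least one triangle,
with all induced arcs. On the reference toy graph where `N(1) = {2, 4,
5}`, `N(2) \ {1} = {3, 4, 9, 11}`, `N(4) \ {1} = {2, 3, 6}` and `N(5) \
{1} = {6, 7, 8}`, the intersections are `{4}`, `{2}` and `∅`, so the
subnetwork of seed 1 is `{1, 2, 4}` and the non-triangle neighbour 5 drops
out. Seeds without triangles yield singletons rather than being skipped,
so every node receives a subnetwork and a score.

**Centralities.** Betweenness uses directed shortest paths. Closeness is
harmonic (unreachable pairs contribute 0), the variant that stays well
defined on directed, disconnected graphs; eccentricity is taken over the
reachable set, with 0 for a node that reaches nothing. Eigenvector
centrality follows $x_i = \frac{1}{\lambda}\sum_j A_{ij} x_j$, read
row-wise: a node accumulates the values of its out-neighbours. It is
computed by power iteration on `A + I` with L1 normalisation from a
uniform start (tolerance 1e-10, at most 1e5 iterations). The identity
shift preserves the eigenvectors of `A` while preventing oscillation on
bipartite or periodic structures; this is the one numerically load-bearing
deviation from the bare iteration. On a defective dominant eigenvalue
(e.g. a directed path, where centrality is degenerate anyway) convergence
is only polynomial and the iteration reports a structured error carrying
its last iterate; such graphs do not arise from the triangle construction
in practice.

**Scoring and the meta-network.** For each subnetwork, every background
function is re-tested (same mode, *raw* p-values — BH is applied only to
background selection) with the subnetwork's gene nodes as the query (miRNA
nodes are excluded: the annotation covers genes). The regulatory
subnetwork score is the Fisher-combined-probability style sum

$$S(v) = \sum_{i:\, v_i > 0} -\log_{10}(v_i),$$

where exact p-values of 1 contribute nothing and an underflowed p-value is
floored at 1e-320 before the log (the `v_i > 0` guard is purely
numerical). Subnetworks then become nodes of a meta-network with an arc
A → B when B's seed lies inside A's subnetwork (self-membership never
creates a self-loop); the power-method value on this meta-network is the
reported PMs column. With the row-wise reading above, a subnetwork that
contains many other seeds accumulates their weight — large, seed-rich
subnetworks rank high, which is the intended "global influence" reading.

The report ranks seeds by S(v) descending, ties broken by subnetwork size
then seed ID. The disease-score column uses a −1.00 sentinel for miRNA
seeds and for genes with fewer than 9 supporting disease publications;
this publication count plays no role in selection (the only Step-1 filter
is ds > 4) — it is purely a reporting convention marking scores based on
thin literature. Two-decimal presentation columns are accompanied by
full-precision companions.

## The synthetic-data generator

Real inputs at full scale (a complete literature corpus, a genome-wide
prediction table, clinical expression cohorts, a proteome-wide PPI) are
not reproducible at desk scale, so `generate_fixtures()` emulates all five
inputs with planted, recoverable truths; every stage is validated against
the generator's manifest.

* **Literature**: a 6000-article corpus with 300 disease articles (5%
  base rate). Disease genes draw 40 publications with disease probability
  `min(0.95, 0.05 × pub_enrichment)` (0.5 at the default ten-fold
  enrichment), background genes 15 uniform draws. These sizes put planted
  genes far above the ds > 4 line and above the 9-publication sentinel
  with high probability while keeping false selections rare.
* **Expression**: miRNA profiles are standard normal; a planted target is
  `rho · x_miRNA + sqrt(1 − rho²) · noise`, so the population correlation
  is exactly `effect_rho` (−0.8 by default, at which the detection power
  at 100 samples is essentially 1; the spec constructor refuses
  underpowered settings). Decoy predicted pairs are independent noise.
* **Topology**: planted pairs are dealt to miRNAs in round-robin
  "modules", and each module's co-targets are joined in a PPI ring so the
  analysis graph genuinely contains triangles. A fraction of modules
  (`planted_term_coverage`) carries the planted GO term, the rest are
  term-free decoy modules — the contrast behind the ranking checks. Three
  reserved genes are planted as depth-1 interactors of base targets with
  full admission endowments (prediction, anticorrelation, background
  term), and one further gene has identical endowments but a PPI path
  only through a depth-1 interactor, probing the depth rule.
* Gaussian expression noise matches the linear-association assumption of
  the Pearson filter; array-specific artefacts (probe effects, batches),
  realistic GO DAG topology and scale-free PPI structure are *not*
  emulated, so passing tests demonstrate correctness of the filtering
  logic, not robustness to those real-data features.

All draws flow from one integer seed with the global RNG state restored
afterwards; identical specs give byte-identical files.

## Numerical and design notes

* Hypergeometric tails go through `phyper` in log space; the enrichment
  closed form uses `lchoose`. Both are checked against exhaustive
  combinatorial enumeration at small sizes in the test suite.
* BH adjustment is the standard step-up (`p.adjust`); note it is *not*
  idempotent on its own output in general — only constant lists are fixed
  points — which the tests reflect.
* Test problem sizes were chosen to exercise every rule at high planted
  signal: enumeration oracles up to universes of 15, 200 random digraphs
  for the triangle oracle, 50 spectral comparisons, and 20 generator
  seeds for the ranking contrast.
* The pipeline is deterministic given its inputs; the run log records an
  md5 digest per artifact so reruns can be compared byte for byte.

## Known limitations

* The literal "paper" enrichment mode is not a calibrated test; its
  values are comparable with each other but are not uniformly distributed
  under the null. The "standard" mode should be preferred when calibrated
  p-values matter.
* No miRNA-family collapsing, no weighting of conserved vs non-conserved
  sites, no confidence weights on PPI edges, no FDR across subnetwork
  scores.
* Eigenvector centrality on a directed graph depends on the chosen
  orientation convention (see above); comparisons with column-wise
  implementations will differ.
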