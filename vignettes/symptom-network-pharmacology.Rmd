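---
title: "Symptom-centered network pharmacology: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Symptom-centered network pharmacology: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sympnet)
```

## The analytical model

Disease-centric gene collection collapses a clinically heterogeneous
disease into one gene list and, with it, the molecular differences between
its manifestations. `sympnet` implements the symptom-centered alternative:
each clinical symptom is treated as an independent query against a
relevance-scored gene–association resource, the per-symptom lists are
filtered and merged by **union**, and gene prioritization happens on the
network of symptom associations rather than on a disease query. The
pipeline then asks three quantitative questions about the resulting core
genes: are they topologically central (consensus centrality), are they
dysregulated in patients (case–control expression), and how close is an
approved drug target to them in the interactome (network proximity)?

### Symptom gene sets

A gene enters a symptom's set when its relevance score is **at least** the
threshold (default 20; the comparison is inclusive because the resource's
own convention is "score ≥ 20"). Sets are merged by union: a gene relevant
to a single symptom is kept, deliberately, because symptom-specific signal
is the object of study. `membership_counts()` provides the multi-list
(Venn) accounting used everywhere downstream.

### Five-metric centrality consensus

Centrality is scored on the symptom-association network. Because the
source material for such analyses sometimes scores a two-mode
gene–symptom network and sometimes a projected gene–gene network — and
published degree scores quantized in steps of `1/24` are most naturally
explained by a two-mode network over 24 symptom-adjacent entities — the
package supports both constructions (`build_symptom_network(mode =
"bipartite")`, the default, or `"projection"`). The five indices are:

* **degree**: `deg(v)/(N−1)`, or in two-mode networks `deg(v)/|opposite
  partition|`, so a gene touching all symptom terms scores 1;
* **betweenness**: exact Brandes shortest-path betweenness on the
  unweighted graph, normalized by `(N−1)(N−2)/2`;
* **closeness**: the Wasserman–Faust form `((r−1)/Σd) · ((r−1)/(N−1))`
  over the `r` reachable nodes, which degrades gracefully on disconnected
  graphs and gives isolated nodes 0;
* **eigenvector (linked / edge)**: the principal eigenvector of the binary
  or confidence-weighted adjacency. The two variants are a documented
  stand-in for a pair of proprietary definitions in a commercial network
  tool; nothing downstream depends on matching those proprietary score
  values — the pipeline only performs set operations over the ranked
  lists.

Shortest paths are always hop counts: interaction confidences act as
inclusion thresholds and eigenvector weights, never as metric distances,
because combined confidence scores are not additive lengths.

Per metric, the top fraction (default 5 %) is selected with
**tie-inclusive** competition ranking: the `⌈0.05·N⌉`-th score is the
cutoff and every gene at the cutoff enters. This makes selection
deterministic under the heavy ties that quantized degree scores produce;
an exclusive policy is available (`top_fraction(ties = "exclude")`). The
**consensus core** is the genes in the top fraction of all five indices;
lowering `min_metrics` recovers the union and at-least-two summaries.

### PPI refinement

The consensus core is validated against a separate PPI network read at
confidence ≥ 0.7 (`read_edge_list()` auto-detects 0–1 vs 0–1000 score
dialects). A candidate is removed when it is absent from the PPI or has
**zero edges within the candidate-induced subgraph**. The induced-subgraph
reading of "no connectivity" is the default because refinement removes
genes *after* mapping an already-filtered candidate set; a whole-network
degree criterion is available (`connectivity = "global"`). Every removal
is logged with its reason, and refinement is idempotent.

### Expression validation

Fold change is the **linear-scale ratio of group means**,
`mean(case)/mean(control)`, computed per probe. Values that include
negatives and never exceed ~30 are auto-detected as log2 and exponentiated
first. Multi-probe genes are bridged by keeping the probe with the
smallest nominal p (alternatives: probe mean before testing, largest
absolute log fold change) — the bridge is configurable because published
per-gene values rarely state it. The test is a two-tailed t-test, Welch by
default (the safer choice when group variances are unknown), pooled
available for comparison; both nominal p and Benjamini–Hochberg FDR are
always reported side by side rather than collapsed. Degenerate inputs have
fixed conventions: both groups constant and equal gives p = 1, constant
and unequal gives p → 0 with a warning, and a nonpositive group mean is an
error because it signals centered or otherwise unsuitable input for a
ratio-based fold change.

### Network proximity

For a target gene `t` and core set `S`, the observed proximity is the mean
BFS distance from `t` to the reachable members of `S` (unreachable members
are listed, not averaged; the target itself is excluded from `S` by
default). The null is built from `n` (default 10,000) gene sets of the
same size drawn **uniformly without replacement** from the network's nodes
excluding the target — uniform rather than degree-matched because the
emulated procedure specifies only random sampling; the sampling background
(all network nodes) is a documented choice, not derivable from the
emulated procedure. Then

\[ z = \frac{d_{obs} - \mu_{null}}{\sigma_{null}}, \qquad p = \Phi(z), \]

with `σ` under the **population convention** (divide by `n`) — at
`n = 10,000` the distinction from the sample convention is negligible but
must be fixed for bit-reproducibility. The p-value is one-sided lower
tail: a z of −0.009 gives p ≈ 0.496, i.e. a target no closer than chance.
A degenerate null (σ = 0, e.g. on a complete graph) raises an explicit
error rather than returning an undefined z. Proximity distances are
computed on the **full background PPI**, so paths may traverse non-core
genes; this is why a target can have few direct neighbors in the core yet
a mean distance near 1 is not expected on the core-induced subgraph alone.
`direct_neighbors()` includes the target itself when it belongs to the
core (configurable), matching the convention of published neighbor lists
that count the target.

### Refined set and over-representation

The enrichment query merges the target's direct neighbors with the top
decile (default 10 %) of the core by centrality, deduplicated. ORA uses
the upper-tail hypergeometric probability `P(X ≥ k)` for overlap `k` given
universe `N`, pathway size `K`, query size `n`, with BH FDR across
pathways. The default universe is the union of all pathway members —
universe choice changes p-values, and the union is the only choice that is
reproducible from the GMT file alone; it can be overridden. Reported
`−log10 p` uses the nominal p, with FDR alongside.

## The synthetic-data generators

`synthetic_spec()` fixes the study conditions for all four generators;
every generator derives its RNG stream deterministically from the one
seed, and identical specs produce byte-identical files.

* **Symptom tables**: 24 symptom terms (the two-mode degree quantization
  hypothesis above, adopted as the default and documented as a hypothesis,
  not a claim about any particular study). Eight hub genes attach to each
  symptom with probability 0.9 and draw relevance from Gamma(shape 10,
  scale 4) (mean 40, almost always above the 20 cutoff); 400 background
  genes attach with probability 0.15 and draw from Gamma(2, 6) (mean 12,
  mostly below the cutoff). The gamma family keeps scores positive and
  right-skewed with mass straddling the threshold, which is what a
  composite evidence score looks like.
* **PPI**: a preferential-attachment graph (`m = 3`), giving the heavy
  right tail of interactome degree distributions; the highest-degree
  vertices are renamed to the hub genes so topological and symptom-level
  hubness coincide, as they do for well-studied inflammatory genes. Edge
  confidences are uniform on [0.4, 1.0], so the 0.7 filter removes about
  half the edges. An optional target analogue is wired either to the hubs
  (proximal, z ≪ 0 expected) or uniformly (null-like).
* **Expression**: 16 cases vs 16 controls — the size of a typical curated
  blood microarray case–control set — with log-normal baselines around
  500, multiplicative log-normal noise at CV 0.1 (microarray intensities
  are approximately log-normal; the noise mean is bias-corrected so the
  planted ratio is the expected ratio), planted fold changes on named
  genes, one or two probes per gene, written in the curated-dataset SOFT
  dialect the loader consumes.
* **Pathways**: 50 random 30-gene sets plus one planted set drawing 80 %
  of its members from a designated query set.

What the generators do **not** emulate: real relevance-scoring algorithms,
probe-level artefacts (background, saturation, batch), correlated genes,
annotation hierarchies, or literature bias in interactomes. Passing tests
therefore demonstrate that the pipeline's computations are correct and
that planted structure of realistic magnitude is recovered — not that any
biological conclusion transfers to real data.

## Numerical choices and degenerate inputs

* Eigenvector centrality uses shifted power iteration on `A + I`
  (tolerance 1e-10 on the score vector, max 10,000 sweeps), which
  preserves the principal eigenvector while converging on bipartite
  components where plain iteration oscillates; scores are
  Euclidean-normalized per connected component, isolated nodes score 0,
  and non-convergence is an error, never a silent partial result.
* Rank ties everywhere use competition (minimum-rank) ranking.
* Duplicate edges keep the maximum confidence; self-loops are dropped;
  symbols are uppercased and stripped with no alias resolution.
* Empty inputs are errors where a statistic would be undefined (empty
  score map, all-unreachable target set, empty effective ORA query) and
  empty results where a set can be empty (empty edge file, empty
  post-filter symptom set, which is retained and logged).

## Problem sizes used in the tests

The test suite checks the centrality implementations against brute-force
oracles (matrix-power path counting, dense eigendecomposition) on random
connected graphs of up to 8 nodes, BH against a naive O(m²) oracle,
and ORA against exhaustive subset enumeration for universes up to 12
genes; planted-structure recovery uses 25–50 generator replicates at the
default spec and the permutation machinery runs at 500–10,000 samples.
These sizes were chosen so each property is checked across many random
instances while the whole suite stays convenient for routine development
runs.

## Known limitations

* The expression stage consumes curated matrices as-is: no normalization,
  background correction or moderated (shrinkage) statistics. For real
  microarray reanalysis a limma-style pipeline upstream is advisable.
* Proximity is single-target; multi-target drug-set proximity (closest
  distance over a target set) is out of scope.
* The two eigenvector variants approximate, but cannot claim to match,
  proprietary implementations; conclusions should rest on the consensus
  over all five indices, which is robust to monotone score differences.
* Symptom terms are opaque labels; ontology mapping between symptom
  vocabularies is editorial work the package does not attempt.
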