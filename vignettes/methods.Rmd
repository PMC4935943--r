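---
title: "Active sub-network identification and activity scoring: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Active sub-network identification and activity scoring: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nasfinder)
```

## The problem

Enrichment tools typically rank canonical pathways by statistical
significance alone. This package instead scores pathways *functionally*:
it asks which parts of the interactome actively carry information from a
module of differentially expressed genes (a DEG module) up to its nearest
regulator molecules — receptors by default — within a tissue-specific
background network, and ranks the resulting sub-networks by how strongly
the underlying expression changes activate them.

The pipeline has three logical stages:

1. **Regulator identification.** The DEG module is mapped onto an
   annotated reference interactome, optionally expanded with supplementary
   interactions that touch module genes and pruned to the tissue under
   study. A breadth-first search from the module genes finds the closest
   nodes of the chosen molecular role (minimal hop distance greater
   than 0), plus any differentially expressed regulators inside the module
   itself (distance 0).
2. **Minimal sub-network construction.** Edges are weighted by the common
   linkage index (below); for each regulator the highest-product path of
   at most nine edges to each module gene is retained, the retained paths
   are merged, and optionally every 1-neighbor of a path node is added.
3. **Contextual enrichment and ranking.** The module genes inside each
   sub-network form the target set *T*, which is compared against
   canonical pathway collections with the Sorensen-Dice index and an
   upper-tail hypergeometric p-value, scored with the network activity
   score (NAS), ranked, and consolidated by pathway name.

## Edge weights: the common linkage index

For adjacent genes $i$ and $j$ the common linkage index is

$$ CL_{ij} \;=\; \frac{D_{ij} + I_{ij}}{n_i + n_j} $$

with $D_{ij} = 1$ for a direct interaction, $I_{ij}$ the number of shared
neighbors, and $n_k$ the degree of node $k$: the proportion of shared
neighborhood relative to the two endpoints' total neighbor counts.
Non-adjacent pairs are assigned $CL = 0$ by definition, even when they
share neighbors. Two useful consequences shape the path search:

* on an edge, $CL > 0$ always (because $D_{ij} = 1$);
* $CL \le 1/2$ always, because each endpoint counts the other endpoint
  and every shared neighbor among its own neighbors, so
  $n_i + n_j \ge 2 + 2 I_{ij} > D_{ij} + I_{ij}$.

A Jaccard-style variant that divides by the size of the neighborhood
union instead is available via `weight_edges(net, method = "jaccard")`
for sensitivity analysis; all shipped defaults use the form above.

## Path retention

A path's score is the product of its edge CL values, and for each
(regulator, module gene) pair the single highest-scoring path of at most
nine edges is retained; genes at hop distance ten or more from every
regulator are reported as uncovered, since longer paths are rare and
dilute the signal (every retained edge multiplies the score by at most
1/2, so a 10-edge path scores at most $2^{-10}$).

The search is a dynamic program over hop counts (a hop-bounded
Bellman-Ford in product space). Because all weights are at most 1/2,
extending a walk strictly decreases its score: the optimum is always a
simple path, and non-simple walks can never tie with it. Ties between
distinct optimal paths are resolved deterministically — fewer edges
first, then the lexicographically smallest node sequence — so reruns are
byte-identical. The test suite checks the search against exhaustive
enumeration of all simple paths on hundreds of small random graphs.

An alternative reading of path retention — keeping one champion path per
length rather than a single global best per pair — is not implemented as
a default because the merged sub-network it produces is a superset of the
single-best construction and blurs the "minimal sub-network" notion; the
single best path per pair is used throughout.

## Enrichment and selection rules

For target set $T$ and reference pathway $R_i$:

* Sorensen-Dice similarity $S = 2|T \cap R_i| / (|T| + |R_i|)$, in
  $[0, 1]$, tolerant of small gene sets;
* hypergeometric upper tail $P(X \ge k)$ for the overlap $k$, with no
  multiple-testing correction — the p-values only rank candidates. The
  universe defaults to the number of distinct genes in the loaded
  collection (overridable); since only ranks matter, any consistent
  universe gives the same ordering. The effective universe is enlarged
  when necessary so the counts stay consistent for target sets containing
  genes outside the collection.

Per sub-network the reference set with the lowest p-value is flagged
`chosen` (ties: highest Dice, then name order). Per regulator, among its
candidate sub-networks, the one whose chosen annotation has the highest
Dice — the similarity score — is flagged `selected` (ties: greatest NAS).
"Highest similarity" could also be read as lowest p; `select_by = "logp"`
switches to that reading.

`annotate_subnetworks()` deliberately returns the **full**
(sub-network × reference set) table rather than only the chosen rows.
Dice and the hypergeometric p depend on set membership alone, so the
per-sub-network choice cannot see expression changes; the NAS ranking of
the full table is what lets an activity signal reorder pathways. The
`chosen`/`selected` flags preserve the selection rules for consumers that
want one record per regulator.

## The network activity score

$$ NAS = \frac{MNF \times CDR}{NGR} \in [0, 1] $$

where $CDR = |T \cap R|$ counts common molecules between the
network-restricted experimental genes and the reference signature,
$NGR = |R|$, and $MNF$ is the mean min-max-normalized fold change over
the $CDR$ genes. Fold changes $v$ (signed) are normalized as
$(v - v_{min}) / (v_{max} - v_{min})$ with the extremes taken over all
DEGs of the comparison, not per module, so NAS values are comparable
across modules of one contrast. This scaling favors positive fold
changes, i.e. pathway activation. Two deliberate conventions:

* $CDR$ intersects the reference set with $T$ (module genes inside the
  minimal network), keeping NAS consistent with the enrichment target;
  intersecting with the full DEG list instead is a one-line variant the
  caller can apply by passing the full module as target.
* the degenerate case $v_{max} = v_{min}$ maps every gene to 0.5
  (neutral activity) with a warning, rather than failing an entire run
  for a flat module.

Consolidated pathways (several regulators selecting the same canonical
pathway) carry the maximum NAS and minimum p among members — the "most
active instance" — with the per-member table always preserved.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `regulator_role` | `receptor` | molecular class at the upstream end of every path |
| `max_path_len` | 9 edges | longest retained path |
| `distance_cap` | 10 hops | module genes at or beyond it count as unreachable |
| `extend_1neighbor` | `TRUE` | add each path node's neighbors to the sub-network |
| `alpha` | 0.05 | significance cut for benchmark confusion counts |
| `universe` | collection size | hypergeometric universe |
| `regulator_scope` | `per_gene` | each module gene nominates its nearest regulators |

"Closest regulator" is interpreted per module gene (nominations are
unioned) rather than as a single module-global minimum: a global minimum
would ignore genes sitting in distant network regions, defeating the
purpose of connecting the regulator to *each* gene of the module.
`regulator_scope = "global"` provides the other reading.

## Tissue pruning

Gene classes follow the tissue-based human proteome maps: tissue enriched
(TE, at least 5-fold higher expression in one tissue than all others),
group enriched (GE, at least 5-fold higher in a small group of tissues),
tissue enhanced (TEn, 5-fold above the all-tissue mean). Pruning removes
all TE/GE genes of tissues other than the selected one unless the gene is
itself TE/GE/TEn in the selected tissue; TEn-elsewhere and unannotated
genes are kept. Genes group-enriched both in the selected tissue and
elsewhere are kept — their selected-tissue class protects them — and
reported via a message, since a GE annotation does not say which tissues
form the group.

## The synthetic-data generator

`synthetic_scenario()` fixes every parameter of a deterministic fixture:
a connected preferential-attachment interactome (default 80 nodes, 200
edges; heavy-tailed degrees as in curated signaling networks), roles
assigned by fraction (10% receptors), and a candidate-pathway design with
**exchangeable membership**: the DEG module is the union of
`n_pathways = 4` disjoint groups of `pathway_size = 6` genes, each group
forming one candidate pathway, the first of which is planted. Planted
genes draw their log fold change from $N(2.0, 0.15)$, decoys from
$N(0, 0.15)$ — an effect size and noise level typical of a strong
differentiation response on a log2 scale.

This exchangeability is the key design choice. Because the candidate
sets overlap the module symmetrically, membership statistics (Dice, p)
cannot distinguish them, and the NAS ranking of the full annotation
table is the *only* channel through which the planted effect can surface.
That yields two sharp, simultaneously testable properties:

* **recovery** — with a planted effect of 2.0 and noise 0.15, the planted
  pathway ranks first by NAS in at least 90% of 50 seeded runs (the
  planted genes' normalized fold changes sit near 1, the decoys' near 0);
* **no bias under the null** — with zero planted effect all candidate
  sets are statistically identical, so the planted one should win in
  about $1/m$ of runs; the suite checks this with an exact binomial test.

What the generator does **not** emulate: probe-level noise and
normalization artifacts, correlated co-expression structure inside
modules, overlap between real canonical pathways, incomplete and biased
interactome coverage, or hub-gene annotation bias. Passing the recovery
test therefore demonstrates the machinery is wired correctly and
sensitive to a planted activity signal — not that real tissue data will
yield comparable accuracy.

Problem sizes throughout the shipped tests (80-node networks, 4 × 6-gene
pathways, 50 seeds per property, 200 random graphs for the path-search
oracle, brute-force hypergeometric enumeration up to a universe of 15)
were chosen so each property is exercised well inside a desk-scale run.

## Benchmarking machinery

Given ranked pathway lists from several tools and a manual
positive/negative annotation per (dataset, pathway): within a scenario
window (top 10, top 100, or all results) a positive pathway with
p < 0.05 is a true positive, a negative below 0.05 a false positive, a
positive at or above 0.05 a false negative, a negative at or above it a
true negative. Labelled pathways outside the window — including pathways
a tool never reported — are treated as *not called* (positive → fn,
negative → tn); this is the only convention under which the top-k
scenarios differ from "all". Precision, recall, specificity and accuracy
follow their standard formulas, with 0/0 yielding an undefined marker
that is excluded from aggregation. Per measure (and dataset) each tool's
value is standardized across tools using the sample (n−1) standard
deviation — conventional for small tool counts — and a tool's cumulative
quality is its mean z-score; per-dataset standardization followed by
averaging is the default, pooled standardization is available via
`pooled = TRUE`. Zero-variance measures give z = 0 for every tool.

## Degenerate inputs and numerical conventions

* Duplicate edges are collapsed and self-loops dropped at load time;
  malformed lines fail fast with their line number.
* Unknown roles map to `other`; expansion never adds typed regulators.
* An empty sub-network (no module gene within nine edges) is allowed and
  reported downstream; a module whose every sub-network has an empty
  target set is an error ("no mappable gene").
* Path-score comparisons use exact floating-point equality plus the
  deterministic tie-break; scores are products of at most nine factors
  computed left-to-right, so equal paths compare equal.
* `hypergeom_pvalue(0, ...)` is exactly 1; inconsistent counts error.

## Known limitations

* The interactome is treated as strictly undirected; signaling direction
  (and sign) is ignored by design, trading mechanism fidelity for
  applicability without a directed background network.
* NAS favors up-regulation by construction; strongly down-regulated but
  biologically active modules score low unless the sign convention of
  the input fold changes is flipped.
* P-values are ranking devices only — they are not corrected for
  multiple testing and should not be reported as significance claims.
* Tissue pruning is all-or-nothing per gene; partial tissue specificity
  of individual interactions is not modelled.
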