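---
title: "Placing polyploid alleles on a diploid backbone: method and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Placing polyploid alleles on a diploid backbone: method and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MEst)
```

# The inference problem

An allopolyploid accession carries several homoeologous alleles per nuclear
locus, each potentially descended from a different diploid lineage. Given

* a **diploid backbone species tree** treated as known and fixed (in
  practice a multilocus coalescent estimate from the diploid accessions,
  rooted with outgroups), and
* per-locus **gene trees** containing the diploid individuals plus the
  cloned polyploid alleles,

the question is, for each allele separately: *on which backbone edge does
this allele's parental lineage attach?* The output is a distribution of
allele weights over backbone edges, summarized over bootstrap replicates.

The method deliberately conditions on the backbone rather than co-estimating
everything: the diploid tree is identifiable from diploid data alone, while
hybrid origins make a joint tree for all alleles ill-posed. Each allele is
also placed independently of its siblings, so alleles from one accession
are free to land on different parental edges — that freedom is the signal
of allopolyploidy.

# Internode distances (NJst)

Distances between the focal allele and the backbone taxa are **average
internode distances**: for taxa $i, j$, the number of internal nodes on
the path between a leaf of $i$ and a leaf of $j$ in the *unrooted* gene
tree, averaged as one flat mean over every (gene tree, cross pair of
individuals) term. Two leaves forming a cherry are one internode apart.
Under the multispecies coalescent this distance is statistically consistent
for species-tree topology, and — because it uses only topology — it is
immune to the rate asymmetries that plague branch-length distances when
subgenomes evolve at different speeds.

Conventions chosen here:

* A degree-2 root is suppressed before counting; a two-leaf tree yields
  count 0. Polytomies are allowed and their nodes count once regardless of
  degree.
* The mean is **flat** over all (tree, pair) terms, not a mean of per-tree
  means, so trees contributing more individual pairs weigh more. `N` in
  the returned object records the term count per pair.
* Counts are measured on each gene tree **exactly as given**. Leaves whose
  taxon is outside the requested taxon set contribute no pair terms but
  still sit on paths and inflate counts. Callers who want them gone must
  prune explicitly — which is precisely what the placement protocol does
  with non-focal polyploid alleles (see below). An earlier draft pruned
  implicitly and was rejected: it silently changed path lengths and hid
  the very distortion the explicit-pruning protocol exists to control.
* Pairs with no contributing term are `NA`. The default `strict` policy
  propagates this to a hard error during scoring ("undefined distance");
  `impute_max` fills with the matrix maximum and says so. Imputation is
  opt-in because a silently imputed allele-to-taxon distance can move a
  placement.

# Balanced minimum evolution and the Pauplin score

A candidate topology $T$ over taxa with distance matrix $D$ is scored with
the balanced tree-length estimate

$$\hat\ell(T) \;=\; \sum_{i<j} 2^{\,1-\tau_{ij}}\, D_{ij},$$

where $\tau_{ij}$ is the number of edges on the $i$–$j$ path in unrooted
$T$. Two exact identities anchor the implementation and are enforced by
property tests: on a binary unrooted tree the weights $2^{1-\tau_{ij}}$ sum
to 1 in every row, and if $D$ is the tree's own additive matrix then
$\hat\ell(T)$ equals the total branch length.

Numerical conventions: terms are accumulated over the upper triangle in
**sorted taxon-label order**, so the score is invariant to input ordering;
candidate scores within `tol = 1e-9` of the minimum are treated as exact
ties. The tolerance is far below any attainable score difference here
(distances are rational numbers with small denominators — averages of
integer internode counts — and weights are powers of two), so it only
absorbs floating-point summation noise and never manufactures ties.

`exhaustive_bme()` enumerates all $(2n-5)!!$ unrooted topologies by
stepwise addition and is capped at $n \le 8$ (10,395 topologies); it exists
as an oracle for testing the candidate scoring, not as a production search.

# The placement protocol

For each focal allele:

1. **Prune** every other polyploid-query allele from every gene tree. Their
   positions are unknown quantities; leaving them in would distort the
   internode counts between the focal allele and the backbone taxa.
2. Compute the internode matrix over backbone taxa plus the focal allele,
   the allele mapped to a reserved taxon name (`.query.`) via an override
   so it never collides with a species name. Outgroup taxa stay in the
   matrix and in the candidate trees: they carry real topological signal
   and anchor the root; the backbone edges they subtend are simply
   candidates like any other.
3. **Graft** a query leaf onto each of the $2n-3$ backbone edges and score
   each resulting topology with $\hat\ell$. The grafted trees and their
   Pauplin weight matrices depend only on the backbone, so
   `candidate_set()` precomputes them once and `run_bootstrap()` reuses
   them across alleles and replicates — this is the main performance lever.
4. The minimum-score edge(s) receive the allele's unit weight, split
   equally among exact ties. Ties are reported, not resolved: a symmetric
   signal (e.g. an allele equidistant from both children of a node) is a
   finding, not a nuisance.

## Edge identifiers

Edges are named by the sorted leaf labels below the edge's child node in
the rooted backbone, joined by `|` (`s04`, `s01|s02`, …). The two edges
incident to the root describe the same unrooted branch; they are merged
under one identifier — the side with the smaller leaf set (lexicographic
tie-break). Candidate grafts are matched to these identifiers by
bipartition, so rooted bookkeeping and unrooted scoring agree.

One consequence: when clade membership is evaluated (below), the merged
root edge belongs to the clade whose fingerprint names it. With an
outgroup present this matches the rooted intuition, because the retained
fingerprint is the ingroup side.

# Bootstrap summarization

`run_bootstrap()` repeats the protocol over $R$ replicate sets of gene
trees and asserts a **conservation invariant** in every replicate: edge
weights must sum exactly to the number of alleles placed. Summaries per
edge and per clade:

* **Support** — the percentage of replicates in which at least one allele
  assigns the edge (or any edge in the clade) positive weight. This
  "presence" rule is the default; `weight_ge_1` instead requires the
  summed fractional weight to reach a full allele, which discounts
  many-way ties.
* **Median** allele count over replicates.
* **90% interval** by trimming: drop the $\lfloor 0.05R \rfloor$ smallest
  and largest replicate counts and report the remaining extremes. For
  $R = 100$ these are the 6th and 95th order statistics. Trimming (rather
  than quantile interpolation) keeps endpoints at actually observed counts.

A **clade** is a named taxon set; an edge belongs to it when the edge's
fingerprint is a subset of the members, with equality meaning the stem
edge (included by default, excludable per clade). Per-accession summaries
rerun the same tally on the allele subset of each accession; because
counts are sums over alleles, accession counts add exactly to the pooled
counts in every replicate — a tested invariant.

Rendering follows display conventions: supports below 70% are hidden from
the annotated tree (kept in the table), `*` marks ≥ 90%, `**` ≥ 95%, and a
**clade bar** is emitted when a clade passes the display threshold but no
single member edge does — the situation where alleles wander within a
clade across replicates while the clade-level signal is firm.

# The simulator

`simulate_gene_trees()` draws gene trees from the multispecies coalescent
on a species tree with branch lengths in coalescent units: within each
branch, $k$ lineages merge after $\mathrm{Exp}\!\binom{k}{2}$ waiting
times, pairs chosen uniformly; survivors enter the parent branch. A
planted polyploid allele is a lineage that starts at time 0 and enters the
population of its **donor edge** at the allele's `attach_time`, from where
it coalesces like any other lineage. The planted edge is the truth against
which placements are scored.

`example_backbone()` is a fixed 15-taxon ultrametric tree — an outgroup
plus three clades of 5, 5, and 4 species — with internal branches of
0.5–1 coalescent units, short enough to generate substantial gene-tree
discordance. `branch_scale` multiplies all branches; at ×50 discordance is
negligible, giving a regime where recovery must be exact (a 10/10 planted
alleles, unique correct edge check in the test suite). These defaults are
study conditions, fixed before the validation experiments were run.

Known limits, accepted deliberately:

* **Replicates are independent MSC draws**, a stand-in for the
  nonparametric bootstrap over alignment columns. They capture coalescent
  variance but not mutational noise or gene-tree estimation error, so
  simulated supports are optimistic relative to real data.
* No mutation model: gene trees are observed directly. Polytomies,
  misrooting, and alignment artifacts of real pipelines are out of scope.
* One effective population size everywhere (time is in coalescent units),
  and the backbone is ultrametric.

# Problem sizes and runtime

Sizes used throughout the tests and the acceptance script are the
package's own choices, set to exercise the method while keeping the full
suite under ~90 s on one core:

* Pauplin identities: 200 random trees, 4–30 taxa.
* Exhaustive-search oracle: 5–6 taxa (105–945 topologies per instance).
* Consistency and recovery: 10–15 taxon trees, 6 loci, $R = 100$
  replicates, up to 20 planted alleles; clade-level recovery under the
  default (discordant) branch lengths stays near 0.98 across seeds.

Scaling: one allele placement costs one internode matrix
($O(\text{loci} \cdot m^2)$ for $m$ leaves) plus $2n-3$ scored candidates
($O(n^2)$ each with precomputed weights). A bootstrap run is linear in
$R \times$ alleles on top of that.
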