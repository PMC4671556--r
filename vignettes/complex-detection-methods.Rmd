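---
title: "Detecting protein complexes in dynamic PPI networks with bicnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting protein complexes in dynamic PPI networks with bicnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bicnet)
```

## The problem

Protein complexes are groups of physically interacting proteins that act as
one functional unit. Graph-clustering methods find them as dense regions of
a protein-protein interaction (PPI) network, but a static network ignores
that interactions are conditional: two proteins can only form a complex when
both are expressed. `bicnet` models this dynamic aspect by *biclustering* a
companion gene expression matrix - finding subsets of genes coherently
expressed over subsets of conditions - and then hunting for complexes only
inside each bicluster's slice of the PPI network. The pipeline has five
stages:

1. **bicluster** the expression matrix;
2. **extract** each bicluster's PPI subnetwork;
3. **prune** unreliable edges from each subnetwork;
4. **detect** candidate complexes in each pruned subnetwork;
5. **merge** the per-bicluster candidate sets and filter duplicates,

followed by evaluation against a reference catalogue.

## Coherence: the mean squared residue

A bicluster $BC(I, J)$ with gene rows $I$ and condition columns $J$ is
scored by its mean squared residue,

$$\mathrm{MSR}(BC) = \frac{1}{|I||J|}\sum_{i \in I}\sum_{j \in J}
  \left(a_{ij} - a_{iJ} - a_{Ij} + a_{IJ}\right)^2,$$

where $a_{iJ}$, $a_{Ij}$ and $a_{IJ}$ are the row, column and overall means
of the submatrix. MSR is zero exactly on *shifting patterns*
($a_{ij} = r_i + c_j$): rows that differ only by additive offsets. It does
not detect scaling patterns; that is a known limitation of the residue and
the reason the synthetic generator plants additive blocks only - scaling
blocks would penalise the residue-based algorithm for something it is not
designed to see. Missing cells are excluded from every mean and from the
residue sum, with the non-missing count replacing $|I||J|$; this avoids
imputation entirely.

## Cheng-Church search and its parameters

`cheng_church()` implements the classic greedy $\delta$-bicluster search in
four phases: *multiple node deletion* (while $\mathrm{MSR} > \delta$, drop
every row/column whose residue exceeds $\alpha \cdot \mathrm{MSR}$),
*single node deletion* (drop the single worst row or column until
$\mathrm{MSR} \le \delta$), *node addition* (re-admit rows and columns one
at a time, best residue first, whenever the bound still holds afterwards),
and *masking* (overwrite the found bicluster's cells with uniform random
values over the data range so the next round searches elsewhere). Two
defaults matter most:

* `delta = 0.5` - the MSR ceiling, in squared expression units. Data are
  used as read; users log-transform beforehand, so the meaning of
  $\delta$ tracks the data's own scale.
* `alpha = 1.2` - how aggressive mass deletion is; values near 1 delete
  faster and riskier.

Ten biclusters are returned by default. Because masked cells are random,
a bicluster found in a later round could violate the $\delta$ bound when
re-measured on the *original* values; a final single-node-deletion
refinement against the original matrix restores the bound there, so every
returned bicluster is a genuine $\delta$-bicluster of the data.

Two behaviours of this search are worth knowing. First, on a background of
unit-variance noise the deletion phases stop the moment the residue dips
under $\delta$, which with $\delta = 0.5$ happens while roughly half of a
random matrix is still present; the first bicluster is therefore a large,
weakly coherent block that *contains* most of a planted module rather than
the module alone. Our planted-recovery experiments show the planted
columns are typically recovered in full while a minority of planted rows
is lost to this stopping rule, an equilibrium that no $\delta$-respecting
addition rule can undo (re-adding the lost rows pushes the residue back
over $\delta$). Downstream stages are robust to this: complex detection
needs the bicluster to *select* the right neighbourhood of the network,
not to be cell-perfect. Second, ties everywhere resolve to the lowest
index, and the masking stream is seeded, so results are reproducible.

`kmeans_rows()` is the one-way baseline: Lloyd iterations under Pearson
distance $d = 1 - r$ over gene rows, `k = 10`, 100 iterations, 1
replicate. Pearson distance is undefined for flat rows; those are assigned
to the nearest centroid in Euclidean distance (with a warning). A cluster
that empties is reseeded with the row farthest from its centroid. Each
cluster becomes a bicluster spanning all conditions, which is exactly what
makes it a baseline: it cannot localise conditions.

## Subnetwork extraction and pruning

For each bicluster, `extract_bicluster_subnetwork()` keeps every PPI edge
with at least one endpoint among the bicluster's genes; the endpoints of
those edges are the subnetwork's nodes. Partners are pulled in as
endpoints only - partner-partner edges are deliberately excluded, so a
complex can only be detected where at least two of its members sit in the
bicluster itself.

PPI data are noisy, so each subnetwork is pruned before detection.
The default edge-reliability score is a closed-neighbourhood Jaccard
index: for an edge $(u, v)$,
$\mathrm{score} = |N^+(u) \cap N^+(v)| / |N^+(u) \cup N^+(v)|$ with
$N^+(x) = N(x) \cup \{x\}$. It is 1 exactly when the endpoints have
identical closed neighbourhoods (edges inside isolated cliques) and small
for bridges between otherwise unrelated hubs. This is a transparent
topological proxy for weighted-clustering-coefficient reliability
measures; it is *pluggable* (`register_edge_scorer()`), so a different
scorer can be swapped in without touching the pipeline. Pruning is a
single pass: all edges are scored once, edges scoring strictly below the
threshold (default `0.1`, kept when equal) are removed together, then
isolated nodes are dropped. Scores are not recomputed as edges disappear -
iterative re-scoring would cascade deletions well beyond what a one-shot
reliability filter intends.

## Detection

Two detectors are built in, behind the same registry contract
(`register_detector()`).

**MCODE-style** (`detect_mcode()`): each node with degree at least
`degree_cutoff = 2` is weighted by the highest core number $k$ of its
closed neighbourhood times the density of that $k$-core; others weigh 0.
Clusters grow outward from unassigned seeds in descending weight, admitting
neighbours whose weight is within `node_score_cutoff = 0.2` of the seed's,
up to `max_depth = 3` hops. Clusters smaller than 3 or lacking a 2-core are
discarded. The optional fluff/haircut post-stages are omitted - the four
parameters above fully describe the configured behaviour.

**CMC-style** (`detect_cmc()`): all maximal cliques with at least 3 nodes
(pivoting Bron-Kerbosch, affordable because per-bicluster subnetworks are
small), then repeated merging of the highest-overlap pair with overlap
$|A \cap B| / \min(|A|, |B|)$ *strictly above* `0.75` whenever the
inter-connectivity (realised fraction of $A\setminus B \times B$ edges)
reaches `0.5`. The original tool's edge-weight clique ranking is omitted;
candidates are processed in a canonical order (size descending, then
lexicographic), which makes the fixpoint deterministic and
input-order-invariant.

## Merging and evaluation

`merge_filter()` pools all per-bicluster complex sets, drops exact
duplicates, and merges any pair sharing more than 75% of the smaller
complex's members when one complex's members interact with (or are shared
with) at least 50% of the other's. The interaction test runs against the
*full unpruned* network, since merged complexes may span biclusters, and
either orientation of the 50% condition suffices - a symmetric reading
that keeps the result independent of pair order. Merging iterates to a
fixpoint in canonical order.

Evaluation uses five scores. Two complexes match when their overlap score
$\mathrm{OS}(A, B) = |A \cap B|^2 / (|A||B|)$ is at least `0.2`. With
$t_{ij}$ the overlap table between reference complex $i$ and predicted
complex $j$:

* $\mathrm{Sn} = \sum_i \max_j t_{ij} / \sum_i n_i$ (clustering-wise
  sensitivity),
* $\mathrm{PPV} = \sum_j \max_i t_{ij} / \sum_j \sum_i t_{ij}$, where the
  denominator counts only realised overlaps, so predictions disjoint from
  every reference complex affect neither sum (the 0/0 convention is ours;
  empty predictions score 0 everywhere),
* $\mathrm{Acc} = \sqrt{\mathrm{Sn} \cdot \mathrm{PPV}}$,
* MMR: the maximum-weight one-to-one matching between predictions and
  references, weighted by OS, divided by the number of reference
  complexes. The matching is solved exactly (weighted bipartite matching),
  never greedily, and matching edges are restricted to pairs at or above
  the same 0.2 OS cutoff used for matching. Published variants of MMR
  sometimes use 0.25; the cutoff is exposed as a parameter
  (`eval_params()`).

`paired_t_test()` compares score vectors from paired runs (same network,
same reference) two-sidedly; sidedness is a convention here, and the
degenerate cases are pinned: all-zero differences give $p = 1$, a constant
nonzero difference gives $p = 0$.

## The synthetic benchmark

`generate_coupled_dataset()` plants one shared truth in all three inputs:
disjoint complexes (default 10, sizes 6-12, over 300 proteins) are both
cliques-with-dropout in the network (within-complex edge probability
`p_in = 0.9` against background `p_out = 0.02`) and additive biclusters in
the 300 x 24 expression matrix (each spanning 12 of 24 conditions, cell
model $\mu_b + r_i + c_j + \varepsilon$, `noise_sd = 0.3`). The free
calibration choices are deliberate: $\mu_b \sim N(0, 1)$ and
$r_i, c_j \sim N(0, 0.5)$ keep planted blocks on the background's N(0, 1)
scale, because a co-expression module in log-scale data is distinguished
by *coherence*, not magnitude - a block that dwarfs the background would
be trivially separable by variance alone and simultaneously look like an
outlier set to a residue-based search. One complex maps to exactly one
bicluster, giving recovery an unambiguous ceiling.

What the generator does *not* emulate: scale-free degree distributions,
overlapping complexes, scaling-pattern biclusters, time-lagged expression
dynamics, and probe-to-ORF identifier mismatches (identifiers are assumed
to agree between matrix and network). Passing the planted-recovery tests
therefore demonstrates the pipeline's internal consistency on coupled
coherent structure, not performance on any real proteome.

Problem sizes used in the test suite and acceptance script (300 x 24
expression, 300-node networks, 5 seeds per summary) are the generator's
own default study conditions; they run in seconds while leaving each stage
nontrivial work.

## Numerical and degenerate-input choices

* Missing expression cells: excluded from all means/sums (never imputed).
* All tie-breaks are deterministic: lowest index for k-means and
  deletions, lexicographic protein IDs in detection, canonical
  (size-descending, lexicographic) ordering in merging.
* Empty results are legal everywhere and warn rather than fail: an empty
  subnetwork, an empty detection output, an empty merged pool, an empty
  prediction set (which scores 0 on every metric).
* Self-loops and duplicate edges are cleaned at parse time; identifiers
  are opaque, case-sensitive strings.
* Seeds flow from one `seed` argument through every stochastic stage
  (masking, k-means initialisation, generators), so identical
  configuration and seed reproduce bit-identical catalogues.

## Known limitations

* The residue is blind to scaling patterns (by design of the score).
* Cheng-Church with a generous $\delta$ returns supersets of planted
  modules (see above); precision at the bicluster level is not a goal of
  the pipeline, recall of the right network neighbourhoods is.
* The default edge scorer is a stand-in for weighted-clustering-based
  reliability measures, not a reimplementation of any of them; register a
  custom scorer for faithful comparisons.
* OPSM- and ISA-style biclusterers and external detectors (ClusterONE,
  ProRank and relatives) are supported only through the registries, not
  shipped.
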