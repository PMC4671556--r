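# bicnet

Protein complexes are cohesive groups of physically interacting proteins.
Detecting them from a protein–protein interaction (PPI) network alone treats
the network as static, although complexes only assemble when their members
are co-expressed. `bicnet` detects complexes in *dynamic* PPI networks: it
biclusters a companion gene expression matrix (subsets of genes coherent
over subsets of conditions), extracts each bicluster's slice of the PPI
network, prunes unreliable edges, runs a graph-clustering detector inside
each slice, and merges the per-bicluster candidates into one catalogue that
is scored against a reference set of complexes.

The package is aimed at systems-biology researchers who want a reproducible,
scriptable implementation of this expression-aware detection strategy, with
a planted-truth synthetic benchmark so every stage can be validated offline.

## The method in brief

* **Biclustering** — Cheng–Church greedy search bounded by the mean squared
  residue
  `MSR(BC) = (1/|I||J|) Σ (a_ij − a_iJ − a_Ij + a_IJ)²`
  (zero exactly on additive "shifting" patterns), with δ = 0.5, α = 1.2 and
  10 output biclusters by default; plus a Pearson-distance k-means row
  clustering as the one-way baseline.
* **Extraction** — all interactions touching a bicluster's genes, partners
  included as endpoints only.
* **Pruning** — closed-neighbourhood Jaccard edge reliability, single pass,
  edges below 0.1 removed (pluggable scorer registry).
* **Detection** — MCODE-style seeded core expansion (degree cutoff 2, node
  score cutoff 0.2, 2-core filter, depth 3) and CMC-style maximal-clique
  merging (overlap > 0.75, inter-connectivity ≥ 0.5).
* **Merge + filter** — pool per-bicluster sets, drop duplicates, merge pairs
  sharing > 75 % of the smaller complex when one side interacts with ≥ 50 %
  of the other.
* **Evaluation** — matched complexes at overlap score OS ≥ 0.2, with
  `OS(A,B) = |A∩B|²/(|A||B|)`, clustering-wise Sn and PPV, geometric
  accuracy `Acc = sqrt(Sn·PPV)`, and the maximum matching ratio (exact
  maximum-weight bipartite matching), plus a paired t-test for
  dynamic-vs-static comparisons.

## Worked example

```r
library(bicnet)

# a coupled synthetic study: 300 proteins, 10 planted complexes (sizes
# 6-12) present both as near-cliques in the PPI network and as additive
# biclusters in a 300 x 24 expression matrix
d <- generate_coupled_dataset(synth_params(seed = 4))

res <- run_pipeline(pipeline_config(seed = 4),
                    expression = d$expression,
                    network    = d$network,
                    reference  = d$reference)
res$report
```

```
Complex evaluation (OS >= 0.20)
  matched reference complexes: 10 / 10
  detected complexes:          37
  Sn 0.9551 | PPV 0.6695 | Acc 0.7996 | MMR 0.6359
```

All 10 planted complexes are recovered (matched at OS ≥ 0.2). The detector
also reports additional candidates from the background (37 detected), which
lowers PPV/MMR without affecting the matched count; on the noiseless
variant (`synth_params(p_in = 1, p_out = 0, noise_sd = 0)`) the pipeline
returns exactly the 10 planted complexes with MMR = 1.0. `tidy()`,
`glance()` and `autoplot()` work on the report, and
`run_static_baseline()` produces the same report format without using
expression data, for paired comparisons via `paired_t_test()`.

A thin command-line front end ships in `inst/cli/bicnet`
(`simulate`, `bicluster`, `extract`, `prune`, `detect`, `merge`,
`evaluate`, `compare`, `run`, `baseline`).

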