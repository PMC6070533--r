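# s2b — double specific betweenness for network module overlaps

Diseases with similar phenotypes tend to have overlapping *modules* in
the protein interaction network, and the proteins in that overlap are
prime candidates for genes involved in both diseases. But module
knowledge is incomplete: for each disease only a *seed* set of known
disease genes is available. **s2b** predicts overlap membership from two
seed sets with the double specific betweenness score

    S2B(k) = [ Σ_{i∈a} Σ_{j∈b, j≠k} sp(k,i,j) · t(i,j) ] /
             [ Σ_{i∈a} Σ_{j∈b, j≠k} t(i,j) ]

the fraction of retained shortest paths linking one seed set to the
other that pass through node *k*. Here `sp(k,i,j) = 1` iff
`d(i,j) = d(i,k) + d(k,j)` (node *k* lies on a shortest *i*–*j* path)
and `t(i,j) = 1` iff `d(i,j)` is at most the network's average shortest
path length, which drops seed pairs too far apart to be informative.
Seeds present in both lists are discarded before scoring. A score
threshold is taken at the elbow of the score-vs-quantile L-curve, and
two randomization tests filter out generically central nodes: **SS1**
compares against random seed sets, **SS2** against degree-preserving
rewired networks (200 randomizations each, candidates need both > 0.90).

The package is written for computational biologists working with
interactome-scale networks (tested to ~12k nodes / ~90k edges class
sizes), but nothing in it is specific to proteins — any two node sets on
any undirected graph work.

Besides the score itself the package ships:

* **Artificial-module benchmark** — a scale-free surrogate network
  generator plus three module models with controlled pairwise overlap
  (`shell` breadth-first rings, `conn` connectivity-significance growth,
  `rwr` random-walk-with-restart ranking), seed subsampling with
  optional contamination, and edge-rewiring perturbations.
* **DIAMOnD baseline** — the iterative hypergeometric module-expansion
  algorithm, run from each seed set separately and intersected, for
  matched-precision comparisons.
* **Candidate subnetwork analysis** — maximal cliques (≥ 4 nodes) of the
  candidate-induced subgraph and clustering of candidates by
  co-occurrence on the retained shortest paths, exportable as annotated
  GraphML.

## Worked example

Simulate a ground-truth module pair on a small scale-free network, score
with half of each module as seeds, and compare against DIAMOnD:

```r
library(s2b)

net <- make_base_network(1200, 8, rng_seed = 1)
tr  <- make_module_pair(net, "shell", overlap_bounds = c(10, 45),
                        size_range = c(50, 100), rng_seed = 2)
tr
#> module pair (shell): |A| = 55, |B| = 79, overlap = 21

rs  <- sample_seeds(tr, fraction = 0.5, rng_seed = 3)
res <- s2b_run(net, rs$raw_a, rs$raw_b, n_random = 200, rng_seed = 4)
res
#> S2B result: 1196 scored nodes, threshold 0.0227 -> 10 candidate(s)

head(as.data.frame(res), 5)
#>    node       s2b  ss1   ss2 rank is_candidate is_seed_a is_seed_b
#>  n00005 0.8037383 1.00 1.000    1         TRUE     FALSE     FALSE
#>  n00001 0.2857143 1.00 1.000    2         TRUE      TRUE     FALSE
#>  n00006 0.1495327 0.35 0.340    3        FALSE     FALSE     FALSE
#>  n00003 0.1174900 0.44 0.065    4        FALSE      TRUE     FALSE
#>  n00004 0.1014686 0.30 0.040    5        FALSE      TRUE     FALSE
```

The per-node table carries the score, both specificity values, the rank
(shared seeds excluded) and candidate/seed flags. Note how the nodes at
ranks 3–5 score high on raw S2B but fail the specificity filters — they
are central in the network rather than specific to these two seed sets.
The top ranked node, `n00005`, is a true overlap member that was never
given as a seed.

```r
dia <- diamond_overlap_candidates(net, rs$raw_a, rs$raw_b, n_iter = 100)
matched_precision(rank_candidates(res$score, res$seed_pair$shared_discarded),
                  dia, tr)
#> $precision_s2b      0.235
#> $precision_diamond  0.059
#> $n_matched          17
```

At equal candidate-list length, S2B places four times more true overlap
members than the intersect-two-DIAMOnD-runs baseline on this pair.

Real data enter through plain files: `read_edge_list()` (two-column TSV
or SIF) and `read_node_list()` (one identifier per line, `#` comments).
A command-line wrapper is installed at
`system.file("cli", "s2b-cli.R", package = "s2b")`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","s2b-cli.R",package="s2b"))')" \
    run --network net.tsv --seeds-a als.txt --seeds-b sma.txt \
    --nrand 200 --seed 1 --out results.tsv
```

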