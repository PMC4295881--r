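# omicfuse

Infer one global association network from several blocks of omics and
clinical measurements on the same subjects, then analyze its community
structure with permutation-calibrated statistics.

The package targets the common multi-omics setting of cohort studies: a
bio-clinical panel, a lipidomics/fatty-acid panel and a targeted
gene-expression panel measured on the same ~100–200 individuals, with block
sizes spanning an order of magnitude. Estimating all associations with one
method would let the largest block dominate; `omicfuse` instead combines

1. a **sparse Gaussian graphical model** (graphical lasso) inside each
   block — edges are nonzero partial correlations
   `rho_jk = -Theta_jk / sqrt(Theta_jj Theta_kk)` of the penalized precision
   matrix `Theta` maximizing
   `log det(Theta) - tr(S Theta) - lambda * sum_{j != k} |Theta_jk|`;
2. **ridge-regularized canonical correlation analysis** between each pair
   of blocks — cross-block pairs scored by
   `M_jk = sum_d cor(x_j, Z_d) cor(y_k, Z_d)` through the averaged canonical
   variates `Z_d`, well-posed even when variables outnumber subjects;
3. an **edge-budget merge** — every component network is calibrated to carry
   exactly as many edges as it has nodes (or, for a block pair, the summed
   node count) before the union is taken, so all blocks contribute
   proportionate structure.

The merged graph is clustered by **spin-glass modularity maximization**
(simulated annealing, resolution `gamma`), and two degree-preserving
permutation tests calibrate the findings: the clustering is significant if
its modularity exceeds the maximum over 100 rewired replicates, and a node
is significantly central within its cluster if its betweenness exceeds the
replicate maxima of the rewired cluster subgraph more often than chance
allows. Hubs (per-cluster maximal-degree nodes), Fisher-exact cluster
overlap tests and gene-set over-representation complete the analysis. A
synthetic multi-block cohort generator with exact ground truth (sparse
precisions, low-rank cross-block coupling, ±2 kg weight-change groups)
supports validation end to end.

## Worked example

```r
library(omicfuse)

cfg <- run_config(sim = simulation_config(seed = 421), B = 100, seed = 421)
res <- run_pipeline(cfg, out_dir = "run1")
```

```
[data] seed=421 elapsed=0.2s 3 blocks
[preprocess] seed=421 elapsed=0.4s 0 vars transformed
[intra] seed=421 elapsed=0.7s bioclinical : 15 edges
[intra] seed=421 elapsed=0.8s fatty_acid : 30 edges
[intra] seed=421 elapsed=1.4s mrna : 221 edges
[inter] seed=421 elapsed=1.4s bioclinical-fatty_acid : 45 edges, lam=(0.1, 0.1)
[inter] seed=421 elapsed=1.5s bioclinical-mrna : 236 edges, lam=(0.1, 0.1)
[inter] seed=421 elapsed=1.5s fatty_acid-mrna : 251 edges, lam=(0.1, 0.1)
[merge] seed=421 elapsed=1.5s 266 nodes, 798 edges
[cluster] seed=421 elapsed=3.5s 85 clusters, Q = 0.548 (significant)
[betweenness] seed=421 elapsed=4.0s 0 significant nodes
[done] seed=421 elapsed=8.4s outputs in run1
```

Each intra-block network carries exactly its node count in edges (15, 30,
221) and each bipartite network the summed node count (45, 236, 251); the
merged graph has 266 nodes and 798 edges. The node-count budget makes
density fall with block size:

```r
degree_table(res$global)$block_density
#>         block   p edges_within     density
#> 1 bioclinical  15           15 0.142857143
#> 2  fatty_acid  30           30 0.068965517
#> 3        mrna 221          221 0.009090909
```

The clustering (Q = 0.548) beats all 100 degree-preserving null replicates
(p = 1/101 ≈ 0.0099), so the modular structure is not explained by the
degree sequence alone. The three largest clusters mix blocks, as a fused
network should — e.g. a 59-node cluster whose hub is a bio-clinical
variable:

```r
res$hubs[c("cluster_1", "cluster_3", "cluster_2")]
#> $cluster_1
#> [1] "bioclinical_004"
#> $cluster_3
#> [1] "bioclinical_001"
#> $cluster_2
#> [1] "fatty_acid_002" "fatty_acid_014"
```

No node reaches betweenness significance here — on this synthetic cohort no
node is more central than its degree forces, which is exactly what the
degree-preserving null is designed to detect. The run directory holds every
artifact (blocks, component networks, merged GraphML/GEXF for force-based
layout in e.g. Gephi, partition, reports, JSON manifest with checksums);
rerunning with the same config and seed reproduces the checksums.

See the vignette (`vignettes/multiomics-networks.Rmd`) for the model,
the synthetic-cohort design, and all numerical choices.

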