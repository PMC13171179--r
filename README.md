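# morphograph

Unsupervised detection of **morphotypes** — discrete morphological forms —
from specimen-by-trait tables, for systematists working on cryptic or
morphologically conservative lineages where linear multivariate statistics
and visual inspection under-resolve phenotypic structure.

Instead of treating specimens as independent points, `morphograph` models the
morphospace as a network:

1. **Size correction.** Morphometric traits become log shape ratios
   `ln(trait/TL)` (total length kept as `ln(TL)`), scale counts become
   `ln(x + 1)`, and every column is standardised to unit variance.
2. **Morphospace graph.** Each specimen is linked to its *k* nearest
   neighbours (Euclidean, default *k* = 4, selectable by a
   modularity-stability sweep over *k* = 3..10) and the adjacency is
   symmetrised by the element-wise maximum with its transpose.
3. **Graph autoencoder.** A three-layer graph convolutional encoder
   (128, 64, *d* units; ELU, layer normalisation, 15% dropout) embeds the
   specimens; the inner-product decoder `Â = σ(ZZᵀ)` reconstructs edge
   probabilities. Training minimises a class-weighted binary cross-entropy
   (full-batch Adam, 1000 epochs, learning rate 0.008 halved every 250
   epochs). The latent dimensionality is chosen from four structural
   metrics: edge AUC, trustworthiness *T(k)*, distance correlation, and the
   final loss.
4. **Community detection.** The reconstructed adjacency is thresholded at
   the valley of its probability distribution (or any fixed `tau`) and
   partitioned by Louvain modularity maximisation,

   Q = (1/2m) Σᵢⱼ [Aᵢⱼ − kᵢkⱼ/2m] δ(cᵢ, cⱼ),

   with *Q* ≥ 0.3 read as non-random structure and NMI quantifying agreement
   with the current taxonomy.
5. **Diagnosis and controls.** A 100-tree random forest plus TreeSHAP ranks
   the traits defining each morphotype; a PCA + k-means + silhouette
   baseline provides the linear comparison; a stratified trait-subset
   stability analysis checks that the community count is not an artifact of
   the chosen characters. A planted-morphotype simulator generates
   ground-truthed data with realistic allometric and count structure.

## Worked example

```r
library(morphograph)

sim <- simulate_morphotypes(sim_config(n_specimens = 120, n_groups = 4,
                                       n_morphometric = 6, n_meristic = 4,
                                       separation = 3, seed = 42))
res <- run_pipeline(sim, k = 4, d = 3, gae = list(epochs = 300), seed = 7)
print(res)
#> morphograph pipeline: N = 120 | k = 4 | d = 3 | 4 morphotypes, Q = 0.7500 | NMI vs taxonomy = 0.0175

nmi(res$partition$labels, sim$planted_labels)
#> [1] 1
head(res$diagnosis$rankings[["1"]], 3)
#>   rank trait mean_abs_shap
#> 1    1   IOS    0.12211929
#> 2    2   MID    0.07135650
#> 3    3    SC    0.04239455
```

The pipeline recovers all four planted groups exactly (NMI = 1 against the
planted labels) with strong modularity (Q = 0.75, far above the 0.3
non-randomness bound), while agreement with the simulated species column is
near zero (0.0175) — by construction, since this fixture shuffles species
labels to decouple taxonomy from morphology. The diagnosis table lists, for
cluster 1, the traits that most drive its separation (here the
intersupraocular, mid-dorsal and subcaudal scale counts); only the rank
order within a cluster is meaningful, not magnitudes across clusters. The
PCA/k-means baseline on the same data retains 7 components and also finds
4 clusters (Q = 0.749) — at this separation the structure is linear enough
for both routes; the graph route is designed for the regimes where it is
not.

Individual stages are available as plain functions (`preprocess_traits()`,
`knn_graph()`, `gae_train()`, `reconstruct_graph()`, `louvain_cluster()`,
`validate_partition()`, `diagnose_clusters()`, `baseline_report()`,
`stability_run()`), and a thin command-line wrapper lives at
`inst/cli/morphograph.R` (`simulate` and `run` subcommands, YAML trait
declaration).

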