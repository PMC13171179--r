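---
title: "Detecting morphotypes in morphospace graphs: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting morphotypes in morphospace graphs: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Morphologically conservative lineages hide their structure: linear
multivariate statistics and visual inspection can miss discrete phenotypic
forms (morphotypes) whose differences are distributed non-linearly across
many correlated traits. `morphograph` treats the problem relationally. Instead
of modelling specimens as independent points, it builds a specimen similarity
graph, learns a low-dimensional embedding that preserves the graph's
connectivity, and reads morphotypes off as communities of the reconstructed
graph. No taxonomic labels enter the analysis; the current classification is
used only afterwards, to quantify how well it agrees with the detected
structure.

## The pipeline

### Size correction

Raw linear measurements are dominated by body size (ontogeny: juveniles and
adults are pooled, with no sex distinction). Each morphometric trait $t$
other than total length becomes a log shape ratio $\ln(t/\mathrm{TL})$;
meristic counts $x$ become $\ln(x + 1)$ to homogenise variances; every column
is then standardised to zero mean and unit sample variance (denominator
$N-1$). Total length itself is kept as $\ln(\mathrm{TL})$: the ratio
$\ln(\mathrm{TL}/\mathrm{TL})$ is identically zero and cannot be
standardised, yet a size axis is a legitimate morphological predictor, so
retaining it as a log-transformed feature preserves that axis while every
other morphometric column is size-corrected. Missing values are a hard error
by default; the corrected matrix must be complete.

### The morphospace graph

Each specimen is connected to its $k$ nearest neighbours by Euclidean
distance on the standardised matrix (Euclidean is the natural metric after
z-scaling; neighbour ties break to the lower row index so the construction is
deterministic). The directed adjacency is symmetrised by the element-wise
maximum with its transpose. The default $k = 4$ follows a sweep over
$k = 3, \dots, 10$ scored by Louvain modularity: `select_k()` picks the $k$
maximising mean modularity among the values whose modularity-SD and
cluster-count-SD ranks both sit in the best tertile, falling back to the
modularity maximum, with final ties to the smallest $k$. The randomness
behind those SDs is the Louvain node order, replicated 20 times per $k$ by
default; the replication source is a package choice, as is the tertile
arbitration — only the criteria themselves (high modularity, low spread of
both quantities) are fixed by the method.

### The graph autoencoder

The encoder is a three-layer graph convolutional network (128, 64, $d$
units) using the symmetric-normalised propagation operator with self-loops,
$\tilde D^{-1/2}(A + I)\tilde D^{-1/2}$. Hidden layers apply, in order:
propagation, linear map, layer normalisation (per node over features,
$\varepsilon = 10^{-5}$, learned gain and bias), ELU ($\alpha = 1$), and 15%
dropout; the final layer is linear after propagation, leaving the latent
space unconstrained. The decoder is the inner product
$\hat A = \sigma(Z Z^{\top})$, so reconstructed entries are edge
probabilities.

Training minimises a weighted binary cross-entropy over all ordered
off-diagonal pairs (each undirected pair counted twice, which cancels in the
mean; the diagonal is excluded because the target adjacency has none):

$$
L = -\frac{1}{N(N-1)} \sum_{i \ne j}
\left[ w^{+} A_{ij} \log \hat A_{ij} + (1 - A_{ij}) \log (1 - \hat A_{ij}) \right],
$$

with $w^{+}$ defaulting to the non-edge/edge ratio, compensating the extreme
sparsity of k-NN graphs. Optimisation is full-batch Adam
($\beta = (0.9, 0.999)$, $\varepsilon = 10^{-8}$) for 1000 epochs, learning
rate $0.008 \cdot 0.5^{\lfloor \mathrm{epoch}/250 \rfloor}$. Weights are
Glorot-uniform initialised from a seeded stream; GCN layers carry no bias
(the layer-norm affine terms take that role). Probabilities are clamped to
$[10^{-7}, 1 - 10^{-7}]$ inside the logs. Runs are bitwise reproducible given
the seed. Everything in this paragraph that the method itself does not fix
(initialisation, Adam moments, loss support, the exact $w^{+}$) is a
documented package default, exposed through `gae_config()`.

### Choosing the latent dimensionality

`evaluate_dims()` trains one model per candidate $d$ and records four
metrics: edge-reconstruction AUC (global fidelity; rank/Mann–Whitney tie
convention), trustworthiness $T(k)$ with the graph's $k$ (local neighbourhood
retention), the Pearson correlation between input-space and latent-space
pairwise distances, and the final loss. The distance correlation is
deliberately the Mantel-style Pearson-on-distances, which can be negative —
an embedding can preserve connectivity while rearranging global distances;
the formal non-negative statistic is available via
`distance_correlation(..., method = "szekely")`. `select_dim()` returns the
smallest $d$ with $T(k) \ge 0.9$ (the conventional high-fidelity level)
whose marginal loss improvement over $d - 1$ is below 1%; both constants are
arguments, and the smallest evaluated $d$ qualifies on fidelity alone since
it has no predecessor. If nothing qualifies, the trustworthiness argmax is
returned with a warning. The metrics are computed in-sample: the model's job
here is faithful compression of the observed graph, not generalisation to
held-out edges.

### From probabilities to morphotypes

The decoder output is converted to an undirected weighted graph by zeroing
the diagonal and removing entries below a threshold $\tau$; surviving
probabilities become edge weights (a binary mode exists). The default
$\tau$ = `"auto"` places the cut at the valley between the two modes of the
off-diagonal probability distribution, found by Otsu's between-class-variance
rule. A fixed $\tau = 0.5$ is tempting but wrong under a weighted loss: the
positive-class weight recalibrates the decoder's probability scale, mapping
an unweighted edge posterior of $1/2$ to roughly $w^{+}/(w^{+}+1)$ (about
0.99 at the default weight), so 0.5 on the trained scale corresponds to an
edge posterior near 1%. Empirically, on planted 12-group data the trained
reconstruction holds within-group entries near saturation while between-group
entries crowd just below and above 0.5 — a consequence of the inner-product
geometry: at most $d + 1$ directions can be pairwise obtuse in $d$
dimensions, so with more groups than that, many between-group inner products
are forced towards zero, i.e. probabilities towards 0.5. A 0.5 cut then
floods the graph with between-group edges and Louvain merges groups, whereas
the distribution valley separates the two masses cleanly. Any numeric $\tau$
can still be forced.

Louvain community detection then maximises Newman–Girvan modularity

$$
Q = \frac{1}{2m} \sum_{i,j} \left[ A_{ij} - \frac{k_i k_j}{2m} \right]
\delta(c_i, c_j)
$$

(weighted generalisation: strengths and total weight) by the usual two
phases — greedy single-node moves in a seeded shuffled order, then
aggregation of communities into super-nodes whose self-loops carry internal
weight — repeated until no move improves $Q$ by more than $10^{-12}$. Ties
keep the current community, else the lowest community id; a `best_of`
argument reruns with derived seeds and keeps the highest-$Q$ partition. The
resolution parameter is fixed at 1.

Partitions are validated on two axes: structural ($Q \ge 0.3$, the
conventional bound for non-random community structure) and taxonomic (NMI
between communities and species labels, normalised by the arithmetic mean of
the entropies; a geometric-mean variant is available since the choice of
normalisation is a convention).

### Diagnosis, baseline, stability

To characterise each morphotype, a 100-tree probability random forest is
fitted with the detected clusters as the response and the standardised traits
as predictors, and decomposed with path-dependent TreeSHAP (implemented in
compiled code over the forest's trees; training-coverage weights define the
conditional expectations). Trait importance for a cluster is the mean
absolute SHAP contribution across all specimens (a members-only variant is a
flag), and only the within-cluster rank order is reported: absolute
magnitudes are partitioned across the classes of the multiclass problem and
are not comparable between clusters.

The linear baseline runs PCA retaining 95% of the variance, k-means over
$k = 2,\dots,15$ with 10 seeded k-means++ starts per $k$, silhouette model
selection (singletons score 0), and scores the chosen labels by modularity on
the symmetrised k-NN(4) graph of the retained PCA coordinates — no Louvain on
the baseline side — plus NMI against taxonomy. The silhouette is computed in
the retained-component space.

The stability analysis perturbs variables, not specimens: for each subset
size it draws up to 1000 distinct trait subsets (exhaustive when fewer
exist), re-runs preprocessing, graph construction and Louvain per subset
(mode `"graph"`), and in parallel re-runs the PCA/k-means scan; mode
`"full_gae"` additionally retrains the autoencoder per subset at a reduced
default of 50 subsets, since a thousand retrainings per size buys little
over the graph-level answer at disproportionate cost. The verdict applies
three explicit criteria: the modal community count at the largest size equals
the full-data solution; the count SD does not increase with size (Spearman
trend $\le 0$); and the fraction of subsets with $Q \ge 0.3$ stays at or
above 0.9 at every size. The 0.9 and the trend test operationalise "low SD"
and "consistently high", which the method leaves qualitative.

## The simulator

`simulate_morphotypes()` generates the data the pipeline assumes, with
planted ground truth. Total length is log-normal (default
$\mu_{\log} = 6$, $\sigma_{\log} = 0.35$ — a few hundred mm with juveniles
and adults pooled); each other morphometric trait follows a group-specific
allometry $t = a_{g} \cdot \mathrm{TL}^{b_{g}} e^{\varepsilon}$ with
$\varepsilon \sim N(0, 0.15^2)$ on the log scale (isometric $b = 1$ by
default; group-specific exponents via `allometry_b`); meristic traits are
Poisson with group-specific means (negative binomial behind a flag). Group
separation is calibrated on the corrected, standardised scale — the space
the pipeline actually operates in — as the RMS per-trait gap between group
means in within-group-SD units: per-trait offsets are drawn
$N(0, (\mathrm{sep} \cdot s_t)^2/2)$, and meristic means are back-transformed
through the delta-method SD of $\log(1 + \mathrm{Poisson})$. A species-label
scheme (`aligned`, `shuffled`, `split`) controls how the taxonomy column
relates to the planted groups, to exercise the NMI machinery.
`default_porthidium_like()` fixes the study-shaped conditions used by the
end-to-end checks: 484 specimens, 13 morphometric + 8 meristic traits, 12
equal groups at separation 3.

What the simulator does not emulate: real trait covariance structure,
unequal group sizes, measurement error, ontogenetic or sexual-dimorphism
signal, and the diffuse, manifold-like geometry of real morphospaces — its
groups are compact Gaussian clouds. Passing the planted-recovery checks
therefore demonstrates that the machinery is correct and sensitive at
realistic dimensions, not that any particular empirical dataset harbours 12
morphotypes.

## Numerical choices and degenerate inputs

Zero-variance trait columns are fatal by default (droppable by flag);
duplicate specimens are allowed (zero distances are valid); an edgeless
reconstructed graph is fatal; AUC is undefined without both classes;
trustworthiness requires $k < N/2$ (formula validity); NMI returns 0 when
either labeling is constant; silhouette singletons score 0; Louvain's
improvement tolerance is $10^{-12}$; seeds derive per-stage sub-seeds below
$2^{31}$ so every stage is individually reproducible.

## Problem sizes used in the checks

The shipped test suite runs the full pipeline at the study shape
(N = 484, 21 traits) across five seeds and a separation ladder
(0.5, 1, 2, 4) for the recovery and monotonicity checks, and uses smaller
instances (N ≤ 120, exhaustive oracles at N ≤ 30, exhaustive partition
search at N ≤ 8) everywhere a brute-force reference is feasible. These sizes
were chosen so the complete suite stays comfortably within a desk-scale run
while still exercising the pipeline at the dimensions the method targets.

## Known limitations

The framework detects communities in a graph built from whichever traits the
investigator measured; it cannot see structure outside that trait space, and
it cannot distinguish genetic divergence from plasticity. The inner-product
decoder bounds how many mutually repelling tight clusters a $d$-dimensional
latent space can represent (at most $d + 1$ pairwise-obtuse directions), so
very fragmented structure may need a larger $d$ than the fidelity metrics
alone suggest. Louvain is a greedy heuristic with a resolution limit; tiny
communities can be absorbed. All fidelity metrics are in-sample by design.
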