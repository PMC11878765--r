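# scTripletClust

Clustering for single-cell RNA-seq count matrices that learns cell
embeddings with a multi-head **graph-attentional autoencoder** on a
denoised KNN cell graph, sharpens them with a **triplet loss whose
positive pairs come from high-order graph neighbours**, and fuses the
result with **self-optimizing (deep embedded) clustering**.  It is aimed
at analysts who have a genes × cells count matrix, know (or assume) the
number of cell types `c`, and want cluster labels plus a
clustering-friendly embedding.

## The method in brief

Given raw counts, the pipeline:

1. **QC + normalization** — removes cells whose library size falls
   outside `[Q25 − IQR, Q75 + IQR]` and genes expressed in ≤ 3 cells;
   scales each cell to the median library size, `log1p`-transforms, and
   reduces to `D = 512` features (PCA, or the most variable genes for
   small data sets), z-scored per feature → input `Y (D × n)`.
2. **Cell graph** — Pearson similarities `S`, network-enhancement
   diffusion to suppress noisy edges, thresholding
   (`E_ij = S_ij` if `Ê_ij ≥ t`), and a union-symmetrized KNN graph with
   `K = round(n / (10c))` clipped to `[6, 20]`.
3. **High-order masks** — pairs at shortest-path distance `k ≤ r` become
   positives with weight `ω_k` (defaults `ω = (1, 0.5)`, `r = 2`); all
   farther pairs are negatives `B = 1 − C_r`.
4. **Autoencoder** — 4-head attentional layers `D → 256 → 64 → 256 → D`
   with Gaussian-kernel attention scores
   `e_ij = exp(−(a·Wh_i − a·Wh_j)²)`; reconstruction loss
   `L_r = Σ|Y − Y′|`.
5. **Joint objective** — with embedding similarities `S′ = cor(Z)`,
   triplet loss `max{s⁻ − s⁺ + margin, 0}` (margin 0.2); DEC soft
   assignments `Q` (Student's-t), sharpened target `P`, clustering loss
   `KL(P‖Q)`; total `L = L_r + αL_c + βL_triplet`, `α = β = 1`.
   Training: Adam, 2e-4 pretraining / 5e-4 joint, centers and `P`
   refreshed every 10 epochs, silhouette-guided early stopping, labels
   from the best-silhouette checkpoint.

The autoencoder, its analytic gradients (validated against finite
differences in the tests), and an Adam optimizer are implemented
directly in R.

## Worked example

```r
library(scTripletClust)

sim <- standard_fixture()                    # 2000 genes x 300 cells, 3 types
dim(sim$counts)
#> [1] 2000  300

res <- run_pipeline(
  sim$counts, n_clusters = 3,
  config = list(epochs_pretrain = 30L, epochs_joint = 150L, seed = 1L),
  truth  = setNames(sim$labels, colnames(sim$counts))
)

table(res$labels)
#>  1  2  3
#> 92 98 90

round(c(ARI = res$ari, NMI = res$nmi, silhouette = res$silhouette_best), 3)
#>        ARI        NMI silhouette
#>      1.000      1.000      0.963
```

280 of the 300 simulated cells survive QC and are partitioned into three
balanced clusters that match the planted labels exactly (ARI and NMI of
1); the best-checkpoint silhouette of 0.96 reflects tight, well-separated
embedding clusters.  `res$Z` holds the 64-dimensional embedding,
`res$history` the per-epoch losses and silhouettes.  Ablations are one
flag away: `mode = "kmeans_only"` (no joint training) and
`mode = "first_order_only"` (positives from direct neighbours only).

A command-line front end with `run`, `simulate`, `preprocess`, and
`evaluate` subcommands is installed at `inst/cli/sctripletclust.R`:

```sh
Rscript inst/cli/sctripletclust.R simulate --preset standard --outdir fixtures/
Rscript inst/cli/sctripletclust.R run --input fixtures/counts.mtx --format mtx \
    --n-clusters 3 --labels fixtures/truth.csv --seed 1 --outdir out/
```

See `vignettes/methods.Rmd` for the model, its assumptions, parameter
meanings, and the design decisions behind the defaults.

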