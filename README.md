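# sagest

Spatial domain identification for spatial transcriptomics, built around two
ideas: **select the genes that carry spatial signal**, then **embed spots
through two complementary graphs**.

Sequencing- and imaging-based spatial transcriptomics measure a counts
matrix `X (N spots × G genes)` with coordinates `S (N × 2)`. The analysis
goal is to partition spots into *spatial domains* — regions sharing a
transcriptional program. Variance-ranked gene lists (HVGs) mix spatial
signal with spatially random technical variance; purely spatial smoothing
cannot connect disconnected regions that share a program (e.g. bilateral
anatomical structures). `sagest` addresses both:

1. **High spatial-specificity genes (HSGs).** Multi-resolution Leiden runs
   yield a consensus matrix `C_ij = (1/r) Σ_t 1[l_i^(t) = l_j^(t)]` and
   pseudo-labels. NMF topics `X ≈ Z Hᵀ` are filtered by Moran's I
   (`I = (N/W) Σ w_jl z_j z_l / Σ z_j²`, threshold 0.2) and random-forest
   Gini importance. Per-topic gene ranks and z-scores define topic-specific
   genes (rank in the topic head, `z > 1.96`); spatially coherent genes the
   decomposition under-ranked are protected; and the final set
   `G_HSG = (G_HVG ∪ G_TSG) \ G_Del*` is guaranteed no smaller than the HVG
   list.
2. **Dual-view graph autoencoder.** A consensus-pruned spatial k-NN graph
   and a consensus/cosine feature graph are encoded by shared-weight GCNs,
   fused by per-spot softmax attention, and trained under
   `L = λ1 L_recon + λ2 L_graph + λ3 L_swav + λ4 L_att` with
   `λ = {10, 10, 5, 1}` — reconstruction MSE through mirrored decoders,
   class-balanced adjacency BCE, SwAV consistency (symmetric KL between
   Sinkhorn-normalized prototype assignments of the two views), and an
   attention-balance penalty. Domains come from a restart-initialized
   Gaussian mixture (known K) or a Calinski–Harabasz resolution search,
   with optional local majority refinement (25 spatial neighbours).

Marker discovery (topic z-scores; domain→topic→gene Pearson chains;
Wilcoxon DEGs at FDR < 0.001, |log2FC| ≥ 1) and rank-based benchmark
scoring (normalized ranks averaged into accuracy / continuity / marker
overall scores) are included, as is a synthetic data generator with ground
truth.

## Worked example

```r
library(sagest)

sim <- generate_synthetic_st(n_side = 20, n_domains = 4, n_genes = 300,
                             seed = 1)
cfg <- sage_config(n_hvgs = 45, n_pcs = 20,
                   dgnn = sage_dgnn_config(d_hid = 64, d_out = 32,
                                           epochs = 400))
fit <- sage(sim$dataset, n_domains = 4, config = cfg, seed = 1)
summary(fit)
#> Spatial domain model
#>   spots: 400  genes: 300
#>   consensus runs: 10  pseudo-label clusters: 2
#>   topics: 30 -> spatial: 4 -> selected: 3
#>   gene sets: HVG 45  TSG 37  HSG 55
#>   graph edges: spatial 1562  feature 260
#>   training: 400 epochs, total loss 16700 -> 4901
#>   domains: 4 (locally refined)

round(sage_evaluate(fit, sim$truth$domain_labels), 3)
#>   nmi   hom   com   ari chaos   pas   asw
#> 0.944 0.944 0.944 0.954 0.173 0.005 0.400
```

The fit recovers the four planted domains (ARI 0.95, NMI 0.94) with almost
no spatially abnormal spots (PAS 0.005). `plot(fit)` draws the domain map;
`plot(fit, type = "loss")` the training curve; `topic_marker_table(fit$selection)`
and `domain_topic_correlation_markers(...)` give marker tables.

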