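# lfimc — incomplete multiview clustering via late fusion

`lfimc` clusters samples described by several *views* — symmetric N×N
kernel (similarity) matrices over the same N samples, such as multi-omics
layers of the same patients, several image descriptors of the same
objects, or multiple kernels over the same proteins — when some
(sample, view) instances are **missing**. It is aimed at people who have
multiple precomputed kernels with a known number of clusters K, an
N×P zero-one visibility mask S, and want a single consensus partition
without imputing data first.

## Method

Under the random-missing assumption (missingness independent of cluster
membership), the visible part of each view retains its cluster structure,
so each view can be clustered on its own and only the resulting
partitions need reconciling — *late* fusion, as opposed to early fusion
by imputation or subspace learning:

1. **Per-view kernel k-means.** For each view j, the visible sub-kernel
   is centered/scaled and clustered via the spectral relaxation
   (top-K eigenvectors U maximizing tr(UᵀKU), then k-means on the
   kernel-PCA embedding). The partition is encoded as a zero-one
   indicator Zʲ ∈ {0,1}^{N×K} with all-zero rows for missing instances.
2. **Masked consensus k-means.** The consensus decision
   Y ∈ {0,1}^{N×K} (one cluster per sample) and per-(view, cluster)
   centroids Mᶜʲ minimize

   min_{Y,M} Σⱼ Σ_c Σᵢ Y_ic · S_ij · ‖Zᵢʲ − Mᶜʲ‖²

   by alternating the exact coordinate minimizers: Y_ic = 1 at
   argmin_c Σⱼ S_ij‖Zᵢʲ − Mᶜʲ‖², and Mᶜʲ = masked mean of cluster c's
   visible rows of Zʲ. The objective is non-increasing and bounded below,
   so the iteration converges; it stops when Y stops changing.
3. **Initialization.** Y⁰ comes from a basic method: zero / mean / k-NN /
   alignment-style kernel filling followed by uniform-average
   multiple-kernel k-means, or a best-single-view oracle
   (`initial_decision`). Late fusion acts as a refinement of Y⁰.

The package also ships the missingness simulator used in benchmark
protocols (exactly round(εN) incomplete samples; each loses view p iff
g_p < q₀, redrawn so at least one view survives), synthetic multiview
generators with controllable consistency, and evaluation metrics (NMI,
accuracy under optimal Hungarian-style matching).

## Worked example

```r
library(lfimc)

# 3 Gaussian-kernel views of 120 samples, 4 shared clusters;
# half the samples lose views at random (epsilon = 0.5, q0 = 0.5)
d   <- synthetic_multiview(n_samples = 120, n_views = 3, n_clusters = 4, seed = 3)
d   <- set_mask(d, generate_mask(120, 3, epsilon = 0.5, seed = 4))
res <- run_late_fusion(d, k = 4, init_method = "zf", seed = 5)

res$state
#> late-fusion state: N = 120, K = 4
#>   init: zf; iterations: 2; converged: TRUE
#>   objective: 78.8523 -> 1.92

round(c(initial = res$initial_nmi, fused = res$fused_nmi), 3)
#> initial   fused
#>   0.550   0.947
```

The masked objective drops from 78.85 to 1.92 in two alternating
iterations, and the consensus NMI against the ground truth rises from
0.550 (zero-filling + multiple-kernel k-means alone) to 0.947 — the
late-fusion step recovers most of the structure the imputation-based
initialization lost to the missing views.

Files on disk work the same way: `read_kernel_set()` reads TSV or raw
float64 kernels plus the mask, `write_partition()` writes 0-based labels
with a JSON sidecar. `inst/scripts/lfimc-cli.R` exposes the pipeline as
shell subcommands (`simulate-data`, `simulate-mask`, `cluster-views`,
`impute`, `init`, `fuse`, `evaluate`, `benchmark`).

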