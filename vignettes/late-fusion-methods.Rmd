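---
title: "Late-fusion consensus clustering for incomplete multiview kernel data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Late-fusion consensus clustering for incomplete multiview kernel data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfimc)
```

## The problem

Multiview data describe the same $N$ samples through $P$ sources — kernel
matrices computed from different omics layers of the same patients,
different image descriptors of the same objects, different feature sets of
the same proteins. In practice, views are incomplete: a patient skipped a
test, a sensor failed. An $N \times P$ zero-one matrix $S$ records
visibility ($S_{ij} = 1$: the instance of sample $i$ is visible in view
$j$), with the standing requirement that every sample is visible in at
least one view.

Most methods for this setting fuse *early*: impute the missing kernel
entries (or learn a shared subspace) and then cluster once. The approach
implemented here fuses *late*, resting on the **random-missing
assumption**: missingness is independent of cluster membership, so every
cluster loses roughly the same fraction of instances and the cluster
structure of the visible part of each view is preserved. Each view can
therefore be clustered on its own, and only the resulting *partitions*
need to be reconciled.

## The model

**Step 1 — per-view clustering.** For view $j$, the principal sub-kernel of
its visible instances is centered and scaled (`center_and_scale`: $K
\mapsto HKH/s$ with $H = I - \tfrac1n \mathbf{1}\mathbf{1}^\top$ and $s$
the mean centered diagonal) and clustered by spectral-relaxed kernel
$k$-means (`kernel_kmeans`): the discrete indicator is relaxed to an
orthonormal $U \in \mathbb{R}^{n \times K}$ maximizing
$\mathrm{tr}(U^\top K U)$, solved by the top-$K$ eigenvectors, followed by
$k$-means on the embedding. The result is encoded as a zero-one indicator
matrix $Z^j \in \{0,1\}^{N \times K}$ whose $i$-th row is the one-hot
cluster label of sample $i$, or all-zero when $S_{ij} = 0$. Row $Z^j_i$ is
the *compressed representation* of instance $i$ in view $j$.

**Step 2 — consensus by masked k-means.** The consensus decision
$Y \in \{0,1\}^{N \times K}$ (rows summing to one) and per-(view, cluster)
centroids $M^j_c \in \mathbb{R}^K$ minimize the masked sum of per-view
$k$-means objectives over the compressed representations:

$$\min_{Y,\,M} \; \sum_{j=1}^{P} \sum_{c=1}^{K} \sum_{i=1}^{N}
  Y_{ic}\, S_{ij}\, \lVert Z^j_i - M^j_c \rVert_2^2 .$$

Alternating minimization solves it exactly coordinate-wise
(`update_decision`, `update_centroids`, driver `fuse`):

* **Y-step**: $Y_{ic} = 1$ for $c = \arg\min_c G_{ic}$ with
  $G_{ic} = \sum_j S_{ij} \lVert Z^j_i - M^j_c\rVert^2$ — the exact
  minimizer for fixed $M$;
* **M-step**: $M^j_c = \sum_i Y_{ic} S_{ij} Z^j_i \,/\, \sum_i Y_{ic}
  S_{ij}$ — the masked mean, the exact minimizer for fixed $Y$.

Both steps weakly decrease an objective bounded below by zero, and $Y$
ranges over a finite set, so the iteration converges; we stop when $Y$ is
unchanged over a full iteration (the classic $k$-means rule — the
objective is piecewise constant in $Y$, so no epsilon threshold is
needed), with `max_iter = 200` as a safety net that no test instance has
ever approached.

**Initialization.** $Y^0$ is not random: it is the output of a basic
incomplete-multiview method (`initial_decision`) — one of the imputation
baselines below followed by multiple-kernel $k$-means, or the
best-single-view oracle — and $M$ is first computed from $Y^0$ by the
M-step. Late fusion is best understood as a refinement of that initial
clustering decision.

## Numerical and design choices

**Embedding scaling.** After eigendecomposition, $k$-means runs on the
kernel-PCA coordinates $U \operatorname{diag}(\sqrt{\lambda_+})$ rather
than on the bare orthonormal $U$. In these coordinates the Euclidean
$k$-means objective equals the kernel $k$-means objective restricted to
the top-$K$ eigenspace — exactly the full objective whenever the kernel
has rank $\le K$. Bare-$U$ clustering weights a near-null eigendirection
as strongly as the leading one; on a centered linear kernel of 2-D data
(rank 2) the third eigenvector is an arbitrary null-space basis vector and
demonstrably destroys the partition (accuracy drops from 0.97 to 0.65 on
the toy data below). The reported `embedding` stays orthonormal; only the
clustering coordinates are scaled.

**k-means internals.** $k$-means++ seeding, best of `n_restarts` (default
10) Lloyd runs, empty clusters repaired by seizing the point farthest from
its current centroid. All randomness flows from an integer seed; view $j$
uses `seed + j - 1` so restarts decorrelate across views while the whole
pipeline stays a deterministic function of its arguments.

**Ties and degenerate cases.** The Y-step breaks ties *stickily*: a
sample keeps its previous cluster whenever that cluster is within
$10^{-12}$ of the row minimum, else takes the lowest index. This makes
"$Y$ unchanged" a sound stopping rule (no limit cycles on exact ties) and
means $Y$ changes only when the objective strictly decreases. A (view,
cluster) pair with no visible member leaves its centroid undefined: the
previous value is retained and flagged, which is harmless because the
corresponding terms are absent from the objective — the convergence
argument is untouched. At initialization such centroids fall back to the
global mean of the view's visible compressed rows. Empty *consensus*
clusters may persist ($K$ is prior knowledge; the objective never forces
$K$ nonempty clusters) and are only warned about.

**Preprocessing order.** Per-view clustering centers/scales the visible
*sub-kernel* — the object actually clustered; centering a completed
matrix would leak mask structure into the geometry. The imputation
baselines, by contrast, center/scale each *completed* kernel before
averaging.

**Kernel validation.** Kernels must be symmetric within $10^{-8}$
(silently symmetrized below that, an error above it — the tolerance
absorbs text-file rounding without masking data errors). Positive
semidefiniteness is checked and warned about but not enforced: the
spectral solver needs only symmetry.

## Baselines

Five standard strategies produce completed kernels and/or an initial
decision (tags as used throughout):

* **ZF** (`zero_fill`): entries involving a missing sample are set to 0.
* **MF** (`mean_fill`): each missing entry $(i,l)$ of view $j$ is the
  per-entry average of $K^{j'}_{il}$ over views where both $i$ and $l$
  are visible; entries visible nowhere fall back to 0.
* **KNN** (`knn_fill`): a missing sample's similarity profile is averaged
  over its visible views; its $k$ most similar samples among those
  visible in the target view donate their rows (default
  `k_neighbors = 5`, a conventional choice; the neighbour metric is the
  mean visible-view kernel row).
* **AF** (`af_fill`, tag `af-copy`): the uniform average of the
  zero-filled kernels is copied into the missing positions of each view —
  the averaging reading of alignment-style filling; no alignment
  optimization is run.
* **BS** (`best_single_view`): an oracle that scores every view's visible
  partition against the ground truth by NMI, keeps the best, and
  completes it with seeded uniform-random labels.

`multiple_kernel_kmeans` combines completed kernels by uniform averaging
after center/scale — the minimal deterministic multiple-kernel rule; no
kernel weights are learned, which keeps every baseline's behaviour
attributable to its filling rule.

## What the simulators emulate

`generate_mask` reproduces the standard benchmark missingness protocol:
exactly $\mathrm{round}(\epsilon N)$ samples are selected as incomplete;
each selected sample draws $g \in [0,1]^P$ and loses view $p$ iff
$g_p < q_0$ (default 0.5), redrawing until at least one view remains.
Literally applied, a selected sample can come out *complete* (conditional
probability $(1-q_0)^P / (1 - q_0^P)$), so the realized incomplete ratio
would undershoot $\epsilon$; since $\epsilon$ is *defined* as the ratio of
samples with missing views, the default `require_missing = TRUE` also
redraws until at least one view is absent, making $\epsilon$ exact. Both
behaviours are kept, and the rejection sampler's conditional pattern
distribution is verified analytically in the tests (e.g. per-view missing
frequency $(q_0 - q_0^2)/(1 - q_0^2 - (1-q_0)^2) = 1/2$ at $P = 2$,
complete-pattern frequency $1/7$ at $P = 3$ without the redraw).

`toy_gaussians` / `random_missing_study` build the three-Gaussian
stability demonstration: means $(0,0)$, $(4,0)$, $(2,3.5)$, unit
covariance, 100 points per cluster, linear kernel — parameters chosen once
so that complete-data accuracy is near 1 and the stability property is
sharp. Instances are deleted uniformly at random, independent of labels.
Visible-instance accuracy stays within a few thousandths of the
complete-data accuracy up to 50% deletion, and matched centroids drift by
a fraction of the minimum inter-centroid gap.

`synthetic_multiview` generates multi-omics-like layers: shared latent
labels; per-view cluster centers placed as a `separation`-scaled random
orthonormal frame (all pairwise center distances equal
`separation`$\cdot\sqrt2$ — defaults `separation = 4`, unit noise, i.e.
clearly but not trivially separated Gaussian clusters in 10 dimensions);
Gaussian kernels with width set to the mean pairwise sample distance (the
usual benchmark convention), or linear kernels. Two controlled
corruptions: `view_consistency < 1` redraws a fraction of labels
independently per view (inconsistent views, the regime where late fusion
is known to struggle), and `merge_pairs` gives two clusters a shared
center in a chosen view — the identifiability construction in which no
single view can separate all $K$ clusters but the fused membership
patterns can.

What these generators do *not* emulate: heteroscedastic or structured
noise, unbalanced clusters, informative (label-dependent) missingness,
views with different sample coverage semantics, or the scale of real
benchmark collections. Passing tests on them demonstrates correctness of
the optimization and the qualitative behaviour of the method under the
random-missing assumption — not performance on any particular real
dataset.

## Evaluation conventions

`nmi` uses natural logarithms and the $\sqrt{H_a H_b}$ normalization (the
common choice in this literature; `max` and `mean` variants are
available), with $0/0 \to 0$ when a partition is trivial. `acc` is
accuracy under the optimal one-to-one cluster matching, solved as a
maximum-weight bipartite matching on the contingency table. Both are
relabeling-invariant. `run_comparison` replays the
initialization-versus-late-fusion design on synthetic data: per
(method, $\epsilon$, seed) it records initial and fused NMI, then ranks
methods by mean fused NMI and by mean gain; every randomized component is
seed-fanned (`seed + 1000 r`) so reports are bit-reproducible.

## Problem sizes used in the shipped checks

The packaged tests and the acceptance script run at desk scale, chosen as
the smallest sizes at which every property is sharp: exhaustive oracles at
$N \le 6$, $K \le 3$, $P \le 3$ (all $K^N$ assignments) and $n \le 8$ for
2-partition enumeration; convergence and improvement studies at
$N = 200$–$300$, $P = 3$, $K = 4$, $\epsilon \in \{0.2, 0.5, 0.8\}$ with
50–100 seeded repetitions; the stability study at 300 toy points with 100
repeats per ratio; sampler frequencies at $10^5$ draws.

## Known limitations

* $K$ must be known; nothing selects it.
* Views are unweighted in the objective; a noisy view counts as much as an
  informative one, and strongly inconsistent views can degrade the
  consensus below a good initialization.
* The per-view partitions $Z^j$ are fixed during fusion; they are never
  re-estimated jointly.
* Dense eigendecomposition costs $O(N^3)$ per view; the implementation
  recomputes all $N \times K$ assignment costs each iteration
  ($O(PNK^2)$) rather than updating incrementally.
* The AF baseline is the averaging copy rule, not a full
  alignment-maximization solver; the BS baseline reads ground truth by
  design and is an oracle reference, not a method.

## A worked miniature

```{r example}
d <- synthetic_multiview(n_samples = 120, n_views = 3, n_clusters = 4,
                         seed = 3)
d <- set_mask(d, generate_mask(120, 3, epsilon = 0.5, seed = 4))
res <- run_late_fusion(d, k = 4, init_method = "zf", seed = 5)
res$state
c(initial = res$initial_nmi, fused = res$fused_nmi)
```

The objective trace is non-increasing and the fused NMI improves on the
zero-filling initialization — the behaviour the method is designed to
deliver under random missingness with consistent views.
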