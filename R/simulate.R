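# Synthetic inputs: the random view-missingness process, the toy
# three-Gaussian stability study, and multiview kernel data with a shared
# cluster structure (multi-omics-like layers of the same samples).

#' Simulate a random view-missingness mask
#'
#' Selects exactly `round(epsilon * n_samples)` samples to be incomplete
#' (the incomplete-sample ratio). For each selected sample a vector
#' g in \[0,1\]^P is drawn and view p is marked missing iff g\[p\] < q0,
#' redrawing until at least one view is present. With
#' `require_missing = TRUE` (default) the draw is also repeated until at
#' least one view is absent, so the realized incomplete-sample ratio
#' equals epsilon exactly; with `FALSE` a selected sample may come out
#' complete (probability (1-q0)^P among accepted draws being
#' (1-q0)^P / (1 - q0^P)). Unselected rows are all-ones.
#'
#' @param n_samples N.
#' @param n_views P (>= 2 when `require_missing`).
#' @param epsilon incomplete-sample ratio in \[0, 1\].
#' @param q0 per-view missing probability in (0, 1); 0.5 is the
#'   conventional setting.
#' @param seed integer seed; the mask is a deterministic function of all
#'   arguments.
#' @param require_missing redraw until a selected sample has >= 1 missing
#'   view (default TRUE).
#' @return zero-one N x P matrix with no all-zero row.
#' @examples
#' m <- generate_mask(10, 2, epsilon = 0.5, seed = 1)
#' rowSums(m)  # every sample keeps at least one view
#' @export
generate_mask <- function(n_samples, n_views, epsilon, q0 = 0.5, seed = 0L,
                          require_missing = TRUE) {
  if (epsilon < 0 || epsilon > 1)
    stop_lfimc("epsilon must be in [0, 1]", "lfimc_validation_error")
  if (q0 <= 0 || q0 >= 1)
    stop_lfimc("q0 must be in (0, 1)", "lfimc_validation_error")
  if (n_views < 1L)
    stop_lfimc("n_views must be >= 1", "lfimc_validation_error")
  if (require_missing && n_views < 2L)
    stop_lfimc("require_missing needs n_views >= 2 (a sample cannot have both a visible and a missing view with one view)",
               "lfimc_validation_error")
  withr::with_seed(as.integer(seed), {
    mask <- matrix(1, n_samples, n_views)
    n_sel <- round(epsilon * n_samples)
    sel <- if (n_sel > 0L) sample.int(n_samples, n_sel) else integer(0)
    for (i in sel) {
      repeat {
        g <- stats::runif(n_views)
        miss <- g < q0
        if (any(!miss) && (!require_missing || any(miss))) break
      }
      mask[i, ] <- as.numeric(!miss)
    }
    mask
  })
}

#' Toy three-Gaussian data
#'
#' Three isotropic 2-D Gaussian clusters with well-separated means
#' ((0,0), (4,0), (2,3.5) by default, unit covariance), shuffled, with
#' labels. A crisp seedable stand-in for studying the stability of
#' visible-instance clustering under random missingness.
#'
#' @param n_per_cluster points per cluster (>= 2).
#' @param seed integer seed.
#' @param means 3 x 2 matrix of cluster means.
#' @param sd common isotropic standard deviation.
#' @return list with `features` (3*n_per_cluster x 2 matrix), `labels`
#'   (integers 1..3), `means`.
#' @export
toy_gaussians <- function(n_per_cluster = 100L, seed = 0L,
                          means = rbind(c(0, 0), c(4, 0), c(2, 3.5)),
                          sd = 1) {
  if (n_per_cluster < 2L)
    stop_lfimc("n_per_cluster must be >= 2", "lfimc_validation_error")
  withr::with_seed(as.integer(seed), {
    k <- nrow(means)
    labels <- rep(seq_len(k), each = n_per_cluster)
    x <- means[labels, , drop = FALSE] +
      matrix(stats::rnorm(length(labels) * ncol(means), sd = sd),
             ncol = ncol(means))
    ord <- sample.int(length(labels))
    list(features = x[ord, , drop = FALSE], labels = labels[ord], means = means)
  })
}

# match each row of `a` (k x d) to a row of `b` minimizing total distance;
# returns the matched distances (k of them). Brute force over permutations.
match_centroids <- function(a, b) {
  k <- nrow(a)
  d <- as.matrix(stats::dist(rbind(a, b)))[seq_len(k), k + seq_len(k), drop = FALSE]
  perms <- all_permutations(k)
  costs <- apply(perms, 1L, function(p) sum(d[cbind(seq_len(k), p)]))
  best <- perms[which.min(costs), ]
  d[cbind(seq_len(k), best)]
}

all_permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Stability of visible-instance clustering under random missingness
#'
#' Repeats the random-deletion experiment: for each missing ratio, delete
#' that fraction of instances uniformly at random (independent of labels —
#' the random-missing assumption made literal), run kernel k-means (linear
#' kernel, centered and scaled) on the visible instances, and record the
#' visible-instance clustering accuracy and the maximum distance between
#' the visible-data cluster centroids and the complete-data cluster
#' centroids after optimal matching. Returns per-ratio means over
#' `n_repeats` repeats.
#'
#' @param n_per_cluster points per cluster of the toy data.
#' @param ratios missing ratios, each in (0, 1).
#' @param n_repeats repeats per ratio (100 for the headline study).
#' @param seed base seed; repeats fan out deterministically.
#' @param n_restarts k-means restarts.
#' @return list with `summary` (data.frame: ratio, mean_acc, mean_drift),
#'   `complete_acc`, `complete_centroids`, `min_centroid_gap`.
#' @export
random_missing_study <- function(n_per_cluster = 100L,
                                 ratios = seq(0.1, 0.5, by = 0.1),
                                 n_repeats = 100L, seed = 0L,
                                 n_restarts = 10L) {
  if (any(ratios <= 0 | ratios >= 1))
    stop_lfimc("ratios must lie in (0, 1)", "lfimc_validation_error")
  toy <- toy_gaussians(n_per_cluster, seed = seed)
  x <- toy$features
  n <- nrow(x)
  k <- nrow(toy$means)
  run_kkm <- function(xx, sd_seed) {
    kk <- suppressWarnings(center_and_scale(tcrossprod(xx)))
    kernel_kmeans(kk, k, n_restarts = n_restarts, seed = sd_seed)$labels
  }
  complete_labels <- run_kkm(x, seed)
  complete_acc <- acc(complete_labels, toy$labels)
  complete_centroids <- t(vapply(seq_len(k), function(c)
    colMeans(x[complete_labels == c, , drop = FALSE]), numeric(ncol(x))))
  gaps <- stats::dist(complete_centroids)
  summary <- data.frame(ratio = ratios, mean_acc = NA_real_, mean_drift = NA_real_)
  for (ri in seq_along(ratios)) {
    ratio <- ratios[ri]
    n_del <- round(ratio * n)
    if (n - n_del < k)
      stop_lfimc("ratio leaves fewer visible points than clusters", "lfimc_validation_error")
    accs <- numeric(n_repeats)
    drifts <- numeric(n_repeats)
    for (r in seq_len(n_repeats)) {
      rs <- as.integer(seed + 7919L * ri + r)
      keep <- withr::with_seed(rs, sort(sample.int(n, n - n_del)))
      lab <- run_kkm(x[keep, , drop = FALSE], rs)
      accs[r] <- acc(lab, toy$labels[keep])
      cen <- t(vapply(seq_len(k), function(c)
        colMeans(x[keep, , drop = FALSE][lab == c, , drop = FALSE]),
        numeric(ncol(x))))
      drifts[r] <- max(match_centroids(cen, complete_centroids))
    }
    summary$mean_acc[ri] <- mean(accs)
    summary$mean_drift[ri] <- mean(drifts)
  }
  list(summary = summary, complete_acc = complete_acc,
       complete_centroids = complete_centroids,
       min_centroid_gap = min(gaps))
}

#' Synthetic multiview kernel data with shared cluster structure
#'
#' Draws latent cluster labels for N samples, then for each view draws K
#' cluster centers in R^{d_j} as `separation` times a random orthonormal
#' frame (all pairwise center distances equal `separation * sqrt(2)`),
#' emits per-sample Gaussian features around the centers, and builds the
#' per-view kernel (linear, or Gaussian with width set to the mean pairwise
#' sample distance of that view). Emulates multi-omics-like layers: every
#' view sees the same latent partition, possibly corrupted.
#'
#' Two corruption mechanisms are available: `view_consistency < 1` redraws
#' the latent label of a random (1 - view_consistency) fraction of samples
#' independently in each view (inconsistent views); `merge_pairs` makes a
#' view uninformative about one pair of clusters by giving the pair a
#' shared center in that view (so no single view can separate all K
#' clusters, but views together can).
#'
#' @param n_samples N (>= 2 * n_clusters).
#' @param n_views P.
#' @param n_clusters K.
#' @param dims per-view feature dimensions d_j (recycled to length P);
#'   each must be >= n_clusters.
#' @param separation scale of the cluster-center frame.
#' @param noise_scale isotropic feature noise standard deviation.
#' @param view_consistency fraction of samples whose latent label is
#'   consistent in every view (default 1).
#' @param kernel per-view kernel type, "linear" or "gaussian" (recycled).
#' @param merge_pairs optional list of length P: `merge_pairs[[j]]` is
#'   either NULL or an integer pair (c1, c2) sharing a center in view j.
#' @param seed integer seed.
#' @return a [multiview_kernel_data] object with a fully visible mask and
#'   ground-truth `labels`.
#' @export
synthetic_multiview <- function(n_samples = 300L, n_views = 3L, n_clusters = 4L,
                                dims = 10L, separation = 4, noise_scale = 1,
                                view_consistency = 1, kernel = "gaussian",
                                merge_pairs = NULL, seed = 0L) {
  if (n_samples < 2L * n_clusters)
    stop_lfimc("need n_samples >= 2 * n_clusters", "lfimc_validation_error")
  if (view_consistency < 0 || view_consistency > 1)
    stop_lfimc("view_consistency must be in [0, 1]", "lfimc_validation_error")
  dims <- rep_len(as.integer(dims), n_views)
  if (any(dims < n_clusters))
    stop_lfimc("each view dimension must be >= n_clusters (orthonormal center frame)",
               "lfimc_validation_error")
  kernel <- rep_len(match.arg(kernel, c("linear", "gaussian"), several.ok = TRUE), n_views)
  if (!is.null(merge_pairs) && length(merge_pairs) != n_views)
    stop_lfimc("merge_pairs must have one element (or NULL) per view", "lfimc_validation_error")
  withr::with_seed(as.integer(seed), {
    labels <- sample(rep_len(seq_len(n_clusters), n_samples))
    kernels <- vector("list", n_views)
    features <- vector("list", n_views)
    for (j in seq_len(n_views)) {
      d <- dims[j]
      frame <- qr.Q(qr(matrix(stats::rnorm(d * n_clusters), d, n_clusters)))
      centers <- separation * t(frame)            # K x d, equidistant rows
      if (!is.null(merge_pairs) && !is.null(merge_pairs[[j]])) {
        pr <- as.integer(merge_pairs[[j]])
        centers[pr[2L], ] <- centers[pr[1L], ]
      }
      lab_j <- labels
      if (view_consistency < 1) {
        flip <- which(stats::runif(n_samples) > view_consistency)
        lab_j[flip] <- sample.int(n_clusters, length(flip), replace = TRUE)
      }
      x <- centers[lab_j, , drop = FALSE] +
        matrix(stats::rnorm(n_samples * d, sd = noise_scale), n_samples, d)
      features[[j]] <- x
      if (kernel[j] == "linear") {
        kernels[[j]] <- tcrossprod(x)
      } else {
        dd <- as.matrix(stats::dist(x))
        sigma <- mean(dd[upper.tri(dd)])
        kernels[[j]] <- exp(-dd^2 / (2 * sigma^2))
      }
    }
    out <- multiview_kernel_data(kernels, labels = labels, check_psd = FALSE)
    attr(out, "features") <- features
    out
  })
}
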