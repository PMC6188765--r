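# Comparison / initialization strategies: kernel imputation (zero, mean,
# k-nearest-neighbour, alignment-style average filling) followed by
# multiple-kernel k-means, plus the best-single-view oracle.

new_completed_kernel_set <- function(kernels, fill_method, n_imputed) {
  kernels <- lapply(kernels, function(k) (k + t(k)) / 2)
  structure(list(kernels = kernels, fill_method = fill_method,
                 n_imputed = n_imputed),
            class = "completed_kernel_set")
}

#' @export
print.completed_kernel_set <- function(x, ...) {
  cat(sprintf("completed_kernel_set (%s): %d views, imputed entries per view: %s\n",
              x$fill_method, length(x$kernels), paste(x$n_imputed, collapse = ", ")))
  invisible(x)
}

# entries of view j involving at least one missing sample
missing_entry_mask <- function(mask_col) {
  vis <- mask_col == 1
  !outer(vis, vis, "&")
}

#' Zero filling of incomplete kernels
#'
#' Sets every kernel entry (i, l) of view j involving a missing sample
#' (S\[i,j\] = 0 or S\[l,j\] = 0) to zero; visible-visible entries are
#' untouched.
#'
#' @param data a [multiview_kernel_data] object.
#' @return a `completed_kernel_set` (fields `kernels`, `fill_method`,
#'   `n_imputed` = per-view count of imputed entries).
#' @export
zero_fill <- function(data) {
  stopifnot(inherits(data, "multiview_kernel_data"))
  kernels <- data$kernels
  n_imp <- integer(data$n_views)
  for (j in seq_len(data$n_views)) {
    miss <- missing_entry_mask(data$mask[, j])
    kernels[[j]][miss] <- 0
    n_imp[j] <- sum(miss)
  }
  new_completed_kernel_set(kernels, "zero", n_imp)
}

#' Mean filling of incomplete kernels
#'
#' Each missing entry (i, l) of view j is replaced by the average of the
#' corresponding entries K^j'\[i, l\] over the views j' where both i and l
#' are visible. Entries visible in no view fall back to 0 (with a warning),
#' matching zero filling for hopeless entries.
#'
#' @inheritParams zero_fill
#' @return a `completed_kernel_set`.
#' @export
mean_fill <- function(data) {
  stopifnot(inherits(data, "multiview_kernel_data"))
  n <- data$n_samples
  num <- matrix(0, n, n)
  den <- matrix(0, n, n)
  vis_prod <- vector("list", data$n_views)
  for (j in seq_len(data$n_views)) {
    v <- outer(data$mask[, j] == 1, data$mask[, j] == 1, "&")
    vis_prod[[j]] <- v
    num <- num + data$kernels[[j]] * v
    den <- den + v
  }
  kernels <- data$kernels
  n_imp <- integer(data$n_views)
  n_hopeless <- 0L
  for (j in seq_len(data$n_views)) {
    miss <- !vis_prod[[j]]
    fill <- matrix(0, n, n)
    # exclude view j itself; at missing entries its own product is 0 anyway
    ok <- den > 0
    fill[ok] <- num[ok] / den[ok]
    n_hopeless <- n_hopeless + sum(miss & !ok)
    kernels[[j]][miss] <- fill[miss]
    n_imp[j] <- sum(miss)
  }
  if (n_hopeless > 0L)
    warning(sprintf("%d entries visible in no view were filled with 0", n_hopeless))
  new_completed_kernel_set(kernels, "mean", n_imp)
}

#' k-nearest-neighbour filling of incomplete kernels
#'
#' For each sample i missing in view j, its similarity to the other
#' samples is measured by the mean of its kernel rows over the views where
#' i is visible. The `k_neighbors` most similar samples among those
#' visible in view j are its neighbours. Row/column i of view j is then
#' the average of the neighbours' rows/columns (restricted to visible
#' columns); entries between two missing samples i and l are the mean of
#' K^j\[Nb(i), Nb(l)\]; the diagonal entry is the neighbours' mean
#' diagonal. The matrix is re-symmetrized.
#'
#' @inheritParams zero_fill
#' @param k_neighbors number of neighbours (default 5).
#' @return a `completed_kernel_set`.
#' @export
knn_fill <- function(data, k_neighbors = 5L) {
  stopifnot(inherits(data, "multiview_kernel_data"))
  if (k_neighbors < 1L)
    stop_lfimc("k_neighbors must be >= 1", "lfimc_validation_error")
  n <- data$n_samples
  kernels <- data$kernels
  n_imp <- integer(data$n_views)
  for (j in seq_len(data$n_views)) {
    vis <- which(data$mask[, j] == 1)
    mis <- which(data$mask[, j] == 0)
    n_imp[j] <- sum(missing_entry_mask(data$mask[, j]))
    if (length(mis) == 0L) next
    if (length(vis) <= k_neighbors)
      stop_lfimc(sprintf("view %d has only %d visible samples; need more than k_neighbors = %d",
                         j, length(vis), k_neighbors), "lfimc_validation_error")
    kj <- data$kernels[[j]]
    nb <- vector("list", n)
    for (i in mis) {
      own_views <- which(data$mask[i, ] == 1)
      # mean similarity over views where both i and the candidate are visible
      num <- rep(0, n); den <- rep(0, n)
      for (jj in own_views) {
        v <- data$mask[, jj]
        num <- num + data$kernels[[jj]][, i] * v
        den <- den + v
      }
      sim <- ifelse(den > 0, num / den, -Inf)
      cand <- setdiff(vis, i)
      cand <- cand[is.finite(sim[cand])]
      if (length(cand) == 0L)
        stop_lfimc("no visible neighbors", "lfimc_validation_error")
      nb[[i]] <- cand[order(sim[cand], decreasing = TRUE)[seq_len(min(k_neighbors, length(cand)))]]
    }
    filled <- kj
    for (i in mis) {
      rowmean <- colMeans(kj[nb[[i]], , drop = FALSE])
      filled[i, vis] <- rowmean[vis]
      filled[vis, i] <- rowmean[vis]
      filled[i, i] <- mean(diag(kj)[nb[[i]]])
    }
    for (i in mis) for (l in mis) if (i < l) {
      v <- mean(kj[nb[[i]], nb[[l]], drop = FALSE])
      filled[i, l] <- v
      filled[l, i] <- v
    }
    kernels[[j]] <- filled
  }
  new_completed_kernel_set(kernels, "knn", n_imp)
}

#' Alignment-style average filling of incomplete kernels
#'
#' Builds the consensus kernel C = (1/P) sum_j (zero-filled K^j) and
#' replaces every missing entry (i, l) of each view by C\[i, l\]; visible
#' entries are kept. This is the averaging variant of
#' alignment-maximization filling (tag `af-copy`): the consensus kernel is
#' copied into the missing positions rather than obtained from the full
#' alignment-maximization closed form.
#'
#' @inheritParams zero_fill
#' @return a `completed_kernel_set`.
#' @export
af_fill <- function(data) {
  stopifnot(inherits(data, "multiview_kernel_data"))
  zf <- zero_fill(data)
  consensus <- Reduce(`+`, zf$kernels) / data$n_views
  kernels <- data$kernels
  n_imp <- integer(data$n_views)
  for (j in seq_len(data$n_views)) {
    miss <- missing_entry_mask(data$mask[, j])
    kernels[[j]][miss] <- consensus[miss]
    n_imp[j] <- sum(miss)
  }
  new_completed_kernel_set(kernels, "af-copy", n_imp)
}

#' Multiple-kernel k-means on completed kernels
#'
#' Center-and-scales each completed kernel, averages them with uniform
#' weights into a single combined kernel, and clusters it with
#' [kernel_kmeans]. The uniform-average combination is the minimal
#' deterministic multiple-kernel rule; no kernel weights are learned.
#'
#' @param completed a `completed_kernel_set`, or a plain list of complete
#'   symmetric N x N kernels.
#' @param k number of clusters.
#' @param n_restarts,seed passed to [kernel_kmeans].
#' @return zero-one N x K consensus decision matrix, with the underlying
#'   `kernel_kmeans_result` attached as attribute `"result"`.
#' @export
multiple_kernel_kmeans <- function(completed, k, n_restarts = 10L, seed = 0L) {
  kernels <- if (inherits(completed, "completed_kernel_set")) completed$kernels else completed
  prepped <- lapply(kernels, function(kk) suppressWarnings(center_and_scale(kk)))
  combined <- Reduce(`+`, prepped) / length(prepped)
  res <- kernel_kmeans(combined, k, n_restarts = n_restarts, seed = seed)
  y <- labels_to_indicator(res$labels, k)
  attr(y, "result") <- res
  y
}

#' Best-single-view baseline (ground-truth oracle)
#'
#' Evaluates each view's visible-instance partition against the
#' ground-truth labels by NMI, picks the best view, and completes its
#' partition by assigning each of its missing instances a uniformly random
#' cluster from the seeded generator. Explicitly an oracle baseline: it
#' reads the truth to select the view.
#'
#' @param data a [multiview_kernel_data] object (used for the mask).
#' @param assignments list of P per-view indicator matrices or
#'   [view_assignment] objects.
#' @param truth integer ground-truth labels (1-based); defaults to
#'   `data$labels`.
#' @param seed seed for the random completion.
#' @return zero-one N x K decision matrix with attributes `"best_view"`
#'   and `"view_nmi"`.
#' @export
best_single_view <- function(data, assignments, truth = data$labels, seed = 0L) {
  stopifnot(inherits(data, "multiview_kernel_data"))
  if (is.null(truth))
    stop_lfimc("best_single_view requires ground-truth labels", "lfimc_validation_error")
  zs <- assignment_matrices(assignments)
  k <- ncol(zs[[1L]])
  scores <- vapply(seq_along(zs), function(j) {
    vis <- which(data$mask[, j] == 1)
    nmi(indicator_to_labels(zs[[j]])[vis], truth[vis])
  }, numeric(1))
  best <- which.max(scores)
  lab <- indicator_to_labels(zs[[best]])
  mis <- which(is.na(lab))
  if (length(mis) > 0L)
    lab[mis] <- withr::with_seed(as.integer(seed),
                                 sample.int(k, length(mis), replace = TRUE))
  y <- labels_to_indicator(lab, k)
  attr(y, "best_view") <- best
  attr(y, "view_nmi") <- scores
  y
}

#' Build an initial consensus decision Y0 from a baseline method
#'
#' Convenience dispatcher producing the initialization the late-fusion
#' step starts from: one of the imputation methods followed by
#' [multiple_kernel_kmeans], or the [best_single_view] oracle.
#'
#' @param data a [multiview_kernel_data] object.
#' @param k number of clusters.
#' @param method one of "zf", "mf", "knn", "af", "bs".
#' @param assignments per-view assignments (required for "bs").
#' @param k_neighbors neighbours for "knn".
#' @param n_restarts,seed passed to the underlying clusterer.
#' @return zero-one N x K decision matrix.
#' @export
initial_decision <- function(data, k, method = c("zf", "mf", "knn", "af", "bs"),
                             assignments = NULL, k_neighbors = 5L,
                             n_restarts = 10L, seed = 0L) {
  method <- match.arg(method)
  if (method == "bs") {
    if (is.null(assignments))
      stop_lfimc("method 'bs' requires per-view assignments", "lfimc_validation_error")
    return(best_single_view(data, assignments, seed = seed))
  }
  completed <- switch(method,
    zf = zero_fill(data),
    mf = suppressWarnings(mean_fill(data)),
    knn = knn_fill(data, k_neighbors = k_neighbors),
    af = af_fill(data))
  multiple_kernel_kmeans(completed, k, n_restarts = n_restarts, seed = seed)
}
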