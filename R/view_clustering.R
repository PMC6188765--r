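# Per-view clustering: kernel centering/scaling and spectral-relaxed
# kernel k-means on the visible instances of each view.

#' Center and scale a kernel matrix
#'
#' Double-centers a kernel in feature space, K -> H K H with
#' H = I - (1/n) 11', and rescales so that the mean diagonal (the average
#' squared feature-space norm) is 1: returns H K H / s with
#' s = mean(diag(H K H)). Standard preprocessing for (multiple-)kernel
#' k-means. If s <= 1e-12 the kernel has collapsed to (numerically) zero
#' under centering — e.g. a constant-feature kernel — and the scaling step
#' is skipped with a warning; the centered matrix is returned with
#' attribute `degenerate = TRUE`.
#'
#' @param kernel symmetric numeric n x n matrix.
#' @return symmetric n x n matrix with row sums ~ 0 and, unless degenerate,
#'   mean diagonal 1.
#' @examples
#' k <- center_and_scale(diag(4))
#' mean(diag(k))      # 1
#' max(abs(rowSums(k)))  # ~ 0
#' @export
center_and_scale <- function(kernel) {
  kernel <- as.matrix(kernel)
  n <- nrow(kernel)
  if (n != ncol(kernel))
    stop_lfimc("kernel must be square", "lfimc_dimension_error")
  rm <- rowMeans(kernel)
  gm <- mean(kernel)
  centered <- kernel - outer(rm, rep(1, n)) - outer(rep(1, n), rm) + gm
  s <- mean(diag(centered))
  if (s <= 1e-12) {
    warning("degenerate kernel: centered matrix has (near-)zero mean diagonal; scaling skipped")
    attr(centered, "degenerate") <- TRUE
    return(centered)
  }
  centered / s
}

# Lloyd's algorithm with k-means++ seeding and farthest-point repair of
# empty clusters; all randomness comes from the current RNG state.
kmeanspp_lloyd_once <- function(x, k, max_iter = 100L) {
  n <- nrow(x)
  xsq <- rowSums(x^2)
  # k-means++ seeding
  centers <- matrix(0, k, ncol(x))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- x[idx, ]
  if (k > 1L) {
    d2 <- pmax(xsq + sum(centers[1L, ]^2) - 2 * drop(x %*% centers[1L, ]), 0)
    for (c in 2L:k) {
      if (sum(d2) <= 0) idx <- sample.int(n, 1L)
      else idx <- sample.int(n, 1L, prob = d2)
      centers[c, ] <- x[idx, ]
      d2 <- pmin(d2, pmax(xsq + sum(centers[c, ]^2) - 2 * drop(x %*% centers[c, ]), 0))
    }
  }
  assign_prev <- integer(n)
  for (it in seq_len(max_iter)) {
    d <- outer(xsq, rowSums(centers^2), "+") - 2 * tcrossprod(x, centers)
    assign <- max.col(-d, ties.method = "first")
    # repair empty clusters: seize the point currently farthest from its centroid
    repeat {
      counts <- tabulate(assign, nbins = k)
      empties <- which(counts == 0L)
      if (length(empties) == 0L) break
      dmin <- d[cbind(seq_len(n), assign)]
      # only points in clusters of size >= 2 may be seized
      movable <- counts[assign] >= 2L
      cand <- which(movable)
      far <- cand[which.max(dmin[cand])]
      assign[far] <- empties[1L]
    }
    for (c in seq_len(k)) centers[c, ] <- colMeans(x[assign == c, , drop = FALSE])
    if (identical(assign, assign_prev)) break
    assign_prev <- assign
  }
  d <- outer(xsq, rowSums(centers^2), "+") - 2 * tcrossprod(x, centers)
  inertia <- sum(pmax(d[cbind(seq_len(n), assign)], 0))
  list(cluster = assign, inertia = inertia)
}

#' Spectral-relaxed kernel k-means
#'
#' Solves the trace-maximization relaxation of kernel k-means: the discrete
#' indicator is relaxed to an orthonormal U in R^{n x k}, maximizing
#' tr(U' K U) s.t. U'U = I, whose optimum is spanned by the k eigenvectors
#' of K with largest eigenvalues. k-means (k-means++ seeding, best of
#' `n_restarts` runs, no row normalization) on the kernel-PCA coordinates
#' U diag(sqrt(pmax(lambda, 0))) then recovers a discrete partition: in
#' these coordinates the Euclidean k-means objective equals the kernel
#' k-means objective restricted to the top-k eigenspace (exactly the full
#' objective when the kernel has rank <= k), whereas k-means on the bare
#' orthonormal U would weight a near-null eigendirection as strongly as
#' the leading one. The kernel is assumed already preprocessed (see
#' [center_and_scale]); pass it through unchanged here.
#'
#' Eigenvectors are taken in descending-eigenvalue order from a
#' deterministic symmetric solver; when the k-th eigenvalue is degenerate
#' the basis U is seed-stable but arbitrary — only the labels are
#' contractual. The result is a deterministic function of
#' `(kernel, k, n_restarts, seed)`.
#'
#' @param kernel symmetric n x n matrix.
#' @param k number of clusters, 2 <= k <= n.
#' @param n_restarts number of k-means restarts on the embedding.
#' @param seed integer seed governing all restarts.
#' @return object of class `kernel_kmeans_result`: list with `labels`
#'   (integers 1..k, one per row of `kernel`), `embedding` (n x k
#'   orthonormal U), `relaxed_objective` (sum of the k largest
#'   eigenvalues = tr(U'KU)), `restart_inertias`.
#' @export
kernel_kmeans <- function(kernel, k, n_restarts = 10L, seed = 0L) {
  kernel <- as.matrix(kernel)
  n <- nrow(kernel)
  if (n != ncol(kernel))
    stop_lfimc("kernel must be square", "lfimc_dimension_error")
  if (max(abs(kernel - t(kernel))) > SYMMETRY_TOL)
    stop_lfimc("kernel must be symmetric", "lfimc_symmetry_error")
  kernel <- (kernel + t(kernel)) / 2
  if (k < 2L) stop_lfimc("k must be at least 2", "lfimc_validation_error")
  if (n < k)
    stop_lfimc(sprintf("too few visible instances: n = %d < k = %d", n, k),
               "lfimc_validation_error")
  eig <- eigen(kernel, symmetric = TRUE)
  u <- eig$vectors[, seq_len(k), drop = FALSE]
  relaxed <- sum(eig$values[seq_len(k)])
  embed <- u %*% diag(sqrt(pmax(eig$values[seq_len(k)], 0)), k)
  runs <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_restarts), function(r) kmeanspp_lloyd_once(embed, k))
  })
  inertias <- vapply(runs, `[[`, numeric(1), "inertia")
  best <- runs[[which.min(inertias)]]
  structure(
    list(labels = as.integer(best$cluster), embedding = u,
         relaxed_objective = relaxed, restart_inertias = inertias),
    class = "kernel_kmeans_result"
  )
}

#' Kernel k-means objective of a discrete partition
#'
#' Evaluates the exact (unrelaxed) kernel k-means sum-of-squares,
#' tr(K) - sum_c (1/N_c) sum_{i,l in c} K\[i,l\], for a given hard
#' partition. Used to compare candidate partitions on the same kernel and
#' as the quantity the spectral relaxation approximately minimizes.
#'
#' @param kernel symmetric n x n matrix.
#' @param labels integer labels (1-based) of length n; clusters may be empty.
#' @return scalar objective value.
#' @export
kernel_kmeans_objective <- function(kernel, labels) {
  kernel <- as.matrix(kernel)
  labels <- as.integer(labels)
  obj <- sum(diag(kernel))
  for (c in unique(labels)) {
    idx <- which(labels == c)
    obj <- obj - sum(kernel[idx, idx]) / length(idx)
  }
  obj
}

#' Cluster the visible instances of each view
#'
#' For each view j: extracts the principal sub-kernel of the visible
#' instances (mask column j), applies [center_and_scale], runs
#' [kernel_kmeans] with per-view seed `seed + j - 1`, and scatters the
#' labels back into an N x K indicator matrix whose missing rows are
#' all-zero.
#'
#' @param data a [multiview_kernel_data] object.
#' @param k number of clusters.
#' @param n_restarts k-means restarts per view.
#' @param seed base seed; view j uses `seed + j - 1`.
#' @return list of P [view_assignment] objects, with per-view
#'   `kernel_kmeans_result`s attached as attribute `"results"`.
#' @export
cluster_each_view <- function(data, k, n_restarts = 10L, seed = 0L) {
  stopifnot(inherits(data, "multiview_kernel_data"))
  n <- data$n_samples
  out <- vector("list", data$n_views)
  results <- vector("list", data$n_views)
  for (j in seq_len(data$n_views)) {
    vis <- which(data$mask[, j] == 1)
    if (length(vis) < k)
      stop_lfimc(sprintf("view %d has %d visible instances; fewer than k = %d",
                         j, length(vis), k), "lfimc_validation_error")
    sub <- data$kernels[[j]][vis, vis, drop = FALSE]
    sub <- suppressWarnings(center_and_scale(sub))
    res <- kernel_kmeans(sub, k, n_restarts = n_restarts, seed = seed + j - 1L)
    z <- matrix(0, n, k)
    z[cbind(vis, res$labels)] <- 1
    out[[j]] <- view_assignment(z, j, mask_col = data$mask[, j])
    results[[j]] <- res
  }
  attr(out, "results") <- results
  out
}
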