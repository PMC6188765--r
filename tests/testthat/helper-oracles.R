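# Independent oracles and small fixture builders. Everything here is
# deliberately brute-force and stays independent of the package's own
# computation paths.

# Masked late-fusion objective evaluated term by term (triple loop).
brute_objective <- function(y, centroid_list, zs, mask) {
  total <- 0
  for (j in seq_along(zs)) {
    for (i in seq_len(nrow(y))) {
      for (c in seq_len(ncol(y))) {
        if (y[i, c] == 1 && mask[i, j] == 1) {
          total <- total + sum((zs[[j]][i, ] - centroid_list[[j]][c, ])^2)
        }
      }
    }
  }
  total
}

# Exhaustive minimum of the decision subproblem over all K^N assignments,
# for fixed centroids.
brute_best_decision <- function(centroid_list, zs, mask, k) {
  n <- nrow(zs[[1L]])
  best <- Inf
  grid <- rep(list(seq_len(k)), n)
  combos <- do.call(expand.grid, grid)
  for (r in seq_len(nrow(combos))) {
    y <- labels_to_indicator(as.integer(unlist(combos[r, ])), k)
    val <- brute_objective(y, centroid_list, zs, mask)
    if (val < best) best <- val
  }
  best
}

# Exact kernel k-means objective of a hard partition, computed from the
# definition via per-cluster block sums (no package code).
brute_kkm_objective <- function(kernel, labels) {
  obj <- sum(diag(kernel))
  for (c in unique(labels)) {
    idx <- which(labels == c)
    obj <- obj - sum(kernel[idx, idx]) / length(idx)
  }
  obj
}

# Global optimum of kernel k-means over all 2-partitions with both
# clusters nonempty.
brute_best_2partition <- function(kernel) {
  n <- nrow(kernel)
  best <- Inf
  for (code in 1:(2^(n - 1) - 1)) {
    lab <- as.integer(intToBits(code))[seq_len(n)] + 1L
    best <- min(best, brute_kkm_objective(kernel, lab))
  }
  best
}

# Clustering accuracy by exhaustive search over label permutations.
brute_acc <- function(pred, true) {
  ks <- sort(unique(true))
  ps <- sort(unique(pred))
  k <- max(length(ks), length(ps))
  perms <- lfimc:::all_permutations(k)
  best <- 0
  for (r in seq_len(nrow(perms))) {
    mapped <- perms[r, match(pred, ps)]
    best <- max(best, mean(mapped == match(true, ks)))
  }
  best
}

# Random fusion instance: Z^j one-hot on visible rows, mask with no
# all-zero row, random defined centroids.
random_fusion_instance <- function(n, k, p, seed) {
  withr::with_seed(seed, {
    repeat {
      mask <- matrix(rbinom(n * p, 1, 0.7), n, p)
      if (all(rowSums(mask) > 0)) break
    }
    zs <- lapply(seq_len(p), function(j) {
      lab <- sample.int(k, n, replace = TRUE)
      z <- labels_to_indicator(lab, k)
      z[mask[, j] == 0, ] <- 0
      z
    })
    centroid_list <- lapply(seq_len(p), function(j)
      matrix(runif(k * k), k, k))
    y <- labels_to_indicator(sample.int(k, n, replace = TRUE), k)
    list(mask = mask, zs = zs, centroid_list = centroid_list, y = y)
  })
}

# A small two-view kernel set with block structure, written to temp files.
write_tiny_kernel_set <- function(dir, n = 6, p = 2) {
  x <- rbind(matrix(0.1, n / 2, 2), matrix(2, n / 2, 2))
  kernels <- lapply(seq_len(p), function(j) tcrossprod(x) + diag(n) * 0.01)
  paths <- file.path(dir, sprintf("kernel%d.tsv", seq_len(p)))
  for (j in seq_len(p)) write_matrix(kernels[[j]], paths[j])
  mask <- matrix(1, n, p)
  mask_path <- file.path(dir, "mask.tsv")
  write_matrix(mask, mask_path)
  list(paths = paths, mask_path = mask_path, kernels = kernels, mask = mask)
}
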