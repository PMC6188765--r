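make_incomplete <- function(seed = 1, n = 12, p = 3) {
  d <- synthetic_multiview(n_samples = n, n_views = p, n_clusters = 2,
                           dims = 3, seed = seed)
  mask <- generate_mask(n, p, epsilon = 0.5, seed = seed + 1)
  set_mask(d, mask)
}

test_that("every fill method is the identity on fully visible data", {
  d <- synthetic_multiview(n_samples = 10, n_views = 2, n_clusters = 2,
                           dims = 3, seed = 2)
  for (f in list(zero_fill, mean_fill, function(x) knn_fill(x, 3), af_fill)) {
    out <- f(d)
    expect_equal(out$kernels, d$kernels)
    expect_equal(sum(out$n_imputed), 0)
  }
})

test_that("fill methods preserve visible-visible entries and symmetry", {
  d <- make_incomplete(seed = 5)
  for (f in list(zero_fill, mean_fill, function(x) knn_fill(x, 3), af_fill)) {
    out <- suppressWarnings(f(d))
    for (j in seq_len(d$n_views)) {
      expect_lt(max(abs(out$kernels[[j]] - t(out$kernels[[j]]))), 1e-8)
      vis <- d$mask[, j] == 1
      expect_equal(out$kernels[[j]][vis, vis], d$kernels[[j]][vis, vis])
    }
  }
})

test_that("zero filling zeroes exactly the rows/columns of missing samples", {
  d <- make_incomplete(seed = 7, n = 5, p = 2)
  d$mask <- matrix(1, 5, 2)
  d$mask[2, 1] <- 0
  out <- zero_fill(d)
  expect_equal(out$kernels[[1]][2, ], rep(0, 5))
  expect_equal(out$kernels[[1]][, 2], rep(0, 5))
  expect_equal(out$n_imputed[1], 2 * 5 - 1)
  expect_equal(out$n_imputed[2], 0)
  vis <- c(1, 3, 4, 5)
  expect_equal(out$kernels[[1]][vis, vis], d$kernels[[1]][vis, vis])
})

test_that("mean filling averages the corresponding visible entries of other views", {
  k1 <- matrix(0.1, 3, 3); diag(k1) <- 1
  k2 <- matrix(0.7, 3, 3); diag(k2) <- 1
  k3 <- matrix(0.3, 3, 3); diag(k3) <- 1
  mask <- cbind(c(1, 0, 1), c(1, 1, 1), c(1, 1, 1))
  d <- multiview_kernel_data(list(k1, k2, k3), mask, check_psd = FALSE)
  out <- mean_fill(d)
  # entry (2,1) missing in view 1, visible in views 2 and 3 -> (0.7 + 0.3) / 2
  expect_equal(out$kernels[[1]][2, 1], 0.5)
  # single other view
  d2 <- multiview_kernel_data(list(k1, k2), mask[, 1:2], check_psd = FALSE)
  expect_equal(mean_fill(d2)$kernels[[1]][2, 1], 0.7)
  # samples 2 and 3 share no visible view -> entry (2,3) filled with 0
  mask3 <- rbind(c(1, 1), c(1, 0), c(0, 1))
  d3 <- multiview_kernel_data(list(k1, k2), mask3, check_psd = FALSE)
  expect_warning(out3 <- mean_fill(d3), "filled with 0")
  expect_equal(out3$kernels[[1]][2, 3], 0)
  expect_equal(out3$kernels[[2]][2, 3], 0)
})

test_that("knn filling copies an exact duplicate neighbour and respects blocks", {
  # sample 2 is missing in view 1 but duplicates sample 1 in view 2
  x <- rbind(c(0, 0), c(0, 0), c(5, 5), c(5.1, 5), c(0.2, 0.1), c(4.9, 5.2))
  k <- tcrossprod(x)
  mask <- cbind(c(1, 0, 1, 1, 1, 1), rep(1, 6))
  d <- multiview_kernel_data(list(k, k), mask, check_psd = FALSE)
  out <- knn_fill(d, k_neighbors = 1)
  vis <- c(1, 3, 4, 5, 6)
  expect_equal(out$kernels[[1]][2, vis], k[1, vis])
  expect_equal(out$kernels[[1]][2, 2], k[1, 1])
  # block structure: the imputed row is closer to its own block
  d2 <- make_incomplete(seed = 9, n = 16)
  out2 <- knn_fill(d2, 3)
  mis <- which(d2$mask[, 1] == 0)
  if (length(mis) > 0) {
    i <- mis[1]
    same <- which(d2$labels == d2$labels[i] & d2$mask[, 1] == 1)
    other <- which(d2$labels != d2$labels[i] & d2$mask[, 1] == 1)
    expect_gt(mean(out2$kernels[[1]][i, same]), mean(out2$kernels[[1]][i, other]))
  }
  expect_error(knn_fill(d, k_neighbors = 0), class = "lfimc_validation_error")
})

test_that("alignment-style filling copies the zero-filled consensus", {
  k1 <- matrix(0.4, 3, 3); diag(k1) <- 1
  k2 <- matrix(0.6, 3, 3); diag(k2) <- 1
  mask <- cbind(c(1, 0, 1), c(1, 1, 1))
  d <- multiview_kernel_data(list(k1, k2), mask, check_psd = FALSE)
  out <- af_fill(d)
  # missing entry (2,1) of view 1: zero-filled values are 0 and 0.6 -> C = 0.3
  expect_equal(out$kernels[[1]][2, 1], 0.3)
  # single view: the consensus is the zero-filled kernel, so af == zf
  d1 <- multiview_kernel_data(list(k1), matrix(1, 3, 1), check_psd = FALSE)
  expect_equal(af_fill(d1)$kernels[[1]], zero_fill(d1)$kernels[[1]])
})

test_that("multiple kernel k-means reduces to single-view clustering on identical kernels", {
  d <- synthetic_multiview(n_samples = 30, n_views = 1, n_clusters = 3,
                           dims = 4, seed = 10)
  k1 <- d$kernels[[1]]
  y_multi <- multiple_kernel_kmeans(list(k1, k1, k1), 3, n_restarts = 5, seed = 11)
  y_single <- multiple_kernel_kmeans(list(k1), 3, n_restarts = 5, seed = 11)
  expect_equal(nmi(indicator_to_labels(y_multi), indicator_to_labels(y_single)), 1)
  y_again <- multiple_kernel_kmeans(list(k1, k1, k1), 3, n_restarts = 5, seed = 11)
  expect_identical(unclass(y_multi), unclass(y_again))
})

test_that("combining complementary views beats each single view", {
  # each view merges a different cluster pair: individually imperfect
  d <- synthetic_multiview(n_samples = 80, n_views = 2, n_clusters = 4,
                           dims = 6, separation = 6, noise_scale = 0.5,
                           merge_pairs = list(c(1, 2), c(3, 4)), seed = 12)
  single <- vapply(1:2, function(j) {
    nmi(indicator_to_labels(multiple_kernel_kmeans(d$kernels[j], 4, seed = 13)),
        d$labels)
  }, numeric(1))
  combined <- nmi(indicator_to_labels(multiple_kernel_kmeans(d$kernels, 4, seed = 13)),
                  d$labels)
  expect_gte(combined, max(single))
})

test_that("best_single_view picks the informative view and completes it reproducibly", {
  d <- make_incomplete(seed = 20, n = 20)
  a <- cluster_each_view(d, 2, n_restarts = 5, seed = 21)
  # a perfect oracle view among the per-view results
  perfect <- labels_to_indicator(d$labels, 2)
  perfect[d$mask[, 1] == 0, ] <- 0
  zs <- list(perfect, a[[2]]$matrix, a[[3]]$matrix)
  y <- best_single_view(d, zs, seed = 22)
  expect_equal(attr(y, "best_view"), 1)
  mis <- which(d$mask[, 1] == 0)
  expect_equal(indicator_to_labels(y)[-mis], d$labels[-mis])
  # exactly the missing rows are random; same seed -> identical
  y2 <- best_single_view(d, zs, seed = 22)
  expect_identical(unclass(y), unclass(y2))
  # chosen view fully visible -> partition returned exactly
  dfull <- synthetic_multiview(n_samples = 20, n_views = 2, n_clusters = 2,
                               dims = 3, seed = 23)
  afull <- cluster_each_view(dfull, 2, n_restarts = 5, seed = 24)
  yfull <- best_single_view(dfull, afull, seed = 25)
  best <- attr(yfull, "best_view")
  expect_equal(unclass(yfull), afull[[best]]$matrix, ignore_attr = TRUE)
  expect_error(best_single_view(dfull, afull, truth = NULL),
               class = "lfimc_validation_error")
})
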