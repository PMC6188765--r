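test_that("fusion objective matches hand-evaluated cases", {
  # all views agree, Y equals the shared partition, unit-vector centroids
  y <- labels_to_indicator(c(1, 2, 1), 2)
  m <- centroid_set(list(diag(2), diag(2)), matrix(TRUE, 2, 2))
  expect_equal(fusion_objective(y, m, list(y, y), matrix(1, 3, 2)), 0)

  # one instance flipped in view 2: objective = ||Z2[i,] - M[c(i),]||^2
  z1 <- labels_to_indicator(c(1, 2, 1, 2), 2)
  z2 <- labels_to_indicator(c(1, 2, 2, 2), 2)
  m2 <- update_centroids(z1, list(z1, z2), matrix(1, 4, 2))
  expect_equal(fusion_objective(z1, m2, list(z1, z2), matrix(1, 4, 2)),
               brute_objective(z1, m2$centroids, list(z1, z2), matrix(1, 4, 2)))

  # masked terms contribute exactly zero
  mask <- cbind(c(1, 1, 0, 1), c(1, 1, 1, 1))
  z1m <- z1; z1m[3, ] <- 0
  m3 <- update_centroids(z1, list(z1m, z2), mask)
  expect_equal(fusion_objective(z1, m3, list(z1m, z2), mask),
               brute_objective(z1, m3$centroids, list(z1m, z2), mask))
})

test_that("centroid update takes masked means and flags undefined pairs", {
  # singleton means
  z <- labels_to_indicator(c(1, 2), 2)
  m <- update_centroids(z, list(z), matrix(1, 2, 1))
  expect_equal(m$centroids[[1]], diag(2))
  expect_true(all(m$defined))

  # masked-out cluster member: zero denominator, previous value retained
  mask <- matrix(c(1, 0), 2, 1)
  zmask <- z; zmask[2, ] <- 0
  m2 <- update_centroids(z, list(zmask), mask, previous = m)
  expect_equal(m2$centroids[[1]][2, ], c(0, 1))   # retained from `m`
  expect_false(m2$defined[1, 2])
  expect_true(m2$defined[1, 1])

  # without a previous set, fallback = global mean of visible rows
  m3 <- update_centroids(z, list(zmask), mask, previous = NULL)
  expect_equal(m3$centroids[[1]][2, ], c(1, 0))   # only visible row is e1
  expect_false(m3$defined[1, 2])

  # arithmetic mean of one-hot rows; rows of defined centroids sum to 1
  z4 <- labels_to_indicator(c(1, 2, 1, 2), 2)     # view partition
  y4 <- labels_to_indicator(c(1, 1, 2, 2), 2)     # consensus groups {1,2},{3,4}
  m4 <- update_centroids(y4, list(z4), matrix(1, 4, 1))
  expect_equal(m4$centroids[[1]][1, ], c(0.5, 0.5))
  expect_equal(rowSums(m4$centroids[[1]]), c(1, 1))
})

test_that("centroid update minimizes the objective: any perturbation increases it", {
  for (s in 1:25) {
    inst <- random_fusion_instance(n = 6, k = 3, p = 2, seed = 100 + s)
    m <- update_centroids(inst$y, inst$zs, inst$mask)
    base <- brute_objective(inst$y, m$centroids, inst$zs, inst$mask)
    for (delta in c(1e-3, 1e-1)) {
      j <- 1 + (s %% 2)
      c <- 1 + (s %% 3)
      if (!m$defined[j, c]) next
      for (coord in 1:3) for (sign in c(-1, 1)) {
        pert <- m$centroids
        pert[[j]][c, coord] <- pert[[j]][c, coord] + sign * delta
        expect_gte(brute_objective(inst$y, pert, inst$zs, inst$mask),
                   base - 1e-12)
      }
    }
  }
})

test_that("decision update is the exact argmin with sticky tie-breaking", {
  # strict argmin
  m <- centroid_set(list(rbind(c(1, 0), c(0, 1))), matrix(TRUE, 1, 2))
  z <- labels_to_indicator(c(1, 2), 2)
  prev <- labels_to_indicator(c(2, 2), 2)
  upd <- update_decision(m, list(z), matrix(1, 2, 1), prev)
  expect_equal(indicator_to_labels(upd$decision), c(1L, 2L))
  expect_true(all(upd$cost >= 0))

  # exact tie keeps the previous cluster
  mtie <- centroid_set(list(rbind(c(0.5, 0.5), c(0.5, 0.5))), matrix(TRUE, 1, 2))
  upd2 <- update_decision(mtie, list(z), matrix(1, 2, 1), prev)
  expect_equal(indicator_to_labels(upd2$decision), c(2L, 2L))

  # tie with previous cluster not among minimizers -> lowest index
  g_case <- centroid_set(list(rbind(c(1, 0), c(1, 0))), matrix(TRUE, 1, 2))
  upd3 <- update_decision(g_case, list(z), matrix(1, 2, 1),
                          labels_to_indicator(c(1, 1), 2))
  expect_equal(indicator_to_labels(upd3$decision)[1], 1L)
})

test_that("decision update attains the exhaustive minimum over all assignments", {
  for (s in 1:30) {
    inst <- random_fusion_instance(n = 5, k = 3, p = 2, seed = 200 + s)
    m <- centroid_set(inst$centroid_list, matrix(TRUE, 2, 3))
    upd <- update_decision(m, inst$zs, inst$mask, inst$y)
    got <- brute_objective(upd$decision, inst$centroid_list, inst$zs, inst$mask)
    best <- brute_best_decision(inst$centroid_list, inst$zs, inst$mask, 3)
    expect_equal(got, best, tolerance = 1e-12)
  }
})

test_that("fuse: identical complete views and matching Y0 is a fixed point", {
  z <- labels_to_indicator(c(1, 1, 2, 2, 3, 3), 3)
  st <- fuse(list(z, z, z), matrix(1, 6, 3), z)
  expect_true(st$converged)
  expect_equal(st$n_iterations, 1)
  expect_equal(st$objective_trace, c(0, 0))
  expect_equal(st$decision, z)
})

test_that("fuse: objective trace is non-increasing and runs converge", {
  for (s in 1:10) {
    d <- synthetic_multiview(n_samples = 60, n_views = 3, n_clusters = 3,
                             dims = 5, seed = 300 + s)
    mask <- generate_mask(60, 3, epsilon = 0.5, seed = 400 + s)
    d <- set_mask(d, mask)
    res <- run_late_fusion(d, 3, init_method = "zf", n_restarts = 5,
                           seed = 500 + s)
    tr <- res$state$objective_trace
    expect_true(all(diff(tr) <= 1e-9))
    expect_true(all(tr >= 0))
    expect_true(res$state$converged)
    expect_lt(res$state$n_iterations, 200)
  }
})

test_that("fuse is invariant to permuting the cluster columns of one view", {
  d <- synthetic_multiview(n_samples = 50, n_views = 3, n_clusters = 3,
                           dims = 5, seed = 600)
  mask <- generate_mask(50, 3, epsilon = 0.5, seed = 601)
  d <- set_mask(d, mask)
  a <- cluster_each_view(d, 3, n_restarts = 5, seed = 602)
  y0 <- initial_decision(d, 3, "zf", seed = 602)
  zs <- lapply(a, function(v) v$matrix)
  st1 <- suppressWarnings(fuse(zs, d$mask, y0))
  perm <- c(3, 1, 2)
  zs2 <- zs
  zs2[[2]] <- zs2[[2]][, perm]
  st2 <- suppressWarnings(fuse(zs2, d$mask, y0))
  expect_identical(st1$decision, st2$decision)
})

test_that("objective decomposes as the sum of per-view visible objectives", {
  inst <- random_fusion_instance(n = 8, k = 3, p = 3, seed = 700)
  m <- update_centroids(inst$y, inst$zs, inst$mask)
  total <- fusion_objective(inst$y, m, inst$zs, inst$mask)
  per_view <- vapply(1:3, function(j) {
    mj <- centroid_set(m$centroids[j], m$defined[j, , drop = FALSE])
    fusion_objective(inst$y, mj, inst$zs[j], inst$mask[, j, drop = FALSE])
  }, numeric(1))
  expect_equal(total, sum(per_view), tolerance = 1e-12)
})

test_that("fuse validates its inputs", {
  z <- labels_to_indicator(c(1, 2), 2)
  expect_error(fuse(list(z), matrix(1, 2, 1), z, max_iter = 0),
               class = "lfimc_validation_error")
  expect_error(fuse(list(z), matrix(c(1, 0), 2, 1), z),
               class = "lfimc_validation_error")  # Z row 2 one-hot but masked
})
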