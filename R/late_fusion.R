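# Consensus step: alternating minimization of the masked sum of per-view
# k-means objectives over the visible compressed representations,
#   min_{Y, M}  sum_j sum_c sum_i  Y[i,c] S[i,j] || Z^j[i,] - M^j[c,] ||^2
# with Y a zero-one N x K decision (rows sum to 1) and M^j[c,] the centroid
# of cluster c in the compressed space of view j.

TIE_TOL <- 1e-12

#' Per-(view, cluster) centroid set
#'
#' Centroids of the consensus clusters in each view's compressed (indicator)
#' space: a list of P matrices, each K x K, row c the centroid M^j\[c,\] of
#' cluster c in view j, plus a P x K logical matrix `defined` flagging
#' (view, cluster) pairs that had at least one visible member at the last
#' update. An undefined centroid keeps its previous value (any value is
#' optimal when its terms are absent from the objective) and is flagged so.
#'
#' @param centroids list of P numeric K x K matrices.
#' @param defined P x K logical matrix.
#' @return object of class `centroid_set`.
#' @export
centroid_set <- function(centroids, defined) {
  stopifnot(is.list(centroids), is.matrix(defined),
            length(centroids) == nrow(defined))
  for (m in centroids)
    if (any(!is.finite(m)))
      stop_lfimc("centroids must be finite", "lfimc_validation_error")
  structure(list(centroids = centroids, defined = defined), class = "centroid_set")
}

#' Late-fusion objective value
#'
#' Evaluates the masked consensus objective
#' sum_j sum_c sum_i Y\[i,c\] S\[i,j\] ||Z^j\[i,\] - M^j\[c,\]||^2.
#' Terms with S\[i,j\] = 0 contribute exactly 0; undefined centroids carry
#' their stored (previous or fallback) value.
#'
#' @param decision zero-one N x K consensus decision Y.
#' @param centroids a [centroid_set].
#' @param assignments list of P per-view indicator matrices (or
#'   [view_assignment] objects).
#' @param mask N x P zero-one visibility matrix.
#' @return nonnegative scalar.
#' @export
fusion_objective <- function(decision, centroids, assignments, mask) {
  y <- validate_decision(decision)
  g <- assignment_cost(centroids, assignments, mask)
  sum(y * g)
}

#' Masked assignment-cost matrix
#'
#' The N x K matrix G with G\[i,c\] = sum_j S\[i,j\] ||Z^j\[i,\] - M^j\[c,\]||^2:
#' the cost of placing sample i in consensus cluster c, accumulated over
#' the views where i is visible.
#'
#' @inheritParams fusion_objective
#' @return nonnegative N x K matrix.
#' @export
assignment_cost <- function(centroids, assignments, mask) {
  stopifnot(inherits(centroids, "centroid_set"))
  zs <- assignment_matrices(assignments)
  mask <- as.matrix(mask)
  n <- nrow(mask)
  k <- ncol(zs[[1L]])
  if (ncol(centroids$centroids[[1L]]) != k || nrow(centroids$centroids[[1L]]) != k)
    stop_lfimc("centroid dimension does not match K of the assignments",
               "lfimc_dimension_error")
  g <- matrix(0, n, k)
  for (j in seq_along(zs)) {
    z <- zs[[j]]
    if (ncol(z) != k || nrow(z) != n)
      stop_lfimc("assignment dimensions inconsistent across views",
                 "lfimc_dimension_error")
    m <- centroids$centroids[[j]]
    vis <- which(mask[, j] == 1)
    zv <- z[vis, , drop = FALSE]
    d <- outer(rowSums(zv^2), rowSums(m^2), "+") - 2 * tcrossprod(zv, m)
    g[vis, ] <- g[vis, ] + pmax(d, 0)
  }
  g
}

#' Consensus decision update (argmin over clusters)
#'
#' Given fixed centroids, assigns each sample to the cluster minimizing its
#' masked cost G\[i,c\] — the exact minimizer of the objective in Y.
#' Tie-breaking is sticky: if the previous cluster is within `1e-12` of the
#' row minimum it is kept, otherwise the lowest-index minimizer is taken
#' (prevents limit cycles on exact ties and makes convergence by
#' Y-stability well-defined).
#'
#' @inheritParams fusion_objective
#' @param previous the previous decision (used only for tie-breaking).
#' @return list with `decision` (new zero-one N x K matrix) and `cost`
#'   (the G matrix).
#' @export
update_decision <- function(centroids, assignments, mask, previous) {
  g <- assignment_cost(centroids, assignments, mask)
  prev <- validate_decision(previous)
  n <- nrow(g); k <- ncol(g)
  prev_lab <- indicator_to_labels(prev)
  lab <- integer(n)
  rowmin <- do.call(pmin, lapply(seq_len(k), function(c) g[, c]))
  for (i in seq_len(n)) {
    cand <- which(g[i, ] <= rowmin[i] + TIE_TOL)
    lab[i] <- if (prev_lab[i] %in% cand) prev_lab[i] else cand[1L]
  }
  list(decision = labels_to_indicator(lab, k), cost = g)
}

#' Centroid update (per-(view, cluster) masked means)
#'
#' Given a fixed decision Y, sets each centroid to the mean of the visible
#' compressed representations of its cluster members,
#' M^j\[c,\] = sum_i Y\[i,c\] S\[i,j\] Z^j\[i,\] / sum_i Y\[i,c\] S\[i,j\] —
#' the exact minimizer of the objective in M. When a (view, cluster) pair
#' has no visible member the denominator is 0: the previous centroid is
#' retained with `defined = FALSE` (its terms are absent from the
#' objective, so any value is optimal and monotonicity is preserved). With
#' `previous = NULL` (initialization) such centroids fall back to the
#' global mean of the view's visible compressed rows.
#'
#' Each defined centroid is a convex combination of one-hot rows: entries
#' in \[0, 1\] summing to 1.
#'
#' @inheritParams fusion_objective
#' @param previous a [centroid_set] or NULL.
#' @return a [centroid_set].
#' @export
update_centroids <- function(decision, assignments, mask, previous = NULL) {
  y <- validate_decision(decision)
  zs <- assignment_matrices(assignments)
  mask <- as.matrix(mask)
  p <- length(zs)
  k <- ncol(y)
  centroids <- vector("list", p)
  defined <- matrix(FALSE, p, k)
  for (j in seq_len(p)) {
    z <- zs[[j]]
    sj <- mask[, j]
    w <- y * sj                      # N x K weights Y[i,c] S[i,j]
    num <- crossprod(w, z)           # K x K: row c = sum_i w[i,c] z[i,]
    den <- colSums(w)
    m <- matrix(0, k, ncol(z))
    ok <- den > 0
    m[ok, ] <- num[ok, , drop = FALSE] / den[ok]
    if (any(!ok)) {
      if (!is.null(previous)) {
        m[!ok, ] <- previous$centroids[[j]][!ok, , drop = FALSE]
      } else {
        vis <- sj == 1
        fallback <- if (any(vis)) colMeans(z[vis, , drop = FALSE]) else rep(1 / ncol(z), ncol(z))
        m[!ok, ] <- matrix(fallback, sum(!ok), ncol(z), byrow = TRUE)
      }
    }
    centroids[[j]] <- m
    defined[j, ] <- ok
  }
  centroid_set(centroids, defined)
}

#' Late fusion of per-view partitions by alternating minimization
#'
#' Learns the consensus decision Y from the per-view indicator matrices
#' Z^j and the visibility mask. Starting from a user-supplied (or
#' baseline-derived, see [initial_decision]) Y0, centroids are initialized
#' by [update_centroids] from Y0, then the decision update and centroid
#' update alternate until Y is unchanged over a full iteration (exact
#' equality — the classic k-means stopping rule) or `max_iter` is reached.
#' The objective value is recorded before the first iteration and after
#' each full (Y, M) iteration; the trace is non-increasing and bounded
#' below by 0, so the iteration converges.
#'
#' Consensus clusters may end up empty (K is prior knowledge and the
#' objective never forces K nonempty clusters); a warning is issued.
#'
#' @param assignments list of P per-view indicator matrices or
#'   [view_assignment] objects (all-zero rows for missing instances).
#' @param mask N x P zero-one visibility matrix.
#' @param initial_decision zero-one N x K matrix Y0, rows summing to 1.
#' @param max_iter iteration cap (safety net; default 200).
#' @param init_method free-form tag recorded in the result.
#' @return object of class `fusion_state`: list with `decision` (final Y),
#'   `centroids` ([centroid_set]), `objective_trace`, `n_iterations`,
#'   `converged`, `init_method`.
#' @examples
#' z <- labels_to_indicator(c(1, 1, 2, 2))
#' st <- fuse(list(z, z), matrix(1, 4, 2), z)
#' st$converged; st$objective_trace
#' @export
fuse <- function(assignments, mask, initial_decision, max_iter = 200L,
                 init_method = "user") {
  if (max_iter < 1L) stop_lfimc("max_iter must be >= 1", "lfimc_validation_error")
  y <- validate_decision(initial_decision)
  mask <- as.matrix(mask)
  zs <- assignment_matrices(assignments)
  # visible rows of Z must be one-hot exactly where the mask says so
  for (j in seq_along(zs)) {
    rs <- rowSums(zs[[j]])
    if (!all((rs == 0) == (mask[, j] == 0)))
      stop_lfimc(sprintf("assignment %d rows inconsistent with mask column %d", j, j),
                 "lfimc_validation_error")
  }
  m <- update_centroids(y, zs, mask, previous = NULL)
  trace <- fusion_objective(y, m, zs, mask)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    upd <- update_decision(m, zs, mask, previous = y)
    y_new <- upd$decision
    m <- update_centroids(y_new, zs, mask, previous = m)
    trace <- c(trace, fusion_objective(y_new, m, zs, mask))
    if (identical(y_new, y)) {
      converged <- TRUE
      y <- y_new
      break
    }
    y <- y_new
  }
  if (any(colSums(y) == 0))
    warning(sprintf("%d of %d consensus clusters are empty", sum(colSums(y) == 0), ncol(y)))
  structure(
    list(decision = y, centroids = m, objective_trace = trace,
         n_iterations = iter, converged = converged, init_method = init_method),
    class = "fusion_state"
  )
}

#' @export
print.fusion_state <- function(x, ...) {
  cat(sprintf("late-fusion state: N = %d, K = %d\n", nrow(x$decision), ncol(x$decision)))
  cat(sprintf("  init: %s; iterations: %d; converged: %s\n",
              x$init_method, x$n_iterations, x$converged))
  cat(sprintf("  objective: %.6g -> %.6g\n",
              x$objective_trace[1L], x$objective_trace[length(x$objective_trace)]))
  invisible(x)
}
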