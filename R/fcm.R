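#' Fuzzy C-means clustering of intensities
#'
#' One-dimensional fuzzy C-means, the soft clustering used to separate
#' fat from fibroglandular tissue by T1 intensity. Minimises the fuzzy
#' objective `J_m = sum_ij u_ij^m d_ij^2` by alternating updates of the
#' memberships
#' `u_ij = 1 / sum_k (d_ij / d_ik)^(2/(m-1))`
#' and the centroids `c_j = sum_i u_ij^m x_i / sum_i u_ij^m`, until the
#' largest centroid shift drops below `tol` or `max_iter` is reached.
#' A sample sitting exactly on a centroid gets membership 1 there and 0
#' elsewhere. Initial centroids are placed at evenly spaced quantiles of
#' the data, so the fit is deterministic; `seed` only matters if
#' `init = "random"`.
#'
#' @param values numeric vector of samples (intensities).
#' @param n_clusters number of clusters `c >= 2`.
#' @param fuzziness fuzzifier `m > 1` (2 is the conventional default).
#' @param tol convergence tolerance on the maximum centroid shift.
#' @param max_iter iteration cap.
#' @param seed integer seed, used only for random initialisation.
#' @param init `"quantile"` (deterministic, default) or `"random"`.
#' @return An object of class `fcm_result`: `centroids` (ascending),
#'   `memberships` (n x c matrix, rows sum to 1), `objective` (per
#'   iteration, non-increasing), `iterations`, `converged`.
#' @export
fcm_cluster <- function(values, n_clusters = 2L, fuzziness = 2,
                        tol = 1e-5, max_iter = 300L, seed = 1L,
                        init = c("quantile", "random")) {
  init <- match.arg(init)
  x <- as.numeric(values)
  if (any(!is.finite(x))) stop("'values' must be finite")
  c <- as.integer(n_clusters)
  if (c < 2L) stop("'n_clusters' must be >= 2")
  if (fuzziness <= 1) stop("'fuzziness' must be > 1")
  if (tol <= 0) stop("'tol' must be > 0")
  if (length(unique(x)) < c)
    stop(sprintf("need at least %d distinct values, got %d",
                 c, length(unique(x))))
  n <- length(x)
  cent <- if (init == "quantile") {
    as.numeric(stats::quantile(x, probs = (seq_len(c) - 0.5) / c,
                               names = FALSE, type = 7))
  } else {
    set.seed(seed)
    sort(sample(unique(x), c))
  }
  # collapse coincident initial centroids (possible for skewed data)
  cent <- sort(cent)
  if (any(diff(cent) == 0))
    cent <- seq(min(x), max(x), length.out = c)
  expo <- 2 / (fuzziness - 1)
  obj <- numeric(0)
  converged <- FALSE
  iter <- 0L
  u <- NULL
  for (iter in seq_len(max_iter)) {
    d2 <- outer(x, cent, function(a, b) (a - b)^2)
    u <- fcm_memberships(d2, expo)
    um <- u^fuzziness
    new_cent <- as.numeric(crossprod(um, x) / colSums(um))
    new_cent <- sort(new_cent)
    obj <- c(obj, sum(um * d2))
    shift <- max(abs(new_cent - cent))
    cent <- new_cent
    if (shift < tol) { converged <- TRUE; break }
  }
  d2 <- outer(x, cent, function(a, b) (a - b)^2)
  u <- fcm_memberships(d2, expo)
  structure(list(centroids = cent, memberships = u, objective = obj,
                 iterations = iter, converged = converged,
                 fuzziness = fuzziness),
            class = "fcm_result")
}

# membership update with the zero-distance convention: a sample at a
# centroid belongs entirely to that cluster (split evenly on exact ties)
fcm_memberships <- function(d2, expo) {
  inv <- d2^(-expo / 2)
  zero <- d2 == 0
  hit <- rowSums(zero) > 0
  u <- inv / rowSums(inv)
  if (any(hit)) {
    u[hit, ] <- 0
    u[hit, ] <- zero[hit, , drop = FALSE] /
      rowSums(zero[hit, , drop = FALSE])
  }
  u
}

#' @export
print.fcm_result <- function(x, ...) {
  cat(sprintf("fcm_result: %d clusters, centroids (%s), %d iteration(s)%s\n",
              length(x$centroids),
              paste(signif(x$centroids, 6), collapse = ", "),
              x$iterations,
              if (x$converged) ", converged" else " (not converged)"))
  invisible(x)
}

# hard assignment by maximum membership; ties broken toward the lower
# (darker) cluster, conservative for fibroglandular tissue
fcm_assign <- function(fit) {
  u <- fit$memberships
  max.col(u, ties.method = "first")
}
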