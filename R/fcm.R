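as_profile_matrix <- function(data) {
  if (inherits(data, "profile_set")) kept_values(data)
  else if (is.matrix(data) && is.numeric(data)) data
  else stopf("'data' must be a profile_set or a numeric matrix")
}

# squared Euclidean distances between rows of x (n x d) and v (k x d)
sq_dist <- function(x, v) {
  d2 <- outer(rowSums(x^2), rowSums(v^2), `+`) - 2 * tcrossprod(x, v)
  pmax(d2, 0)
}

# membership matrix for fuzzifier m given squared distances; points that
# coincide with a centroid get crisp membership there
fcm_memberships <- function(d2, m) {
  zero <- d2 < .Machine$double.eps
  w <- d2^(-1 / (m - 1))
  u <- w / rowSums(w)
  hit <- rowSums(zero) > 0
  if (any(hit)) {
    u[hit, ] <- 0
    u[hit, ] <- zero[hit, , drop = FALSE] / rowSums(zero[hit, , drop = FALSE])
  }
  u
}

#' Fuzzy c-means clustering of expression profiles
#'
#' Soft partitioning of standardized profiles into `k` clusters under a
#' Euclidean metric. Each profile belongs to every cluster with a membership
#' degree in `[0, 1]`; memberships of one profile sum to 1. The algorithm
#' alternates the classical updates
#' \deqn{u_{gi} = 1 \Big/ \sum_j (\|x_g - v_i\| / \|x_g - v_j\|)^{2/(m-1)},
#'   \qquad v_i = \sum_g u_{gi}^m x_g \Big/ \sum_g u_{gi}^m}
#' until the largest centroid movement falls below `tol` or `max_iter` is
#' reached, minimizing the fuzzified within-cluster sum of squares
#' \eqn{J = \sum_i \sum_g u_{gi}^m \|x_g - v_i\|^2}. A profile coinciding
#' with a centroid receives membership 1 there. Centroids are initialized
#' from `k` distinct data rows sampled under `seed`, so runs are
#' reproducible. The centroid of a cluster equals the membership-weighted
#' mean profile — the cluster "core" drawn as the thick central curve in
#' cluster plots.
#'
#' @param data A standardized [profile_set()] or a numeric matrix
#'   (profiles x stages).
#' @param k Number of clusters (1 <= k <= number of profiles).
#' @param m Fuzzifier, > 1; 2 is the classical default. As `m` approaches 1
#'   memberships become crisp (k-means-like).
#' @param seed Integer seed for the centroid initialization.
#' @param max_iter Iteration cap.
#' @param tol Convergence threshold on the maximum absolute centroid
#'   movement.
#' @return An object of class `"fuzzy_partition"`: list with `k`, `m`,
#'   `centroids` (k x stages), `memberships` (profiles x k), `objective`
#'   (final J), `objective_trace` (J per iteration), `xie_beni` (NA for
#'   k = 1), `seed`, `iterations`, `converged`.
#' @references Bezdek JC (1981) Pattern Recognition with Fuzzy Objective
#'   Function Algorithms. Plenum Press.
#' @export
fcm <- function(data, k, m = 2, seed = 1L, max_iter = 1000L, tol = 1e-8) {
  x <- as_profile_matrix(data)
  n <- nrow(x)
  k <- check_count(k, "k")
  if (k > n) stopf("k (%d) exceeds the number of profiles (%d)", k, n)
  check_scalar_number(m, "m")
  if (m <= 1) stopf("fuzzifier 'm' must be > 1, got %g", m)
  max_iter <- check_count(max_iter, "max_iter")
  # seeded initialization on k distinct data rows, weighted k-means++ style:
  # after a uniform first pick, rows are drawn with probability proportional
  # to their squared distance from the centroids chosen so far, which places
  # the k starting centroids in distinct dense regions
  v <- with_seed(seed, {
    idx <- sample.int(n, 1L)
    while (length(idx) < k) {
      d2 <- sq_dist(x, x[idx, , drop = FALSE])
      w <- apply(d2, 1L, min)
      w[idx] <- 0
      idx <- c(idx, if (sum(w) > 0) sample.int(n, 1L, prob = w)
               else sample(setdiff(seq_len(n), idx), 1L))
    }
    x[idx, , drop = FALSE]
  })
  trace <- double(0L)
  converged <- FALSE
  iter <- 0L
  u <- matrix(1, n, 1L)
  for (iter in seq_len(max_iter)) {
    d2 <- sq_dist(x, v)
    u <- fcm_memberships(d2, m)
    um <- u^m
    v_new <- crossprod(um, x) / colSums(um)
    trace <- c(trace, sum(um * d2))
    if (max(abs(v_new - v)) < tol) {
      v <- v_new
      converged <- TRUE
      break
    }
    v <- v_new
  }
  d2 <- sq_dist(x, v)
  u <- fcm_memberships(d2, m)
  obj <- sum(u^m * d2)
  rownames(v) <- paste0("cluster_", seq_len(k))
  colnames(v) <- colnames(x)
  dimnames(u) <- list(rownames(x), rownames(v))
  part <- structure(
    list(k = k, m = m, centroids = v, memberships = u, objective = obj,
         objective_trace = trace, xie_beni = NA_real_, seed = seed,
         iterations = iter, converged = converged),
    class = "fuzzy_partition")
  if (k >= 2L)
    # a partition with coinciding centroids has undefined separation and
    # can never be the preferred one; score it as infinitely bad
    part$xie_beni <- tryCatch(xie_beni_index(x, part),
                              error = function(e) Inf)
  part
}

#' @export
print.fuzzy_partition <- function(x, ...) {
  cat(sprintf(paste0("fuzzy_partition: k = %d, m = %g, %d profiles, ",
                     "objective %.4g, Xie-Beni %s, %d iterations%s\n"),
              x$k, x$m, nrow(x$memberships), x$objective,
              ifelse(is.na(x$xie_beni), "NA", sprintf("%.4g", x$xie_beni)),
              x$iterations,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Xie-Beni validity index of a fuzzy partition
#'
#' Ratio of the fuzzified within-cluster compactness to the separation of
#' the two closest centroids:
#' \deqn{XB = \frac{\sum_i \sum_g u_{gi}^m \|x_g - v_i\|^2}
#'   {n \cdot \min_{i \ne j} \|v_i - v_j\|^2}.}
#' Smaller values indicate a better partitioning; the index is the criterion
#' [select_k()] minimizes over candidate cluster numbers.
#'
#' @param data The clustered profiles (matrix or standardized
#'   [profile_set()]).
#' @param partition A [fcm()] result with `k >= 2`.
#' @return A positive scalar.
#' @references Xie XL, Beni G (1991) A validity measure for fuzzy
#'   clustering. IEEE PAMI 13:841-847.
#' @export
xie_beni_index <- function(data, partition) {
  stopifnot(inherits(partition, "fuzzy_partition"))
  x <- as_profile_matrix(data)
  if (partition$k < 2L)
    stopf("Xie-Beni index requires k >= 2 (centroid separation undefined)")
  v <- partition$centroids
  sep <- sq_dist(v, v)
  diag(sep) <- Inf
  min_sep <- min(sep)
  if (min_sep < .Machine$double.eps)
    stopf("duplicate centroids: minimum centroid separation is zero")
  compact <- sum(partition$memberships^partition$m * sq_dist(x, v))
  compact / (nrow(x) * min_sep)
}

#' Select the number of clusters by repeated fuzzy c-means runs
#'
#' Runs [fcm()] `reps` times per candidate `k` from independent seeded
#' initializations, scores each `k` by the minimum Xie-Beni index across its
#' repetitions, and returns the `k` with the smallest score (ties broken
#' toward the smaller `k`). The full per-k table supports a validity-curve
#' report.
#'
#' @param data Standardized profiles (matrix or [profile_set()]).
#' @param k_range Integer vector of candidate cluster numbers (all >= 2).
#' @param reps Number of seeded restarts per `k`.
#' @param m Fuzzifier.
#' @param seed Master seed; per-run seeds are derived from it.
#' @param ... Further arguments passed to [fcm()] (`max_iter`, `tol`).
#' @return List with `best_k`, `table` (data.frame of `k`, `xb_min`,
#'   `xb_median`), and `best` (the winning [fcm()] partition).
#' @export
select_k <- function(data, k_range = 2:12, reps = 10L, m = 2, seed = 1L, ...) {
  x <- as_profile_matrix(data)
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) == 0L) stopf("'k_range' must not be empty")
  if (any(k_range < 2L) || any(k_range > nrow(x) - 1L))
    stopf("'k_range' must lie within [2, n - 1]")
  reps <- check_count(reps, "reps")
  seeds <- matrix(derive_seeds(seed, length(k_range) * reps),
                  nrow = length(k_range))
  xb <- matrix(NA_real_, length(k_range), reps)
  best <- NULL
  for (i in seq_along(k_range)) {
    for (r in seq_len(reps)) {
      part <- fcm(x, k = k_range[i], m = m, seed = seeds[i, r], ...)
      xb[i, r] <- part$xie_beni
      if (is.null(best) || part$xie_beni < best$xie_beni - 1e-15 ||
          (abs(part$xie_beni - best$xie_beni) <= 1e-15 && part$k < best$k))
        best <- part
    }
  }
  score <- apply(xb, 1L, min)
  best_k <- k_range[which.min(score)]  # which.min takes the first = smallest k
  if (best$k != best_k) {
    r <- which.min(xb[match(best_k, k_range), ])
    best <- fcm(x, k = best_k, m = m,
                seed = seeds[match(best_k, k_range), r], ...)
  }
  list(best_k = best_k,
       table = data.frame(k = k_range, xb_min = score,
                          xb_median = apply(xb, 1L, median)),
       best = best)
}

#' Hard cluster assignment from a fuzzy partition
#' @param partition A [fcm()] result.
#' @return Named integer vector: for each profile, the index of its
#'   highest-membership cluster.
#' @export
cluster_assignments <- function(partition) {
  stopifnot(inherits(partition, "fuzzy_partition"))
  apply(partition$memberships, 1L, which.max)
}
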