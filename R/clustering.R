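# Normalization of inverse weights and the greedy hierarchical merge that
# groups them into clusters, producing the parameters of the stable
# expansion.

#' Normalize inverse weights
#'
#' Combined p-values depend only on the ratios of the weights, so the scale
#' is free.  This fixes it by demanding that the inverse weights sum to the
#' number of p-values: `lambda_i = (1/w_i) * L / sum_k (1/w_k)`, making the
#' average inverse weight exactly 1.  All clustering radii in this package
#' are measured on this scale.
#'
#' @param set a [weighted_pvalues()] set.
#' @return numeric vector of normalized inverse weights, summing to `L`.
#' @export
normalize_inverse_weights <- function(set) {
  set <- validate_weighted_pvalues(set)
  inv <- 1 / set$weights
  inv * length(inv) / sum(inv)
}

#' Greedy hierarchical clustering of inverse weights
#'
#' Exactly identical values are merged first (they form one cluster
#' whatever the radius).  Then, repeatedly, the closest pair of current
#' cluster centers is found; if their distance is strictly smaller than
#' `radius` they are replaced by their occurrence-weighted mean.  The
#' process stops when all center gaps are `>= radius`.  When several pairs
#' are equally close, the leftmost pair (after ascending sort) is merged --
#' a deterministic tie-break.  Final centers are recomputed as exact member
#' means, so within-cluster deviations sum to zero to machine precision.
#'
#' @param lambdas positive normalized inverse weights (see
#'   [normalize_inverse_weights()]); their sum should equal their length.
#' @param radius non-negative clustering radius `r` on the normalized
#'   scale.  `r = 0` merges only exactly identical values.
#' @return an object of class `cluster_set`: `radius`, `centers` (ascending
#'   cluster means), `multiplicities`, `members` (list of member inverse
#'   weights per cluster), `deviations` (members minus center) and `L`.
#' @export
cluster_inverse_weights <- function(lambdas, radius) {
  if (!is.numeric(radius) || length(radius) != 1L || !is.finite(radius) ||
      radius < 0) {
    pc_stop("clustering radius must be a single non-negative number")
  }
  if (length(lambdas) < 1L || any(!is.finite(lambdas) | lambdas <= 0)) {
    pc_stop("inverse weights must be positive and finite")
  }
  L <- length(lambdas)
  if (abs(sum(lambdas) - L) > 1e-6 * L) {
    pc_warn(sprintf(
      "inverse weights sum to %.6g, not L = %d; did you normalize?",
      sum(lambdas), L), class = "pcombine_scale_warning")
  }
  ord <- order(lambdas)
  sorted <- lambdas[ord]
  # pre-merge exact duplicates
  centers <- numeric(0)
  members <- list()
  i <- 1L
  while (i <= L) {
    j <- i
    while (j < L && sorted[j + 1L] == sorted[i]) j <- j + 1L
    centers <- c(centers, sorted[i])
    members[[length(members) + 1L]] <- sorted[i:j]
    i <- j + 1L
  }
  counts <- lengths(members)
  # greedy agglomeration of adjacent centers
  while (length(centers) > 1L) {
    gaps <- diff(centers)
    k <- which.min(gaps)           # leftmost minimal gap
    if (gaps[k] >= radius) break
    new_center <- (centers[k] * counts[k] + centers[k + 1L] * counts[k + 1L]) /
      (counts[k] + counts[k + 1L])
    centers[k] <- new_center
    members[[k]] <- c(members[[k]], members[[k + 1L]])
    counts[k] <- counts[k] + counts[k + 1L]
    centers <- centers[-(k + 1L)]
    members <- members[-(k + 1L)]
    counts <- counts[-(k + 1L)]
  }
  centers <- vapply(members, mean, numeric(1))   # exact member means
  deviations <- lapply(seq_along(members),
                       function(j) members[[j]] - centers[j])
  structure(
    list(radius = radius, centers = centers,
         multiplicities = as.integer(counts), members = members,
         deviations = deviations, L = L),
    class = "cluster_set"
  )
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("Cluster set: m = %d clusters, L = %d, radius = %g\n",
              length(x$centers), x$L, x$radius))
  print(data.frame(center = x$centers, multiplicity = x$multiplicities,
                   max_abs_dev = vapply(x$deviations,
                                        function(d) max(abs(d)), numeric(1))),
        row.names = FALSE)
  invisible(x)
}

#' Power sums of within-cluster deviations
#'
#' `D_{j,k} = sum_i delta_{j,i}^k` for every cluster `j` and order
#' `1 <= k <= max_order`.  `D_{j,1} = 0` by construction (centers are
#' member means); `D_{j,2}` measures spread and `D_{j,3}` the skewness of
#' the inverse weights in cluster `j` -- clusters symmetric about their
#' center have zero odd moments.
#'
#' @param cs a [cluster_inverse_weights()] result.
#' @param max_order highest power to compute (`>= 1`).
#' @return an object of class `cluster_moments`: a matrix `D` with one row
#'   per cluster and one column per order.
#' @export
cluster_moments <- function(cs, max_order) {
  if (!inherits(cs, "cluster_set")) pc_stop("cs must be a cluster_set")
  if (max_order < 1) pc_stop("max_order must be >= 1")
  m <- length(cs$centers)
  D <- matrix(0, nrow = m, ncol = max_order)
  for (j in seq_len(m)) {
    for (k in seq_len(max_order)) {
      D[j, k] <- sum(cs$deviations[[j]]^k)
    }
  }
  structure(list(D = D, max_order = as.integer(max_order)),
            class = "cluster_moments")
}
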