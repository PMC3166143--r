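# Independent ground-truth engines: Monte-Carlo sampling of the weighted
# exponential sum, and numerical inversion of its characteristic function
# along a contour below the poles.  Used by the test suite to verify every
# analytic method, and exported so users can run the same checks.

#' Oracle configuration
#'
#' @param mc_samples Monte-Carlo sample count (>= 1000; default 1e6).
#' @param seed RNG seed for the Monte-Carlo oracle.
#' @param quad_digits decimal precision of the partial-fraction quadrature
#'   route (>= 20; default 50).
#' @param quad_method which route's value to report:
#'   `"partial_fraction_hp"` (extended-precision partial fractions, the
#'   default) or `"contour_quadrature"` (double-precision contour
#'   integration).  Both are always computed and cross-checked.
#' @return a list of class `oracle_config`.
#' @export
oracle_config <- function(mc_samples = 1e6, seed = 1L, quad_digits = 50,
                          quad_method = c("partial_fraction_hp",
                                          "contour_quadrature")) {
  if (mc_samples < 1e3) pc_stop("mc_samples must be >= 1000")
  if (quad_digits < 20) pc_stop("quad_digits must be >= 20")
  structure(list(mc_samples = as.integer(mc_samples), seed = as.integer(seed),
                 quad_digits = quad_digits,
                 quad_method = match.arg(quad_method)),
            class = "oracle_config")
}

oracle_estimate <- function(estimate, standard_error, method) {
  structure(list(estimate = estimate, standard_error = standard_error,
                 method = method),
            class = "oracle_estimate")
}

#' @export
print.oracle_estimate <- function(x, ...) {
  cat(sprintf("Oracle estimate (%s): %.8g", x$method, x$estimate))
  if (is.finite(x$standard_error) && x$standard_error > 0) {
    cat(sprintf(" +/- %.2g", x$standard_error))
  }
  cat("\n")
  invisible(x)
}

with_preserved_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Monte-Carlo oracle for the combined p-value
#'
#' Draws `T = sum_i w_i E_i` with `E_i` unit exponential (equivalently
#' `-log U_i` for uniform `U_i`) and returns the fraction of samples with
#' `T >= t`, with its binomial standard error.  Seeded and reproducible;
#' the caller's RNG state is left untouched.
#'
#' @param weights positive weights `w_i`.
#' @param t observed statistic (non-negative).
#' @param config an [oracle_config()].
#' @return an `oracle_estimate`.
#' @export
monte_carlo_pvalue <- function(weights, t, config = oracle_config()) {
  if (any(!is.finite(weights) | weights <= 0)) {
    pc_stop("weights must be positive and finite")
  }
  if (!is.finite(t) || t < 0) pc_stop("t must be non-negative")
  n <- config$mc_samples
  total <- with_preserved_rng(config$seed, {
    T <- numeric(n)
    for (w in weights) T <- T + w * stats::rexp(n)
    sum(T >= t)
  })
  est <- total / n
  oracle_estimate(est, sqrt(est * (1 - est) / n), "monte_carlo")
}

# ---- contour quadrature route ----------------------------------------------

# Gauss-Legendre nodes/weights on [-1, 1] by Golub-Welsch.
gauss_legendre <- function(n) {
  k <- seq_len(n - 1L)
  b <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1L)] <- b
  J[cbind(k + 1L, k)] <- b
  ev <- eigen(J, symmetric = TRUE)
  list(nodes = rev(ev$values), weights = rev(2 * ev$vectors[1L, ]^2))
}

.pc_gl16 <- NULL
pc_gl16 <- function() {
  if (is.null(.pc_gl16)) {
    utils::assignInMyNamespace(".pc_gl16", gauss_legendre(16L))
  }
  .pc_gl16
}

# Tail probability by inversion of the characteristic function
#   phi(omega) = prod_j (lambda_j / (lambda_j - i omega))^{N_j},
#   S(t) = (1/2 pi) integral over Im(omega) = -a of e^{-i omega t} phi(omega) / (i omega),
# with the contour a = lambda_min / 2 below the real axis (all poles sit on
# the negative imaginary axis, the nearest at -i lambda_min).  The real
# half-line [0, X] is integrated by panelwise Gauss-Legendre; the
# remainder is taken straight down from X (non-oscillatory, integrand
# decays like e^{-y t}) via adaptive quadrature.  Symmetry of the contour
# doubles the real part.
contour_tail_quadrature <- function(rates, mults, t) {
  if (t == 0) return(1)
  a <- min(rates) / 2
  g <- function(omega) {
    phi <- rep(1 + 0i, length(omega))
    for (j in seq_along(rates)) {
      phi <- phi * (rates[j] / (rates[j] - 1i * omega))^mults[j]
    }
    exp(-1i * omega * t) * phi / (1i * omega)
  }
  X <- 3 * max(rates) + 2 * a
  h <- min(pi / (2 * max(t, 0.5)), a / 2)
  np <- as.integer(ceiling(X / h))
  edges <- seq(0, X, length.out = np + 1L)
  gl <- pc_gl16()
  mid <- (edges[-1L] + edges[-(np + 1L)]) / 2
  half <- (edges[-1L] - edges[-(np + 1L)]) / 2
  xs <- rep(mid, each = 16L) + rep(half, each = 16L) * rep(gl$nodes, np)
  ws <- rep(half, each = 16L) * rep(gl$weights, np)
  horiz <- sum(ws * Re(g(xs - 1i * a)))
  vert_re <- function(y) Re(-1i * g(X - 1i * (a + y)))
  vert <- stats::integrate(vert_re, 0, Inf, rel.tol = 1e-12,
                           abs.tol = 1e-16 * max(abs(horiz), 1e-300),
                           subdivisions = 500L, stop.on.error = FALSE)$value
  (horiz + vert) / pi
}

#' Quadrature oracle for the grouped general case
#'
#' Evaluates the tail probability by two independent numerical routes:
#' (a) the partial-fraction survival form at `quad_digits` decimal
#' precision, and (b) double-precision contour integration of the
#' characteristic-function inversion integral below all poles.  The two
#' routes are cross-checked on every call against an explicit error model
#' for route (b) (machine epsilon times the contour cancellation factor
#' `exp((lambda_min - a) t)`, floored at 8 significant digits); a
#' disagreement raises an internal-consistency error.
#'
#' @param params a [gc_parameters()] object.
#' @param config an [oracle_config()].
#' @return an `oracle_estimate` whose `estimate` comes from the configured
#'   `quad_method` (extended-precision partial fractions by default).
#' @export
quadrature_pvalue <- function(params, config = oracle_config()) {
  if (!inherits(params, "gc_parameters")) {
    pc_stop("params must be a gc_parameters object")
  }
  rates <- params$rates
  mults <- params$multiplicities
  t <- params$t
  pa <- gc_survival_hp(rates, mults, t, hp_ctx(config$quad_digits))$value
  pb <- contour_tail_quadrature(rates, mults, t)
  a <- min(rates) / 2
  cancel <- exp(min((min(rates) - a) * t, 600))
  tol <- max(1e-8, 1e3 * .Machine$double.eps * cancel)
  if (abs(pa - pb) > tol * max(abs(pa), 1e-300)) {
    pc_stop(sprintf(
      "quadrature routes disagree: partial fractions %.12g vs contour %.12g (tol %.2g)",
      pa, pb, tol), class = "pcombine_oracle_inconsistency")
  }
  est <- if (config$quad_method == "partial_fraction_hp") pa else pb
  oracle_estimate(est, 0, config$quad_method)
}

# ---- fixture generator -----------------------------------------------------

#' Generate synthetic weighted p-value fixtures
#'
#' Deterministic (given `seed`) generator of the weight regimes the test
#' suite exercises, on the normalized inverse-weight scale (mean 1):
#'
#' * `well_separated`: pairwise gaps of order `1/L` -- the comfortable
#'   regime where Good's formula is stable in double precision.
#' * `near_degenerate`: all normalized inverse weights within about 1e-5 of
#'   1 -- distinct in double precision but catastrophically cancelling.
#' * `grouped`: 2-4 well-separated cluster centers with intra-cluster
#'   spread below 0.05.
#' * `symmetric_clusters`: like `grouped` but members placed symmetrically
#'   about each center, forcing all odd deviation moments to zero.
#'
#' @param kind one of the four regimes above.
#' @param L number of records (>= 1).
#' @param seed RNG seed; the caller's RNG state is preserved.
#' @param p_dist `"uniform"` draws null p-values; `"beta"` draws
#'   alternative-like p-values skewed toward zero (Beta(0.3, 1)).
#' @return a [weighted_pvalues()] set.
#' @export
generate_fixture <- function(kind = c("well_separated", "near_degenerate",
                                      "grouped", "symmetric_clusters"),
                             L, seed,
                             p_dist = c("uniform", "beta")) {
  kind <- match.arg(kind)
  p_dist <- match.arg(p_dist)
  if (L < 1) pc_stop("L must be >= 1")
  L <- as.integer(L)
  with_preserved_rng(seed, {
    lam <- switch(kind,
      well_separated = {
        base <- if (L == 1L) 1 else seq(0.5, 1.5, length.out = L)
        jitter <- if (L == 1L) 0 else stats::runif(L, -1, 1) * 0.2 / L
        base + jitter
      },
      near_degenerate = 1 + stats::runif(L, -1, 1) * 1e-5,
      grouped = {
        nc <- if (L < 2L) 1L else sample(2:min(4L, L), 1L)
        centers <- if (nc == 1L) 1 else seq(0.6, 1.4, length.out = nc)
        assign_cluster <- sample(rep(seq_len(nc), length.out = L))
        centers[assign_cluster] + stats::runif(L, -0.02, 0.02)
      },
      symmetric_clusters = {
        nc <- if (L < 4L) 1L else 2L
        centers <- if (nc == 1L) 1 else c(0.7, 1.3)
        sizes <- rep(L %/% nc, nc)
        sizes[1L] <- sizes[1L] + L %% nc
        vals <- numeric(0)
        for (j in seq_len(nc)) {
          n <- sizes[j]
          half <- n %/% 2L
          d <- if (half > 0L) stats::runif(half, 0.005, 0.02) else numeric(0)
          v <- c(centers[j] + d, centers[j] - d,
                 if (n %% 2L == 1L) centers[j])
          vals <- c(vals, v)
        }
        vals
      })
    lam <- lam * L / sum(lam)
    p <- switch(p_dist,
                uniform = stats::runif(L),
                beta = pmin(pmax(stats::rbeta(L, 0.3, 1), 1e-10), 1))
    weighted_pvalues(p, 1 / lam,
                     ids = sprintf("%s_%02d", kind, seq_len(L)))
  })
}
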