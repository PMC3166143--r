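# The controlled expansion: exactness limits, term structure, convergence
# and the truncation bound.

test_that("radius 0 recovers the exact formula term for term", {
  s <- generate_fixture("well_separated", 5, seed = 11)
  e0 <- expansion_combine(s, expansion_config(4, 0))
  g <- gc_combine(as_gc_parameters(s), digits = 16)
  expect_identical(e0$raw_pvalue, g$raw_pvalue)
  expect_true(all(e0$details$terms$value == 0))
  expect_identical(e0$truncation_bound, 0)
  # and matches good_combine for distinct weights
  expect_sig_digits(e0$pvalue, good_combine(s, digits = 16)$pvalue, 12)
})

test_that("exactly equal weights give Fisher through a single cluster", {
  p <- c(0.04, 0.3, 0.11, 0.6)
  s <- weighted_pvalues(p, rep(2.7, 4))
  e <- expansion_combine(s, expansion_config(4, 0.05))
  expect_equal(length(e$details$cluster_set$centers), 1L)
  expect_equal(e$pvalue, fisher_combine(weighted_pvalues(p))$pvalue,
               tolerance = 1e-13)
})

test_that("term structure: no order 1, no cross-cluster mixing below 4", {
  lam <- dyadic_symmetric_lambdas()
  cs <- cluster_inverse_weights(lam, 0.1)
  expect_equal(length(cs$centers), 2L)
  mom <- cluster_moments(cs, 6L)
  terms <- correction_terms(cs, mom, t = 3.5, max_order = 6L)
  expect_true(all(terms$order != 1L))
  expect_gte(min(terms$order), 2L)
  low <- terms[terms$order <= 3L, ]
  expect_true(all(!grepl(",", low$clusters)))
  # order equals the total multiplicity shift of the pattern
  expect_equal(terms$order, vapply(terms$shift, sum, integer(1)))
  # order 4 includes the cross-cluster (2, 2) pattern with coefficient
  # (D_{1,2}/2)(D_{2,2}/2)
  cross <- terms[terms$order == 4L & grepl(",", terms$clusters), ]
  expect_equal(nrow(cross), 1L)
  expect_equal(cross$coefficient,
               (mom$D[1, 2] / 2) * (mom$D[2, 2] / 2))
  # and the single-cluster orders carry D2/2, -D3/3, D4/4 + D2^2/8
  o2 <- terms[terms$order == 2L, ]
  expect_equal(sort(o2$coefficient), sort(mom$D[, 2] / 2))
  o4 <- terms[terms$order == 4L & !grepl(",", terms$clusters), ]
  expect_equal(sort(o4$coefficient),
               sort(mom$D[, 4] / 4 + mom$D[, 2]^2 / 8))
})

test_that("correction terms vanish where they must", {
  # max_order = 0: empty list
  lam <- dyadic_symmetric_lambdas()
  cs <- cluster_inverse_weights(lam, 0.1)
  mom <- cluster_moments(cs, 1L)
  expect_equal(nrow(correction_terms(cs, mom, 3.5, 0L)), 0L)
  # exactly symmetric clusters: the order-3 terms are present with value 0
  mom <- cluster_moments(cs, 3L)
  terms <- correction_terms(cs, mom, 3.5, 3L)
  o3 <- terms[terms$order == 3L, ]
  expect_equal(nrow(o3), 2L)
  expect_true(all(o3$value == 0))
  # singletons: every term is zero at every order
  cs1 <- cluster_inverse_weights(c(0.7, 1.3), 0.1)
  terms1 <- correction_terms(cs1, cluster_moments(cs1, 6L), 2.2, 6L)
  expect_true(all(terms1$value == 0))
})

test_that("expansion error decreases with order and bound tracks it", {
  for (seed in c(3, 17, 29)) {
    s <- generate_fixture("grouped", 8, seed = seed)
    exact <- suppressWarnings(
      gc_combine(as_gc_parameters(s), digits = 60, warn_threshold = Inf))$pvalue
    errs <- vapply(c(0L, 2L, 3L, 4L, 6L), function(k) {
      abs(expansion_combine(s, expansion_config(k, 0.05))$pvalue - exact)
    }, numeric(1))
    expect_true(all(diff(errs) <= 1e-12 * max(exact, 1e-12)))
    e4 <- expansion_combine(s, expansion_config(4, 0.05))
    expect_gte(e4$truncation_bound, abs(errs[4]) - 1e-16)
  }
})

test_that("truncation bound edge cases", {
  # all deviations zero: bound exactly 0
  cs <- cluster_inverse_weights(c(1, 1, 1), 0.05)
  expect_identical(truncation_bound(cs, cluster_moments(cs, 4L), 2, 4L), 0)
  # rho >= 1: refused with advice
  cs_wide <- cluster_inverse_weights(c(0.05, 1.95), 3)
  expect_error(
    truncation_bound(cs_wide, cluster_moments(cs_wide, 4L), 2, 4L),
    class = "pcombine_bound_unavailable")
})

test_that("no clipping at order 4 for rho <= 0.1 fixtures", {
  for (fx in fixture_suite(4L, seed0 = 300L)) {
    e <- expansion_combine(fx, expansion_config(4, 0.05))
    cs <- e$details$cluster_set
    rho <- max(mapply(function(d, c) max(abs(d)) / c,
                      cs$deviations, cs$centers))
    if (rho <= 0.1) {
      expect_false(e$clipped)
      expect_gte(e$raw_pvalue, 0)
      expect_lte(e$raw_pvalue, 1)
    }
  }
})

test_that("degenerate two-value sweep: expansion stable, Good unstable", {
  p <- c(0.03, 0.2)
  fis <- fisher_combine(weighted_pvalues(p))$pvalue
  prev_diff <- Inf
  prev_ci <- 0
  for (eps in 10^-(seq(2, 14, 2))) {
    s <- weighted_pvalues(p, c(1, 1 + eps))
    e <- expansion_combine(s, expansion_config(4, 0.05))
    d <- abs(e$pvalue - fis)
    expect_lte(d, prev_diff + 1e-15)
    prev_diff <- d
    ci <- suppressWarnings(good_combine(s, digits = 16))$cancellation_index
    expect_gt(ci, prev_ci)
    prev_ci <- ci
  }
  expect_lt(prev_diff, 1e-12)   # converged to Fisher
  expect_gt(prev_ci, 1e12)      # double-precision Good lost all figures
})
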