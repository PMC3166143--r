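# Fisher / Good / general-case formulas and the partial-fraction engine.

test_that("fisher_combine matches closed forms and ignores weights", {
  expect_equal(fisher_combine(weighted_pvalues(0.3))$pvalue, 0.3)
  # Q(2, log 4) = 0.25 * (1 + log 4), by the finite Erlang sum
  expect_equal(fisher_combine(weighted_pvalues(c(0.5, 0.5)))$pvalue,
               0.25 * (1 + log(4)), tolerance = 1e-14)
  # Q(3, 3 log 10) via the independent finite sum e^-x (1 + x + x^2/2)
  x <- 3 * log(10)
  expect_equal(fisher_combine(weighted_pvalues(c(0.1, 0.1, 0.1)))$pvalue,
               exp(-x) * (1 + x + x^2 / 2), tolerance = 1e-13)
  p <- c(0.02, 0.4, 0.7)
  expect_identical(fisher_combine(weighted_pvalues(p, c(5, 5, 5)))$pvalue,
                   fisher_combine(weighted_pvalues(p))$pvalue)
})

test_that("good_combine matches the two-rate closed form", {
  # p = (0.1, 0.1), w = (1, 2): t = log 1000 on the raw scale; the exact
  # survival is 2 e^{-t/2} - e^{-t} = 0.0622456
  t <- log(1000)
  expected <- 2 * exp(-t / 2) - exp(-t)
  s <- weighted_pvalues(c(0.1, 0.1), c(1, 2))
  expect_equal(good_combine(s, digits = 16)$pvalue, expected,
               tolerance = 1e-13)
  expect_equal(good_combine(s, digits = 50)$pvalue, expected,
               tolerance = 1e-13)
  # single record: any weight returns the p-value itself
  expect_equal(good_combine(weighted_pvalues(0.3, 5.0))$pvalue, 0.3)
})

test_that("good_combine refuses exactly degenerate weights", {
  s <- weighted_pvalues(c(0.1, 0.2), c(1, 1))
  expect_error(good_combine(s), class = "pcombine_degenerate_weights_error")
})

test_that("worked example: double-precision Good is flagged negative", {
  s <- example_b_set()
  expect_warning(
    res <- good_combine(s, digits = 16),
    class = "pcombine_cancellation_warning"
  )
  expect_lt(res$raw_pvalue, 0)
  expect_true(res$clipped)
  expect_gt(res$cancellation_index, 1e6)
})

test_that("gc_combine matches Erlang and two-rate closed forms", {
  expect_equal(gc_combine(gc_parameters(1, 3L, 2))$pvalue, 5 * exp(-2),
               tolerance = 1e-13)
  t <- log(1000)
  expect_equal(gc_combine(gc_parameters(c(0.5, 1), c(1L, 1L), t))$pvalue,
               2 * exp(-t / 2) - exp(-t), tolerance = 1e-13)
  # double path agrees with the extended-precision path when stable
  gp <- gc_parameters(c(0.4, 0.9, 1.7), c(2L, 1L, 3L), 5.5)
  expect_equal(gc_combine(gp, digits = 16)$pvalue,
               gc_combine(gp, digits = 50)$pvalue, tolerance = 1e-12)
})

test_that("gc_combine reduces to Fisher for m = 1, any rate", {
  set.seed(21)
  for (i in 1:5) {
    L <- sample(1:8, 1)
    p <- stats::runif(L)
    t0 <- -sum(log(p))
    rate <- stats::rexp(1) + 0.05
    expect_sig_digits(
      gc_combine(gc_parameters(rate, L, t0 / rate))$pvalue,
      fisher_combine(weighted_pvalues(p))$pvalue, 12)
  }
})

test_that("gc_combine with all singletons reduces to good_combine", {
  set.seed(22)
  for (i in 1:5) {
    s <- generate_fixture("well_separated", sample(2:7, 1), seed = 50 + i)
    expect_sig_digits(gc_combine(as_gc_parameters(s))$pvalue,
                      good_combine(s)$pvalue, 12)
  }
})

test_that("gc_combine is scale invariant in (rates, t)", {
  gp <- gc_parameters(c(0.6, 1.1, 1.9), c(1L, 2L, 1L), 4.2)
  p0 <- gc_combine(gp)$pvalue
  for (c in c(0.1, 3, 41.7)) {
    expect_sig_digits(
      gc_combine(gc_parameters(gp$rates * c, gp$multiplicities, gp$t / c))$pvalue,
      p0, 12)
  }
})

test_that("combined p-values are non-decreasing in each input p-value", {
  set.seed(23)
  p <- c(0.05, 0.3, 0.6)
  w <- c(0.8, 1.1, 1.6)
  for (i in 1:3) {
    grid <- seq(0.01, 1, length.out = 8)
    prev_f <- prev_g <- prev_gc <- prev_e <- -Inf
    for (v in grid) {
      p2 <- p
      p2[i] <- v
      s <- weighted_pvalues(p2, w)
      f <- fisher_combine(s)$pvalue
      g <- good_combine(s, digits = 16)$pvalue
      gc_ <- gc_combine(as_gc_parameters(s), digits = 16)$pvalue
      e <- expansion_combine(s, expansion_config(4, 0.05))$pvalue
      expect_gte(f, prev_f - 1e-14)
      expect_gte(g, prev_g - 1e-14)
      expect_gte(gc_, prev_gc - 1e-14)
      expect_gte(e, prev_e - 1e-14)
      prev_f <- f; prev_g <- g; prev_gc <- gc_; prev_e <- e
    }
  }
})

# The reconstruction identity sum_{j,k} c_{jk}/(lambda_j + s)^k is itself
# a cancelling sum, so its double-precision tolerance must scale with the
# cancellation it suffers at the probe point.
expect_reconstructs <- function(pf, s) {
  terms <- numeric(0)
  for (j in seq_along(pf$rates)) {
    for (k in seq_len(pf$multiplicities[j])) {
      terms <- c(terms, pf$coefficients[[j]][k] / (pf$rates[j] + s)^k)
    }
  }
  expected <- prod((pf$rates + s)^(-pf$multiplicities))
  cancel <- sum(abs(terms)) / abs(expected)
  expect_equal(sum(terms), expected,
               tolerance = 1e-12 * max(1, cancel))
}

test_that("partial-fraction coefficients: closed forms and reconstruction", {
  # m = 1: single pole of order N with coefficient 1
  pf <- partial_fraction_coefficients(gc_parameters(1.3, 4L, 1))
  expect_equal(pf$coefficients[[1]], c(0, 0, 0, 1))
  # m = 2, N = (1, 1), rates (a, b): 1/(b - a) and 1/(a - b)
  a <- 0.6; b <- 1.7
  pf <- partial_fraction_coefficients(gc_parameters(c(a, b), c(1L, 1L), 1))
  expect_equal(pf$coefficients[[1]], 1 / (b - a))
  expect_equal(pf$coefficients[[2]], 1 / (a - b))
  # m = 2, N = (2, 1): three coefficients, probe-point identity at s = 0.37
  gp <- gc_parameters(c(0.7, 1.3), c(2L, 1L), 1)
  for (method in c("derivative", "index_sum")) {
    pf <- partial_fraction_coefficients(gp, method = method)
    expect_equal(length(unlist(pf$coefficients)), 3L)
    expect_reconstructs(pf, 0.37)
  }
})

test_that("derivative and index-sum coefficient routes agree", {
  set.seed(31)
  for (i in 1:6) {
    m <- sample(2:4, 1)
    # well-separated rates: the double-precision coefficient routes are
    # only meaningful away from near-degeneracy (gaps >= 0.25)
    rates <- seq(0.4, by = 0.5, length.out = m) + stats::runif(m, 0, 0.2)
    mults <- sample(1:4, m, replace = TRUE)
    gp <- gc_parameters(rates, mults, 1)
    cd <- partial_fraction_coefficients(gp, "derivative")$coefficients
    ci <- partial_fraction_coefficients(gp, "index_sum")$coefficients
    for (j in seq_len(m)) {
      expect_equal(cd[[j]], ci[[j]], tolerance = 1e-8)
    }
    # reconstruction identity at random probe points
    pf <- partial_fraction_coefficients(gp)
    for (s in stats::runif(3, 0, 5)) {
      expect_reconstructs(pf, s)
    }
  }
})
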