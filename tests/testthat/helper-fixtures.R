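# Shared fixtures and small assertion helpers.

# Printed inputs of the published worked example with nearly degenerate
# weights: five p-values whose weights agree to 4-5 decimal places.
example_b_set <- function() {
  weighted_pvalues(
    c(0.008000257, 0.008579261, 0.0008911761, 0.006967988, 0.004973110),
    c(0.54531152, 0.54532057, 0.54531221, 0.54531399, 0.54531776),
    ids = paste0("m", 1:5)
  )
}

# Two exactly symmetric clusters built from dyadic rationals, so member
# means and deviations are exact in double precision and odd deviation
# moments vanish exactly: {24, 26}/32 about 25/32 and {38, 40}/32 about
# 39/32.  The values sum to 4 = L, i.e. they are already normalized.
dyadic_symmetric_lambdas <- function() c(24, 26, 38, 40) / 32

rel_err <- function(a, b) abs(a - b) / max(abs(b), .Machine$double.xmin)

expect_sig_digits <- function(a, b, digits) {
  expect_lte(rel_err(a, b), 10^(-digits))
}

# Deterministic mixed-regime fixture suite used by several property tests.
fixture_suite <- function(n_per_kind = 13L, seed0 = 1000L) {
  kinds <- c("well_separated", "near_degenerate", "grouped",
             "symmetric_clusters")
  out <- list()
  i <- 0L
  set.seed(1)
  for (k in kinds) {
    for (j in seq_len(n_per_kind)) {
      L <- sample(2:10, 1)
      out[[length(out) + 1L]] <- generate_fixture(k, L, seed = seed0 + i)
      i <- i + 1L
    }
  }
  out
}
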