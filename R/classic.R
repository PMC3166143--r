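# Closed-form combination formulas: Fisher (equal weights), Good (all
# distinct weights), and the exact general case with grouped weights.
#
# All three are tail probabilities of a weighted sum of unit exponentials.
# With m distinct rates lambda_j of multiplicity N_j, partial fractions of
#   prod_j (lambda_j + s)^(-N_j) = sum_{j,k} c_{jk} / (lambda_j + s)^k
# give the survival function
#   S(t) = Lambda * sum_{j,k} c_{jk} * Q(k, lambda_j t) / lambda_j^k ,
# with Lambda = prod_j lambda_j^{N_j} and Q the regularized upper
# incomplete gamma function.  The pole coefficients follow from the
# exponential-of-series recurrence
#   E_0 = prod_{l != j} (lambda_l - lambda_j)^(-N_l)
#   E_n = (1/n) * sum_{k=1}^{n} beta_k E_{n-k},
#   beta_k = (-1)^k sum_{l != j} N_l (lambda_l - lambda_j)^(-k),
# where c_{j, N_j - n} = E_n: no factorials, no symbolic differentiation.
# The formula is exact but cancels catastrophically when rates are nearly
# degenerate, which is why it is evaluated in extended precision by
# default; the stable alternative is expansion_combine().

# ---- double-precision engine (vectorized over t) ---------------------------

pf_coeffs_double <- function(rates, mults) {
  m <- length(rates)
  C <- vector("list", m)
  for (j in seq_len(m)) {
    Nj <- mults[j]
    diffs <- rates[-j] - rates[j]
    Nl <- mults[-j]
    E <- numeric(Nj)                       # E[n+1] = E_n
    E[1] <- prod(diffs^(-Nl))
    if (Nj > 1L) {
      for (n in seq_len(Nj - 1L)) {
        beta <- vapply(seq_len(n), function(k) {
          (-1)^k * sum(Nl * diffs^(-k))
        }, numeric(1))
        E[n + 1L] <- sum(beta * E[n:1]) / n
      }
    }
    # coefficient of (lambda_j + s)^(-k) is E_{N_j - k}
    C[[j]] <- E[Nj - seq_len(Nj) + 1L]
  }
  C
}

# Survival function of the hypoexponential with repeated rates, double
# precision, vectorized over t.  Returns the tail probabilities; when
# `terms` is TRUE also returns the per-pole contributions at t[1] for
# cancellation diagnostics.
gc_survival_double <- function(rates, mults, t, terms = FALSE) {
  C <- pf_coeffs_double(rates, mults)
  logLambda <- sum(mults * log(rates))
  out <- numeric(length(t))
  tvals <- if (terms) numeric(0)
  for (j in seq_along(rates)) {
    for (k in seq_len(mults[j])) {
      contrib <- C[[j]][k] * exp(logLambda - k * log(rates[j])) *
        stats::pgamma(rates[j] * t, shape = k, lower.tail = FALSE)
      out <- out + contrib
      if (terms) tvals <- c(tvals, contrib[1L])
    }
  }
  if (terms) list(value = out, terms = tvals) else out
}

# ---- extended-precision engine ---------------------------------------------

# Q(k, x) = exp(-x) * sum_{q=0}^{k-1} x^q / q!  for integer k >= 1.
hp_gamma_q <- function(k, x, ctx) {
  acc <- hp_from_int(1, ctx)
  term <- hp_from_int(1, ctx)
  if (k > 1L) {
    for (q in seq_len(k - 1L)) {
      term <- hp_div_small(hp_mul(term, x, ctx), q, ctx)
      acc <- hp_add(acc, term, ctx)
    }
  }
  hp_mul(hp_exp(hp_neg(x), ctx), acc, ctx)
}

pf_coeffs_hp <- function(rates, mults, ctx) {
  m <- length(rates)
  R <- lapply(rates, hp_from_double, ctx = ctx)
  C <- vector("list", m)
  for (j in seq_len(m)) {
    Nj <- mults[j]
    others <- setdiff(seq_len(m), j)
    invd <- lapply(others, function(l) {
      hp_recip(hp_sub(R[[l]], R[[j]], ctx), ctx)   # exact double difference
    })
    Nl <- mults[others]
    E <- vector("list", Nj)
    E0 <- hp_from_int(1, ctx)
    for (i in seq_along(others)) {
      E0 <- hp_mul(E0, hp_pow_int(invd[[i]], Nl[i], ctx), ctx)
    }
    E[[1L]] <- E0
    if (Nj > 1L) {
      pw <- lapply(invd, function(v) hp_from_int(1, ctx)) # invd^k, updated in place
      beta <- vector("list", Nj - 1L)
      for (k in seq_len(Nj - 1L)) {
        b <- hp_zero()
        for (i in seq_along(others)) {
          pw[[i]] <- hp_mul(pw[[i]], invd[[i]], ctx)
          b <- hp_add(b, hp_mul_small(pw[[i]], Nl[i], ctx), ctx)
        }
        if (k %% 2 == 1) b <- hp_neg(b)
        beta[[k]] <- b
      }
      for (n in seq_len(Nj - 1L)) {
        s <- hp_zero()
        for (k in seq_len(n)) {
          s <- hp_add(s, hp_mul(beta[[k]], E[[n - k + 1L]], ctx), ctx)
        }
        E[[n + 1L]] <- hp_div_small(s, n, ctx)
      }
    }
    C[[j]] <- lapply(seq_len(Nj), function(k) E[[Nj - k + 1L]])
  }
  C
}

gc_survival_hp <- function(rates, mults, t, ctx) {
  C <- pf_coeffs_hp(rates, mults, ctx)
  R <- lapply(rates, hp_from_double, ctx = ctx)
  tH <- hp_from_double(t, ctx)
  Lambda <- hp_from_int(1, ctx)
  for (j in seq_along(rates)) {
    Lambda <- hp_mul(Lambda, hp_pow_int(R[[j]], mults[j], ctx), ctx)
  }
  S <- hp_zero()
  abs_sum <- hp_zero()
  for (j in seq_along(rates)) {
    x <- hp_mul(R[[j]], tH, ctx)
    invlam <- hp_recip(R[[j]], ctx)
    for (k in seq_len(mults[j])) {
      term <- hp_mul(C[[j]][[k]], hp_gamma_q(k, x, ctx), ctx)
      term <- hp_mul(term, hp_pow_int(invlam, k, ctx), ctx)
      term <- hp_mul(term, Lambda, ctx)
      S <- hp_add(S, term, ctx)
      abs_sum <- hp_add(abs_sum, hp_abs(term), ctx)
    }
  }
  cancel <- if (hp_is_zero(S)) Inf else {
    10^(hp_log10_abs(abs_sum) - hp_log10_abs(S))
  }
  list(value = hp_to_double(S), cancellation_index = max(1, cancel))
}

# ---- public operations -----------------------------------------------------

#' Fisher's method: combine equally weighted p-values
#'
#' Combines `L` p-values with equal weight.  The statistic is
#' `t0 = -sum(log(p_i))`, distributed as Erlang(`L`, 1) under the null, so
#' the combined p-value is the regularized upper incomplete gamma function
#' `Q(L, t0)`.  Any weights in the set are ignored: with a common weight
#' the combined value is provably weight independent.
#'
#' @param set a [weighted_pvalues()] set.
#' @return a `combination_result`.
#' @examples
#' fisher_combine(weighted_pvalues(c(0.5, 0.5)))$pvalue  # 0.25 * (1 + log 4)
#' @export
fisher_combine <- function(set) {
  set <- validate_weighted_pvalues(set)
  t0 <- -sum(log(set$pvalues))
  p <- stats::pgamma(t0, shape = length(set$pvalues), lower.tail = FALSE)
  combination_result(p, "fisher", t0, precision_digits = 16)
}

#' Good's formula: combine p-values with all-distinct weights
#'
#' Evaluates `P = sum_i c_i V^(1/w_i)` with `V = prod p_k^(w_k)` carried in
#' log space and `c_i = prod_{k != i} (1 - w_k/w_i)^(-1)`.  The pairwise
#' weight differences in the denominators make the formula ill-conditioned
#' when weights are close: the terms grow while their sum stays in [0, 1].
#' The result therefore carries a `cancellation_index`
#' (`sum |term| / |sum term|`); when it exceeds `warn_threshold` a warning
#' of class `pcombine_cancellation_warning` is emitted, and by default the
#' formula is evaluated in extended precision.  Exactly equal weights are
#' refused (use [gc_combine()] or [expansion_combine()]): perturbing them
#' silently would hide the instability.
#'
#' @param set a [weighted_pvalues()] set with pairwise distinct normalized
#'   inverse weights.
#' @param digits decimal digits to evaluate with; `digits <= 16` uses
#'   native double precision (this is the numerically fragile route the
#'   expansion exists to replace).
#' @param warn_threshold cancellation-index level above which a warning is
#'   emitted.
#' @return a `combination_result`.
#' @export
good_combine <- function(set, digits = 50, warn_threshold = 1e6) {
  set <- validate_weighted_pvalues(set)
  lam <- normalize_inverse_weights(set)
  if (anyDuplicated(lam)) {
    pc_stop(paste0("weights are exactly degenerate (equal normalized ",
                   "inverse weights); use gc_combine() or ",
                   "expansion_combine()"),
            class = "pcombine_degenerate_weights_error")
  }
  t <- sum(-log(set$pvalues) / lam)
  L <- length(lam)
  if (L == 1L) {
    return(combination_result(set$pvalues, "good", t,
                              cancellation_index = 1,
                              precision_digits = digits))
  }
  if (digits <= 16) {
    terms <- vapply(seq_len(L), function(i) {
      exp(-lam[i] * t) * prod(lam[-i] / (lam[-i] - lam[i]))
    }, numeric(1))
    raw <- sum(terms)
    cancel <- sum(abs(terms)) / abs(raw)
  } else {
    ctx <- hp_ctx(digits)
    lamH <- lapply(lam, hp_from_double, ctx = ctx)
    tH <- hp_from_double(t, ctx)
    S <- hp_zero(); abs_sum <- hp_zero()
    for (i in seq_len(L)) {
      term <- hp_exp(hp_neg(hp_mul(lamH[[i]], tH, ctx)), ctx)
      for (k in seq_len(L)[-i]) {
        term <- hp_mul(term,
                       hp_div(lamH[[k]],
                              hp_sub(lamH[[k]], lamH[[i]], ctx), ctx), ctx)
      }
      S <- hp_add(S, term, ctx)
      abs_sum <- hp_add(abs_sum, hp_abs(term), ctx)
    }
    raw <- hp_to_double(S)
    cancel <- if (hp_is_zero(S)) Inf else {
      max(1, 10^(hp_log10_abs(abs_sum) - hp_log10_abs(S)))
    }
  }
  if (is.finite(cancel) && cancel > warn_threshold || !is.finite(cancel)) {
    pc_warn(sprintf(
      "good_combine: cancellation index %.3g exceeds %.3g; %s",
      cancel, warn_threshold,
      if (digits <= 16) "increase `digits` or use expansion_combine()"
      else "result may need more digits or expansion_combine()"),
      class = "pcombine_cancellation_warning")
  }
  combination_result(raw, "good", t, cancellation_index = cancel,
                     precision_digits = digits)
}

#' Exact general case: grouped weights
#'
#' The survival probability at `t` of a sum of `L` unit-mean-scaled
#' exponentials grouped into `m` distinct rates `lambda_j` with
#' multiplicities `N_j` -- the hypoexponential distribution with repeated
#' rates.  Interpolates Fisher (`m = 1`) and Good (all `N_j = 1`).
#' Computed by partial fractions; evaluated in extended precision by
#' default because the formula's intrinsic cancellation makes double
#' precision meaningless for nearly degenerate rates.
#'
#' @param params a [gc_parameters()] object (or a [weighted_pvalues()] set,
#'   which is grouped via [as_gc_parameters()]).
#' @param digits decimal digits; `digits <= 16` uses native doubles.
#' @param warn_threshold cancellation-index warning level.
#' @return a `combination_result`.
#' @examples
#' # Erlang(3, 1) at t = 2: 5 * exp(-2)
#' gc_combine(gc_parameters(1, 3, 2))$pvalue
#' @export
gc_combine <- function(params, digits = 50, warn_threshold = 1e6) {
  if (inherits(params, "weighted_pvalues")) params <- as_gc_parameters(params)
  if (!inherits(params, "gc_parameters")) {
    pc_stop("params must be a gc_parameters object or weighted_pvalues set")
  }
  if (digits <= 16) {
    res <- gc_survival_double(params$rates, params$multiplicities, params$t,
                              terms = TRUE)
    raw <- res$value
    cancel <- max(1, sum(abs(res$terms)) / abs(raw))
  } else {
    res <- gc_survival_hp(params$rates, params$multiplicities, params$t,
                          hp_ctx(digits))
    raw <- res$value
    cancel <- res$cancellation_index
  }
  if (!is.finite(cancel) || cancel > warn_threshold) {
    pc_warn(sprintf(
      "gc_combine: cancellation index %.3g exceeds %.3g; increase `digits` or use expansion_combine()",
      cancel, warn_threshold),
      class = "pcombine_cancellation_warning")
  }
  combination_result(raw, "gc", params$t, cancellation_index = cancel,
                     precision_digits = digits)
}

#' Partial-fraction coefficients of the grouped-rate pole product
#'
#' Decomposes `prod_j (lambda_j + s)^(-N_j)` into
#' `sum_{j,k} c_{jk} / (lambda_j + s)^k`, `1 <= k <= N_j`.  Two independent
#' routes are implemented: `"derivative"` (default) uses the
#' exponential-of-series recurrence on the log of the cross-factor product;
#' `"index_sum"` expands each cross factor as a binomial series and sums
#' over constrained index patterns.  Both must agree; the second is
#' retained as a cross-check of the first.
#'
#' @param params a [gc_parameters()] object (`t` is ignored here).
#' @param method `"derivative"` or `"index_sum"`.
#' @return an object of class `partial_fraction_coefficients`: a list with
#'   `coefficients` (a list over `j` of numeric vectors indexed by `k`),
#'   `rates`, `multiplicities` and the overall `prefactor`
#'   `prod_j lambda_j^{N_j}`.
#' @export
partial_fraction_coefficients <- function(params,
                                          method = c("derivative",
                                                     "index_sum")) {
  method <- match.arg(method)
  if (!inherits(params, "gc_parameters")) {
    pc_stop("params must be a gc_parameters object")
  }
  rates <- params$rates
  mults <- params$multiplicities
  C <- if (method == "derivative") {
    pf_coeffs_double(rates, mults)
  } else {
    pf_coeffs_index_sum(rates, mults)
  }
  structure(
    list(coefficients = C, rates = rates, multiplicities = mults,
         prefactor = prod(rates^mults), method = method),
    class = "partial_fraction_coefficients"
  )
}

# Constrained-index-sum route: around s = -lambda_j,
#   (lambda_l + s)^(-N_l) = sum_k choose(N_l+k-1, k) (-x)^k (lambda_l-lambda_j)^(-N_l-k)
# and c_{j,k} is the coefficient of x^(N_j - k) in the product over l != j,
# i.e. a sum over all index patterns {k_l} with sum k_l = N_j - k.
pf_coeffs_index_sum <- function(rates, mults) {
  m <- length(rates)
  C <- vector("list", m)
  compositions <- function(total, parts) {
    if (parts == 0L) {
      if (total == 0L) return(list(integer(0))) else return(list())
    }
    out <- list()
    for (first in 0:total) {
      for (rest in compositions(total - first, parts - 1L)) {
        out[[length(out) + 1L]] <- c(first, rest)
      }
    }
    out
  }
  for (j in seq_len(m)) {
    Nj <- mults[j]
    diffs <- rates[-j] - rates[j]
    Nl <- mults[-j]
    coefs <- numeric(Nj)
    for (k in seq_len(Nj)) {
      n <- Nj - k
      total <- 0
      for (pat in compositions(n, length(Nl))) {
        total <- total + prod(
          choose(Nl + pat - 1, pat) * (-1)^pat * diffs^(-(Nl + pat))
        )
      }
      coefs[k] <- total
    }
    C[[j]] <- coefs
  }
  C
}

# Evaluate sum_{j,k} c_{jk}/(lambda_j + s)^k at a probe point; used by the
# reconstruction-identity tests.
pf_reconstruct <- function(pf, s) {
  total <- 0
  for (j in seq_along(pf$rates)) {
    for (k in seq_len(pf$multiplicities[j])) {
      total <- total + pf$coefficients[[j]][k] / (pf$rates[j] + s)^k
    }
  }
  total
}
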