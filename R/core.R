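# Domain types and the weighted log statistic.

pc_stop <- function(msg, class = "pcombine_domain_error") {
  stop(structure(
    class = c(class, "pcombine_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

pc_warn <- function(msg, class = "pcombine_warning") {
  warning(structure(
    class = c(class, "pcombine_warning_generic", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' A set of independent p-values with positive weights
#'
#' The user-facing input of every combination method: `L` p-values
#' `p_i` in (0, 1] together with strictly positive, finite weights `w_i`.
#' Only the ratios of the weights matter for the combined p-value.
#'
#' @param pvalues numeric vector of p-values, each in (0, 1].  A p-value of
#'   exactly 1 is legal (it contributes nothing); a p-value of exactly 0 is
#'   an error, because it makes the combined statistic infinite and the
#'   caller should decide how to handle it.
#' @param weights numeric vector of positive finite weights, same length as
#'   `pvalues`.  Defaults to equal weights.
#' @param ids optional character labels for the records, used in error
#'   messages and reports.
#' @return an object of class `weighted_pvalues` with elements `pvalues`,
#'   `weights` and `ids`.
#' @examples
#' s <- weighted_pvalues(c(0.01, 0.2, 0.03), c(1, 2, 1.5))
#' weighted_log_statistic(s)
#' @export
weighted_pvalues <- function(pvalues,
                             weights = rep(1, length(pvalues)),
                             ids = NULL) {
  if (is.null(ids)) ids <- as.character(seq_along(pvalues))
  set <- structure(
    list(pvalues = as.numeric(pvalues), weights = as.numeric(weights),
         ids = as.character(ids)),
    class = "weighted_pvalues"
  )
  validate_weighted_pvalues(set)
}

#' Validate a weighted p-value set
#'
#' Checks the invariants of [weighted_pvalues()]: non-empty, equal lengths,
#' every p-value in (0, 1], every weight positive and finite.  Errors name
#' the offending record.
#'
#' @param set a `weighted_pvalues` object (or a bare list with the same
#'   fields).
#' @return the set, unchanged, if all invariants hold.
#' @export
validate_weighted_pvalues <- function(set) {
  p <- set$pvalues
  w <- set$weights
  ids <- if (!is.null(set$ids)) set$ids else as.character(seq_along(p))
  if (length(p) < 1L) {
    pc_stop("empty input: at least one p-value is required")
  }
  if (length(p) != length(w)) {
    pc_stop(sprintf("lengths differ: %d p-values but %d weights",
                    length(p), length(w)))
  }
  bad <- which(!is.finite(p) | p <= 0 | p > 1)
  if (length(bad)) {
    pc_stop(sprintf("p-value out of (0, 1] for record '%s': %s",
                    ids[bad[1L]], format(p[bad[1L]])))
  }
  bad <- which(!is.finite(w) | w <= 0)
  if (length(bad)) {
    pc_stop(sprintf("weight not a positive finite number for record '%s': %s",
                    ids[bad[1L]], format(w[bad[1L]])))
  }
  set
}

#' @export
print.weighted_pvalues <- function(x, ...) {
  cat(sprintf("Weighted p-value set: L = %d\n", length(x$pvalues)))
  df <- data.frame(id = x$ids, p_value = x$pvalues, weight = x$weights)
  print(utils::head(df, 10L), row.names = FALSE)
  if (nrow(df) > 10L) cat(sprintf("... and %d more records\n", nrow(df) - 10L))
  invisible(x)
}

#' Weighted log statistic
#'
#' The observed value of the combination statistic,
#' `t = -sum_i w_i * log(p_i)`, carried entirely in log space so that the
#' product of p-values is never formed (it underflows for modest `L`).
#' The combined p-value of every method in this package is the probability
#' that a weighted sum of unit exponentials exceeds this statistic.
#'
#' @param set a validated [weighted_pvalues()] set.
#' @return a single non-negative number.
#' @export
weighted_log_statistic <- function(set) {
  set <- validate_weighted_pvalues(set)
  -sum(set$weights * log(set$pvalues))
}

# The same statistic on the normalized inverse-weight scale (inverse
# weights rescaled to sum to L).  Internal: all grouped/expanded methods
# work on this scale; the result is identical by scale invariance.
statistic_normalized <- function(set) {
  lam <- normalize_inverse_weights(set)
  sum(-log(set$pvalues) / lam)
}

#' Grouped parameters for the exact general case
#'
#' The input of the exact grouped-weights formula: `m` distinct inverse
#' weights (rates) in strictly ascending order, the number of p-values
#' carrying each rate, and the observed statistic `t`.  The combined
#' p-value is the survival function at `t` of a sum of `L = sum(N_j)`
#' exponential variables, `N_j` of them with rate `lambda_j` (the
#' hypoexponential distribution with repeated rates).
#'
#' @param rates strictly ascending vector of positive rates (inverse
#'   weights) `lambda_j`.
#' @param multiplicities positive integers `N_j`, one per rate.
#' @param t observed statistic, a non-negative number.
#' @return an object of class `gc_parameters`.
#' @seealso [gc_combine()], [as_gc_parameters()]
#' @export
gc_parameters <- function(rates, multiplicities, t) {
  rates <- as.numeric(rates)
  multiplicities <- as.integer(multiplicities)
  if (length(rates) < 1L || length(rates) != length(multiplicities)) {
    pc_stop("rates and multiplicities must be non-empty and equal length")
  }
  if (any(!is.finite(rates) | rates <= 0)) {
    pc_stop("all rates must be positive and finite")
  }
  if (any(diff(rates) <= 0)) {
    pc_stop("rates must be strictly ascending (merge duplicates first)")
  }
  if (any(multiplicities < 1L)) {
    pc_stop("all multiplicities must be positive integers")
  }
  if (!is.finite(t) || t < 0) {
    pc_stop("the statistic t must be a non-negative number")
  }
  structure(list(rates = rates, multiplicities = multiplicities, t = t),
            class = "gc_parameters")
}

#' Group a weighted p-value set into general-case parameters
#'
#' Normalizes the inverse weights (see [normalize_inverse_weights()]),
#' groups records whose normalized inverse weights are exactly equal, and
#' computes the statistic on the normalized scale.
#'
#' @param set a [weighted_pvalues()] set.
#' @return a [gc_parameters()] object.
#' @export
as_gc_parameters <- function(set) {
  set <- validate_weighted_pvalues(set)
  lam <- normalize_inverse_weights(set)
  t <- sum(-log(set$pvalues) / lam)
  u <- sort(unique(lam))
  mult <- vapply(u, function(v) sum(lam == v), integer(1))
  gc_parameters(u, mult, t)
}

#' @export
print.gc_parameters <- function(x, ...) {
  cat(sprintf("General-case parameters: m = %d groups, L = %d, t = %g\n",
              length(x$rates), sum(x$multiplicities), x$t))
  print(data.frame(rate = x$rates, multiplicity = x$multiplicities),
        row.names = FALSE)
  invisible(x)
}

# Result container shared by all methods.
combination_result <- function(raw, method, t,
                               order_used = NA_integer_,
                               truncation_bound = NA_real_,
                               cancellation_index = NA_real_,
                               precision_digits = NA_real_,
                               details = NULL) {
  clipped <- is.finite(raw) && (raw < 0 || raw > 1)
  pvalue <- min(max(raw, 0), 1)
  structure(
    list(pvalue = pvalue, raw_pvalue = raw, method = method, t = t,
         order_used = order_used, truncation_bound = truncation_bound,
         cancellation_index = cancellation_index, clipped = clipped,
         precision_digits = precision_digits, details = details),
    class = "combination_result"
  )
}

#' @export
print.combination_result <- function(x, ...) {
  cat(sprintf("Combined p-value: %.10g  (method: %s)\n", x$pvalue, x$method))
  cat(sprintf("  statistic t = %g\n", x$t))
  if (!is.na(x$order_used)) {
    cat(sprintf("  expansion order = %d, truncation bound = %.3g\n",
                x$order_used, x$truncation_bound))
  }
  if (!is.na(x$cancellation_index)) {
    cat(sprintf("  cancellation index = %.3g\n", x$cancellation_index))
  }
  if (x$clipped) {
    cat(sprintf("  WARNING: raw value %.6g outside [0, 1]; clipped\n",
                x$raw_pvalue))
  }
  invisible(x)
}
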