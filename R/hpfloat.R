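# Minimal arbitrary-precision decimal floating point, pure R.
#
# The exact combination formulas (Good's formula, the grouped general case)
# suffer catastrophic cancellation when inverse weights are nearly
# degenerate; evaluating them faithfully requires more than double
# precision.  No arbitrary-precision arithmetic package is available in the
# target environment, so this file provides the small subset of operations
# the package needs: +, -, *, /, integer powers, exp, and conversions.
#
# Representation: a number is list(s, e, d) with sign s in {-1, 0, 1},
# limbs d (base 1e7, most significant first, d[1] != 0 when s != 0) and
# exponent e such that  value = s * sum(d[i] * BASE^(e - i)).
# All limb arithmetic stays below 2^53 so plain doubles carry it exactly.

.HP_BASE <- 1e7

#' Create an extended-precision context
#'
#' @param digits number of decimal digits to carry (1 to 150).
#' @return a list with the working precision; passed to the `hp_*` helpers.
#' @keywords internal
#' @noRd
hp_ctx <- function(digits = 50) {
  stopifnot(is.numeric(digits), length(digits) == 1L, digits >= 1, digits <= 150)
  list(digits = digits, nl = as.integer(ceiling((digits + 14) / 7)) + 2L)
}

hp_zero <- function() list(s = 0L, e = 0L, d = numeric(0))

hp_is_zero <- function(a) a$s == 0L

# Resolve carries/borrows so every limb lies in [0, BASE).  Entries may be
# negative (borrow) or >= BASE (carry); the leading limbs must be able to
# absorb any final carry, so callers prepend guard zeros.
hp_fix <- function(v) {
  repeat {
    q <- floor(v / .HP_BASE)
    if (!any(q != 0)) return(v)
    v <- v - q * .HP_BASE
    n <- length(v)
    v[-n] <- v[-n] + q[-1L]
    if (q[1L] != 0) stop("hp_fix: carry out of guard limb")
  }
}

# Normalize a raw limb vector into canonical form, truncating to working
# precision.  `d` entries must already be in [0, BASE).
hp_make <- function(s, e, d, ctx) {
  n <- length(d)
  i <- 1L
  while (i <= n && d[i] == 0) i <- i + 1L
  if (i > n) return(hp_zero())
  if (i > 1L) {
    d <- d[i:n]
    e <- e - (i - 1L)
  }
  if (length(d) > ctx$nl) d <- d[seq_len(ctx$nl)]
  j <- length(d)
  while (j > 1L && d[j] == 0) j <- j - 1L
  list(s = as.integer(s), e = as.integer(e), d = d[seq_len(j)])
}

hp_from_int <- function(n, ctx) {
  stopifnot(abs(n) < 2^53)
  s <- sign(n)
  n <- abs(n)
  if (n == 0) return(hp_zero())
  d <- numeric(0)
  while (n > 0) {
    d <- c(n %% .HP_BASE, d)
    n <- n %/% .HP_BASE
  }
  hp_make(s, length(d), d, ctx)
}

# Multiply by 2^k exactly (used for double conversion and exp range
# reduction).  Chunked so limb products stay exact.
hp_scale2 <- function(a, k, ctx) {
  if (a$s == 0L || k == 0) return(a)
  if (k > 0) {
    while (k > 0) {
      step <- min(k, 26L)           # 2^26 < 1e8: safe for hp_mul_small
      a <- hp_mul_small(a, 2^step, ctx)
      k <- k - step
    }
  } else {
    k <- -k
    while (k > 0) {
      step <- min(k, 23L)           # 2^23 < 1e7: safe for hp_div_small
      a <- hp_div_small(a, 2^step, ctx)
      k <- k - step
    }
  }
  a
}

# Exact conversion from double: decompose into 53-bit mantissa and binary
# exponent, so hp(x) equals the double bit-for-bit.
hp_from_double <- function(x, ctx) {
  if (!is.finite(x)) stop("hp_from_double: non-finite input")
  if (x == 0) return(hp_zero())
  if (abs(x) < 2^-900) {            # near-subnormal: rescale exactly first
    return(hp_scale2(hp_from_double(x * 2^600, ctx), -600L, ctx))
  }
  e2 <- floor(log2(abs(x)))
  m <- x / 2^(e2 - 52)
  if (abs(m) >= 2^53) {             # log2 rounded down a hair
    e2 <- e2 + 1
    m <- m / 2
  }
  if (m != round(m)) {              # subnormal or log2 rounded up
    e2 <- e2 - 1
    m <- m * 2
  }
  stopifnot(m == round(m))
  hp_scale2(hp_from_int(m, ctx), e2 - 52, ctx)
}

hp_to_double <- function(a) {
  if (a$s == 0L) return(0)
  n <- min(length(a$d), 4L)
  f <- 0
  for (i in seq_len(n)) f <- f + a$d[i] * .HP_BASE^(-i)
  dec <- a$e * 7
  if (dec > 320) return(a$s * Inf)
  if (dec < -340) return(a$s * 0)
  a$s * f * 10^dec
}

# Approximate base-10 magnitude, safe for values far outside double range.
hp_log10_abs <- function(a) {
  if (a$s == 0L) return(-Inf)
  log10(a$d[1] + if (length(a$d) > 1L) a$d[2] / .HP_BASE else 0) + 7 * (a$e - 1)
}

hp_neg <- function(a) {
  a$s <- -a$s
  a
}

hp_abs <- function(a) {
  a$s <- abs(a$s)
  a
}

hp_cmp_abs <- function(a, b) {
  if (a$s == 0L) return(if (b$s == 0L) 0L else -1L)
  if (b$s == 0L) return(1L)
  if (a$e != b$e) return(if (a$e > b$e) 1L else -1L)
  la <- length(a$d); lb <- length(b$d); n <- max(la, lb)
  da <- c(a$d, numeric(n - la))
  db <- c(b$d, numeric(n - lb))
  dd <- da - db
  i <- which(dd != 0)
  if (length(i) == 0L) return(0L)
  if (dd[i[1L]] > 0) 1L else -1L
}

hp_cmp <- function(a, b) {
  if (a$s != b$s) return(if (a$s > b$s) 1L else -1L)
  if (a$s == 0L) return(0L)
  a$s * hp_cmp_abs(a, b)
}

hp_add <- function(a, b, ctx) {
  if (a$s == 0L) return(b)
  if (b$s == 0L) return(a)
  if (hp_cmp_abs(a, b) < 0) { tmp <- a; a <- b; b <- tmp }
  off <- a$e - b$e
  if (off > ctx$nl + 3L) return(a)
  la <- length(a$d); lb <- length(b$d)
  n <- max(la, off + lb)
  v <- numeric(n)
  v[seq_len(la)] <- a$d
  idx <- off + seq_len(lb)
  if (a$s == b$s) v[idx] <- v[idx] + b$d else v[idx] <- v[idx] - b$d
  v <- hp_fix(c(0, v))
  hp_make(a$s, a$e + 1L, v, ctx)
}

hp_sub <- function(a, b, ctx) hp_add(a, hp_neg(b), ctx)

# Schoolbook multiplication.  Column sums stay below ~26 * (1e7)^2 < 2^53,
# exact in doubles for every precision this package supports.
hp_mul <- function(a, b, ctx) {
  if (a$s == 0L || b$s == 0L) return(hp_zero())
  la <- length(a$d); lb <- length(b$d)
  w <- numeric(la + lb)
  for (i in seq_len(la)) {
    idx <- i + seq_len(lb)
    w[idx] <- w[idx] + a$d[i] * b$d
  }
  w <- hp_fix(c(0, w))
  hp_make(a$s * b$s, a$e + b$e + 1L, w, ctx)
}

hp_mul_small <- function(a, m, ctx) {
  if (a$s == 0L || m == 0) return(hp_zero())
  s <- a$s * sign(m)
  m <- abs(m)
  stopifnot(m < 1e8, m == round(m))
  v <- hp_fix(c(0, 0, a$d * m))
  hp_make(s, a$e + 2L, v, ctx)
}

hp_div_small <- function(a, m, ctx) {
  if (a$s == 0L) return(hp_zero())
  s <- a$s * sign(m)
  m <- abs(m)
  stopifnot(m <= 1e7, m == round(m), m > 0)
  len <- ctx$nl + 2L
  d <- a$d
  if (length(d) < len) d <- c(d, numeric(len - length(d)))
  q <- numeric(len)
  r <- 0
  for (i in seq_len(len)) {
    v <- r * .HP_BASE + d[i]
    qi <- floor(v / m)
    ri <- v - qi * m
    if (ri < 0) { qi <- qi - 1; ri <- ri + m }
    if (ri >= m) { qi <- qi + 1; ri <- ri - m }
    q[i] <- qi
    r <- ri
  }
  hp_make(s, a$e, q, ctx)
}

# Reciprocal by Newton iteration x <- x + x(1 - b x); the seed comes from a
# double estimate of the leading limbs, so convergence is quadratic from
# ~15 digits.
hp_recip <- function(b, ctx) {
  if (b$s == 0L) stop("hp_recip: division by zero")
  f <- b$d[1L] * 1e-7
  if (length(b$d) > 1L) f <- f + b$d[2L] * 1e-14
  if (length(b$d) > 2L) f <- f + b$d[3L] * 1e-21
  x <- hp_from_double(1 / f, ctx)
  x$e <- x$e - b$e
  x$s <- b$s
  one <- hp_from_int(1, ctx)
  iters <- max(3L, as.integer(ceiling(log2((ctx$digits + 10) / 13))) + 2L)
  for (i in seq_len(iters)) {
    err <- hp_sub(one, hp_mul(b, x, ctx), ctx)
    x <- hp_add(x, hp_mul(x, err, ctx), ctx)
  }
  x
}

hp_div <- function(a, b, ctx) hp_mul(a, hp_recip(b, ctx), ctx)

hp_pow_int <- function(a, n, ctx) {
  stopifnot(n == round(n))
  if (n < 0) return(hp_pow_int(hp_recip(a, ctx), -n, ctx))
  res <- hp_from_int(1, ctx)
  base <- a
  while (n > 0) {
    if (n %% 2 == 1) res <- hp_mul(res, base, ctx)
    n <- n %/% 2
    if (n > 0) base <- hp_mul(base, base, ctx)
  }
  res
}

# exp by range reduction (halving until |r| <= 1/4), Taylor series, and
# repeated squaring.  Guard limbs in the context absorb the squaring loss.
hp_exp <- function(x, ctx) {
  if (x$s == 0L) return(hp_from_int(1, ctx))
  xd <- hp_to_double(x)
  if (!is.finite(xd) || abs(xd) > 1e5) {
    stop("hp_exp: |argument| too large (", format(xd), ")")
  }
  k <- 0L
  if (abs(xd) > 0.25) k <- as.integer(ceiling(log2(abs(xd) / 0.25)))
  r <- hp_scale2(x, -k, ctx)
  s <- hp_from_int(1, ctx)
  term <- hp_from_int(1, ctx)
  n <- 0
  repeat {
    n <- n + 1
    term <- hp_div_small(hp_mul(term, r, ctx), n, ctx)
    if (term$s == 0L || term$e < s$e - (ctx$nl + 1L)) break
    s <- hp_add(s, term, ctx)
    if (n > 1000) stop("hp_exp: series failed to converge")
  }
  for (i in seq_len(k)) s <- hp_mul(s, s, ctx)
  s
}
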