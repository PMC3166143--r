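---
title: "Combining weighted p-values: model, numerics, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combining weighted p-values: model, numerics, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcombine)
```

## The model

Given `L` independent p-values `p_i` with positive weights `w_i`, the
combined significance is the tail probability of the weighted log
statistic. Under the null each `p_i` is uniform on (0, 1], so
`-log p_i` is a unit exponential `E_i`, and

$$t = -\sum_i w_i \log p_i, \qquad P = \Pr\Big(\sum_i w_i E_i \ge t\Big).$$

`T = Σ w_i E_i` is a weighted sum of exponentials; its survival function
evaluated at the observed `t` is the combined p-value. Everything in this
package is a way of computing that survival function. Two assumptions are
load-bearing: the p-values are *independent*, and they are *continuous*
(uniform under the null). Correlated or discrete p-values are outside the
model; so is any recipe for choosing the weights themselves, which encode
how much each test is trusted and must come from the user.

Because `T` scales with the weights while `t` scales identically, only
weight *ratios* matter. The package therefore normalizes inverse weights
`λ_i = 1/w_i` so that `Σ λ_i = L` (mean inverse weight exactly 1), and
all radii and tolerances below live on that scale.

## The four methods

**Equal weights** (`fisher_combine`). `T` is Erlang(`L`, 1) and
`P = Q(L, t₀)` with `t₀ = -Σ log p_i`, the regularized upper incomplete
gamma function. The result is provably independent of the common weight,
so weights are ignored.

**All weights distinct** (`good_combine`).
`P = Σ_i c_i e^{-λ_i t}` with `c_i = Π_{k≠i} λ_k/(λ_k - λ_i)`. The
product `V = Π p_k^{w_k}` is never formed; it is carried as the log-space
statistic (for modest `L`, `V` underflows doubles). The pairwise
differences in the denominators are the method's Achilles heel: for
nearly equal weights the `c_i` diverge while `P` stays in [0, 1], so the
sum cancels catastrophically. The result object carries a
`cancellation_index`, `Σ|term| / |Σ term|`; its base-10 logarithm is the
number of decimal digits the evaluation burned. Above `1e6` a warning of
class `pcombine_cancellation_warning` fires (threshold chosen as the
point where fewer than 10 of 16 double digits survive — the classical
"hold more decimal places" signal). Exactly equal weights are refused
rather than perturbed: perturbation would silently reintroduce the
instability this package exists to expose, and the grouped formula is the
correct tool.

**Grouped weights** (`gc_combine`). With `m` distinct rates `λ_j` of
multiplicity `N_j` (`Σ N_j = L`), `T` is hypoexponential with repeated
rates. Partial fractions of `Π_j (λ_j + s)^{-N_j}` give

$$P = \Lambda \sum_{j=1}^m \sum_{k=1}^{N_j} c_{jk}
      \frac{Q(k, \lambda_j t)}{\lambda_j^{k}}, \qquad
  \Lambda = \prod_j \lambda_j^{N_j}.$$

The pole coefficients come from an exponential-of-series recurrence on
the log of the cross-factor product — `E_0 = Π_{l≠j}(λ_l-λ_j)^{-N_l}`,
`E_n = n^{-1} Σ_k β_k E_{n-k}` with `β_k = (-1)^k Σ_l N_l (λ_l-λ_j)^{-k}`
— which needs no factorials and no symbolic differentiation. An
independent constrained-index-sum route to the same coefficients is
retained (`partial_fraction_coefficients(..., method = "index_sum")`) and
the two are required to agree in the test suite, along with the
reconstruction identity at probe points. `m = 1` reduces to Fisher; all
`N_j = 1` reduces to Good.

**Nearly degenerate weights** (`expansion_combine`) — the package's main
method, described next.

## The controlled expansion

Cluster the normalized inverse weights (greedy merge, below) and write
each as `λ_{j,i} = λ̄_j + δ_{j,i}` about its cluster mean. In the
inversion integral of the characteristic function the pole product
factors as

$$\prod_{j,i} \frac{1}{\lambda_{j,i}+s}
  = \prod_j \frac{1}{(\bar\lambda_j+s)^{N_j}}
    \exp\Big(\sum_j \sum_{k\ge 2} \frac{(-1)^k D_{j,k}}{k}\, z_j^k\Big),
  \qquad z_j = \frac{1}{\bar\lambda_j+s},$$

where `D_{j,k} = Σ_i δ_{j,i}^k`. The `k = 1` term is absent because
centers are member means (`D_{j,1} = 0`). Taylor-expanding the
exponential and collecting equal total powers of `δ` turns every monomial
`Π_j z_j^{k_j}` into the *same* grouped survival function with
multiplicities shifted `N_j → N_j + k_j`, evaluated at the well-separated
centers. The degeneracy has moved out of the pole denominators into the
small coefficients: with per-cluster series
`E_{j,0} = 1`, `E_{j,n} = n^{-1} Σ_{k=2}^{n} (-1)^k D_{j,k} E_{j,n-k}`,
a shift pattern `{k_j}` carries coefficient `Π_j E_{j,k_j}`. Explicitly,
order 2 carries `D_{j,2}/2` per cluster, order 3 carries `-D_{j,3}/3`
(zero for clusters symmetric about their center), and order 4 carries
`D_{j,4}/4 + D_{j,2}²/8` per cluster plus the first cross-cluster
products `(D_{j,2}/2)(D_{j',2}/2)`. The exact prefactor
`A = Π_{j,i}(1 + δ_{j,i}/λ̄_j)` is kept outside the expansion
(evaluated by `log1p`), so with radius 0 — all deviations zero — the
method reproduces the exact grouped formula *term for term*, bit for bit.

The default order is 4, the first order at which clusters mix; orders up
to 6 are available. Base functions are evaluated in plain doubles by
default (`precision_digits = 16`): double-precision stability is the
method's headline property, and the extended-precision engine is reserved
for the exact formulas and oracles.

### Truncation bound

Let `ρ = max_{j,i} |δ_{j,i}|/λ̄_j` (requires `ρ < 1`; otherwise the bound
is refused with advice to shrink the radius). Two majorizations bound the
tail beyond order `k`:

* *Coefficients*: the absolute coefficient mass at order `n`, including
  the `Π λ̄_j^{-k_j}` factors, is at most `C(L+n-1, n) ρⁿ` (geometric
  series bound on each `(1 + δ z)^{-1}` factor).
* *Base functions*: replacing any added exponential summand by one at the
  smallest center rate increases the sum stochastically, so every
  order-`n` base factor is dominated by the base function with all `n`
  shifts on the smallest-center cluster.

The bound sums these majorants explicitly for several orders past `k`
and closes the tail geometrically once the ratio
`ρ (L+n)/(n+1) × [base ratio]` falls below 0.95. Because the bound
certifies a *finite-precision* partial sum, an evaluation-noise term
`32 ε · (cancellation index of the zeroth base) · |P₀|` is added: without
it the bound would be violated by roundoff whenever the true truncation
error sits below the noise floor. With all deviations exactly zero the
partial sums are bit-identical and the bound is exactly 0. Dominance of
the bound over `|P_{k+2} - P_k|` is verified empirically on the fixture
suite; the geometric closure assumes the base-function step ratio is
non-increasing in `n`, which holds on every fixture tested but is not
proved, so the bound is best read as a sharp, empirically validated
majorant rather than a theorem.

## Normalization and clustering choices

The greedy merge sorts the normalized inverse weights, pre-merges exact
duplicates (identical values are one cluster whatever the radius), then
repeatedly merges the closest pair of current cluster centers — by
occurrence-weighted mean — while their gap is strictly below `r`.
Decisions a reader might wonder about:

* *Strict inequality*: a gap exactly equal to `r` does **not** merge;
  termination requires all gaps `≥ r`.
* *Ties*: when several pairs are equally close, the leftmost (after
  ascending sort) merges first. Any fixed rule would do; this one is
  deterministic and order-independent.
* *Distances between centers*, not member extremes: matches the
  iterative averaging of the merge itself, and makes re-clustering the
  terminated centers a no-op (idempotence, tested).
* *Final centers are recomputed as exact member means*, so `Σ_i δ_{j,i}`
  vanishes to machine precision and the order-1 term is genuinely absent.
* *Default radius 0.05* on the normalized scale: clusters tighter than 5%
  of the mean inverse weight give `ρ ≲ 0.05`, putting the order-4
  truncation bound far below any plausible reporting precision, while
  centers at least 0.05 apart keep the double-precision base functions
  well conditioned. The alternative `radius = "auto"` tries
  0.1, 0.05, 0.02, 0.01, 0 and keeps the largest radius whose truncation
  bound (including its noise term) meets `accuracy_goal` relative to the
  zeroth-order value, skipping radii whose base evaluations are unstable
  (non-positive majorants or cancellation index above `1e6`).

## Extended precision

The exact formulas need more than 16 digits exactly when weights are
nearly degenerate — the regime of interest — so `gc_combine`,
`good_combine` and the quadrature oracle evaluate at 50 decimal digits by
default. No arbitrary-precision package is assumed: the package carries a
small base-1e7 decimal floating-point engine (`R/hpfloat.R`) with exact
double conversion (crucially, differences of nearly equal doubles are
computed exactly), Newton-iteration division, and `exp` by halving plus
Taylor plus squaring. Fifty digits comfortably covers cancellation
indices up to ~1e30; the worked example with weights equal to five
decimal places burns 15-17 digits. The engine supports up to 150 digits;
beyond that limb sums would overflow the 2^53 integer range of doubles.

## Oracles

*Monte-Carlo*: `T` is sampled directly as `Σ w_i E_i` from seeded unit
exponentials (the caller's RNG state is saved and restored); the
estimate's binomial standard error accompanies it. Agreement is always
judged in standard-error units, with the analytic value supplying the
standard error when the empirical one degenerates (estimate 0 or 1).

*Quadrature*: two routes. Route (a) evaluates the partial-fraction
survival form at 50 digits. Route (b) integrates the
characteristic-function inversion integral along the contour
`Im ω = -λ_min/2`, below which no poles lie: panelwise 16-point
Gauss-Legendre on `[0, X]` with panels no wider than half an oscillation
period, then a non-oscillatory vertical descent from `X` (integrand
decays like `e^{-yt}`), exploiting Hermitian symmetry to take twice the
real part. Route (b) runs in doubles; its error model is machine epsilon
times the contour cancellation factor `e^{(λ_min - a)t}`, and the two
routes are cross-checked on every call at that tolerance (floored at 8
significant digits). A disagreement raises an error rather than a
warning: an oracle that disagrees with itself must never return a value.

## What the synthetic fixtures do and do not establish

`generate_fixture` produces the four weight regimes the methods
distinguish — well separated, nearly degenerate (spread ~1e-5 around 1,
mimicking weights that agree to several decimals), grouped (2-4 centers,
intra-cluster spread < 0.05), and exactly symmetric clusters (odd moments
zero by construction) — with p-values either uniform (null) or
Beta(0.3, 1) (alternative-like, skewed toward zero). A green suite
establishes correctness of the *tail computation* across those regimes
and calibration under the uniform null. It does not establish anything
about real data: fixtures are independent by construction, their weights
are exact doubles rather than estimated quantities, and no fixture
exercises correlated p-values, discrete p-values, or weight
misspecification — all outside the model.

## Degenerate and edge inputs

* `p_i = 1` is legal and contributes zero to the statistic. `p_i = 0` is
  a hard error, not clamped: it makes `t` infinite, and deciding what
  that means belongs upstream.
* Raw results outside [0, 1] (possible only for the unstable exact
  routes) are clipped at the result boundary with `clipped = TRUE` and
  the raw value preserved — diagnostics are never destroyed.
* A single p-value returns itself under every method.
* Statistics are computed once in double precision (`t` is a
  well-conditioned sum); extended precision applies to the tail
  evaluation, where the conditioning problem actually lives.

## Known limitations

Independence is assumed, not checked. The choice of weights is out of
scope. The truncation bound's geometric closure is empirically validated
rather than proved. Monte-Carlo verification is uninformative below
roughly `10/n` tail mass (the quadrature oracle is authoritative there).
The expansion supports orders up to 6; radii so large that `ρ ≥ 1` are
rejected rather than summed divergently.
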