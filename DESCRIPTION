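Package: pcombine
Title: Stable Combination of Independent, Weighted P-Values
Version: 0.1.0
Authors@R:
    person("pcombine", "maintainers", email = "pcombine@example.org",
           role = c("aut", "cre"))
Description: Combines independent p-values with arbitrary positive weights.
    Implements Fisher's method (equal weights), Good's formula (distinct
    weights), the exact general case in which p-values fall into groups of
    equal weight (the survival function of a hypoexponential distribution
    with repeated rates, computed by partial fractions), and a numerically
    stable controlled expansion in powers of inverse-weight deviations for
    nearly degenerate weights, with explicit truncation-error bounds.
    Includes an extended-precision arithmetic engine, Monte-Carlo and
    characteristic-function quadrature oracles for independent verification,
    a synthetic fixture generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
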