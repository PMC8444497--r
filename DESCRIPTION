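Package: veinlaw
Title: Murray's Law Conformity Analysis for Branching Vein Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing how closely measured tube bifurcations conform
    to Murray's Law and related biophysical optima, developed for insect wing
    venation morphometrics. Solves the junction-exponent equation
    d0^k = d1^k + d2^k for every measured fork with a complete taxonomy of
    geometric cases (including asymmetric forks for which no real exponent
    exists), builds the standard processed dataset variants with truncation
    and filtering provenance, detects the parent-diameter threshold above
    which deviation from Murray's Law plateaus via Bayesian two-segment
    change-point regression, and summarises bifurcation-angle structure.
    Includes a synthetic venation-measurement generator with known ground
    truth so the full pipeline can be exercised and validated by
    parameter-recovery simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    coda,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    optparse,
    rjags,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
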