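# Shared fixtures, all built in code.

# A hand-constructed solved table covering every geometric case, with known
# bookkeeping outcomes for the four dataset variants:
#   rows 1-4  standard    (k ~ 3.11, 3.00, 1.94, 22.76 — row 4 beyond the
#                          upper truncation bound)
#   rows 5-6  both_wider  (k ~ -7.27, -17.67 — row 6 beyond the lower bound)
#   rows 7-8  mixed       (argmin exponents)
#   row  9    degenerate  (child equals parent)
#   row 10    uncomputable (symmetric children within 1e-9 of the parent)
make_case_fixture <- function() {
  tibble::tibble(
    d0 = rep(100, 10),
    d1 = c(80, 100 * 2^(-1/3), 70, 97, 110, 104, 105, 101, 100, 99.9999999),
    d2 = c(80, 100 * 2^(-1/3), 70, 97, 110, 104, 95, 80, 100, 99.9999999)
  ) |>
    solve_junctions()
}

# Small canonical measurement CSV written to a temp file.
write_measurement_csv <- function(df, path = tempfile(fileext = ".csv")) {
  readr::write_csv(df, path, na = "")
  path
}

# Independent brute-force bisection oracle for the standard/both-wider root
# (deliberately naive: fixed bisection on a^k + b^k - 1).
bisect_oracle <- function(a, b, lo, hi, tol = 1e-13) {
  f <- function(k) a^k + b^k - 1
  stopifnot(f(lo) > 0, f(hi) < 0)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Direct piecewise-linear synthetic regression data (bypasses the
# venation generator) for sampler-focused tests.
make_piecewise_data <- function(n, tau = 50, alpha = 2, beta1 = -0.04,
                                beta2 = 0, sigma = 0.3, seed = 1) {
  withr::with_seed(seed, {
    x <- exp(runif(n, log(10), log(1000)))
    mu <- alpha + beta1 * pmin(x, tau) + beta2 * pmax(x - tau, 0)
    tibble::tibble(d0 = x, k_dev = mu + rnorm(n, 0, sigma))
  })
}
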