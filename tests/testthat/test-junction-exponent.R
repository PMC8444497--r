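test_that("classification covers the full case taxonomy and ignores child order", {
  expect_equal(classify_junction(100, 80, 80), "standard")
  expect_equal(classify_junction(100, 110, 110), "both_wider")
  expect_equal(classify_junction(100, 105, 99.9), "mixed")
  expect_equal(classify_junction(100, 100, 50), "degenerate")
  expect_equal(classify_junction(100, 100, 100), "degenerate")

  withr::with_seed(11, {
    d0 <- runif(500, 10, 1000)
    d1 <- d0 * exp(rnorm(500, 0, 0.3))
    d2 <- d0 * exp(rnorm(500, 0, 0.3))
    expect_identical(classify_junction(d0, d1, d2),
                     classify_junction(d0, d2, d1))
  })

  expect_error(classify_junction(100, -1, 50), "diameters")
  expect_error(classify_junction(0, 10, 10), "diameters")
})

test_that("the biophysical reference constructions solve exactly", {
  # transport capacity conserved: d1 = d2 = d0 * 2^(-1/3) gives k = 3
  murray <- solve_k(1, 2^(-1/3), 2^(-1/3))
  expect_equal(murray$k, 3, tolerance = 1e-9)
  # flow velocity conserved: d1 = d2 = d0 * 2^(-1/2) gives k = 2
  davinci <- solve_k(1, 2^(-1/2), 2^(-1/2))
  expect_equal(davinci$k, 2, tolerance = 1e-9)
  expect_identical(unique(c(murray$case, davinci$case)), "standard")
})

test_that("solved exponents match frozen oracle values across cases", {
  # independent bisection oracle froze 2.246363675642 for (1, 0.9, 0.5)
  r <- solve_k(1, 0.9, 0.5)
  expect_equal(r$k, 2.246363675642, tolerance = 1e-9)
  expect_identical(r$k_kind, "exact_root")

  # symmetric wider children: closed form ln 2 / ln(1/1.1)
  r <- solve_k(1, 1.1, 1.1)
  expect_equal(r$k, -7.272540897342, tolerance = 1e-9)
  expect_identical(r$case, "both_wider")

  # mixed fork: argmin, frozen from the closed form
  r <- solve_k(1, 1.05, 0.999)
  expect_equal(r$k, -78.0674162311, tolerance = 1e-6)
  expect_identical(r$case, "mixed")
  expect_identical(r$k_kind, "argmin")
})

test_that("exact roots satisfy the residual contract", {
  withr::with_seed(21, {
    n <- 2000
    d0 <- runif(n, 10, 1000)
    same_side <- runif(n) < 0.8
    f1 <- ifelse(same_side, runif(n, 0.3, 0.97), runif(n, 1.03, 1.5))
    f2 <- ifelse(same_side, runif(n, 0.3, 0.97), runif(n, 1.03, 1.5))
    res <- solve_k(d0, d0 * f1, d0 * f2)
    roots <- res[res$k_kind == "exact_root", ]
    expect_gt(nrow(roots), 1000)
    expect_true(all(roots$residual <= 1e-9))
  })
})

test_that("solver agrees with the symmetric closed-form oracle", {
  expect_equal(k_symmetric(1, 0.5), 1)
  expect_equal(k_symmetric(1, 2^(-1/3)), 3)
  expect_equal(k_symmetric(2, 1), 1)
  expect_error(k_symmetric(1, 1), "degenerate")

  withr::with_seed(31, {
    d0 <- runif(2000, 10, 1000)
    ratio <- c(runif(1000, 0.2, 0.98), runif(1000, 1.02, 1.6))
    dc <- d0 * ratio
    got <- solve_k(d0, dc, dc)
    expect_true(all(abs(got$k - k_symmetric(d0, dc)) <= 1e-9))
  })
})

test_that("solver agrees with a naive bisection oracle off the symmetric axis", {
  cases <- list(c(0.9, 0.5), c(0.95, 0.3), c(0.6, 0.55), c(0.85, 0.7))
  for (ab in cases) {
    k_oracle <- bisect_oracle(ab[1], ab[2], lo = 0.1, hi = 50)
    expect_equal(solve_k(1, ab[1], ab[2])$k, k_oracle, tolerance = 1e-9)
  }
})

test_that("mixed forks have no real root and the argmin matches its closed form", {
  expect_equal(k_mixed_argmin(1.05, 0.999), -78.0674162311, tolerance = 1e-6)
  expect_equal(k_mixed_argmin(1.1, 0.6), 2.7698275758, tolerance = 1e-6)
  expect_equal(k_mixed_argmin(1.7, 1 / 1.7), 0)
  expect_error(k_mixed_argmin(0.9, 0.5), "a > 1 > b")

  withr::with_seed(41, {
    a <- runif(1000, 1.001, 1.8)
    b <- runif(1000, 0.2, 0.999)
    res <- solve_k(rep(1, 1000), a, b)
    ok <- res$k_kind == "argmin"
    expect_gt(mean(ok), 0.99)  # a handful may exceed the magnitude cap
    # no-root lemma: even at the minimiser, f(k) stays above 1
    expect_true(all(res$residual[ok] > 0))
    expect_true(all(abs(res$k[ok] - k_mixed_argmin(a[ok], b[ok])) <= 1e-6))
  })
})

test_that("solutions are scale invariant and symmetric in the children", {
  withr::with_seed(51, {
    d0 <- runif(300, 10, 1000)
    d1 <- d0 * runif(300, 0.3, 1.4)
    d2 <- d0 * runif(300, 0.3, 1.4)
    base <- solve_k(d0, d1, d2)
    # powers of two scale diameters without floating-point ratio error
    scaled <- solve_k(8 * d0, 8 * d1, 8 * d2)
    expect_identical(base$k, scaled$k)
    swapped <- solve_k(d0, d2, d1)
    expect_identical(base$k, swapped$k)
    expect_identical(base$case, swapped$case)
  })
})

test_that("k grows monotonically with symmetric child diameter", {
  dc <- seq(30, 99, by = 1)
  ks <- solve_k(rep(100, length(dc)), dc, dc)$k
  expect_true(all(diff(ks) > 0))
})

test_that("degenerate and extreme forks are flagged, not solved", {
  r <- solve_k(100, 100, 80)
  expect_identical(r$case, "degenerate")
  expect_true(is.na(r$k))

  # symmetric children within 1e-9 of the parent push |k| past the cap
  r <- solve_k(100, 99.9999999, 99.9999999)
  expect_identical(r$case, "uncomputable")
  expect_true(is.na(r$k))
})

test_that("solve_junctions appends solution columns to a measurement table", {
  tbl <- tibble::tibble(d0 = c(100, 100), d1 = c(80, 110), d2 = c(80, 112))
  out <- solve_junctions(tbl)
  expect_named(out, c("record_id", "d0", "d1", "d2", "k", "case", "k_kind",
                      "residual", "iterations"))
  expect_identical(out$case, c("standard", "both_wider"))
  expect_error(solve_junctions(tibble::tibble(d0 = 1, d1 = 1)), "d2")
})
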