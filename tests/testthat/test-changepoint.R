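test_that("input contracts are enforced", {
  d <- make_piecewise_data(100)
  expect_error(fit_changepoint(d[1:30, ]), "at least 40")
  same_x <- tibble::tibble(d0 = rep(50, 60), k_dev = rnorm(60))
  expect_error(fit_changepoint(same_x), "distinct x")
  expect_error(fit_changepoint(tibble::tibble(a = 1)), "columns")
  expect_error(fit_changepoint(d, iterations = 100, warmup = 100), "warmup")
})

test_that("the sampler recovers a known change point and joined segments", {
  d <- make_piecewise_data(400, tau = 50, alpha = 2, beta1 = -0.04,
                           beta2 = 0, sigma = 0.3, seed = 13)
  fit <- fit_changepoint(d, chains = 3, iterations = 3000, seed = 13)
  s <- tidy(fit)
  est <- setNames(s$estimate, s$term)
  tau <- s[s$term == "tau", ]
  # point recovery within posterior uncertainty (single-realisation CI
  # membership is knife-edge by definition; calibration over replicates is
  # exercised by the recovery harness)
  expect_lt(abs(est[["tau"]] - 50), 7)
  expect_lt(tau$conf.high - tau$conf.low, 25)
  expect_lt(abs(est[["alpha"]] - 2), 0.3)
  expect_lt(abs(est[["beta1"]] + 0.04), 0.01)
  b2 <- s[s$term == "beta2", ]
  expect_true(b2$conf.low <= 0 && 0 <= b2$conf.high)
  # every tau draw stays inside the observed x range
  draws <- changepoint_draws(fit)
  expect_true(all(draws$tau >= min(d$d0) & draws$tau <= max(d$d0)))
  expect_equal(nrow(draws), 3 * 2000)

  g <- glance(fit)
  expect_true(g$converged)
  expect_lt(g$max_rhat, 1.05)
  expect_equal(g$warmup, 1000)
})

test_that("summaries are invariant to input row order", {
  d <- make_piecewise_data(200, seed = 17)
  fit1 <- fit_changepoint(d, chains = 2, iterations = 1500, seed = 3)
  perm <- withr::with_seed(1, d[sample.int(nrow(d)), ])
  fit2 <- fit_changepoint(perm, chains = 2, iterations = 1500, seed = 3)
  expect_identical(tidy(fit1)$estimate, tidy(fit2)$estimate)
})

test_that("a constant response leaves both slopes covering zero", {
  d <- tibble::tibble(d0 = exp(seq(log(10), log(1000), length.out = 120)),
                      k_dev = 0.7)
  fit <- fit_changepoint(d, chains = 2, iterations = 2000, seed = 2)
  s <- tidy(fit)
  for (term in c("beta1", "beta2")) {
    row <- s[s$term == term, ]
    expect_true(row$conf.low <= 0 && 0 <= row$conf.high)
  }
})

test_that("with pure-noise response the change point posterior stays diffuse", {
  # With no x-dependence in y the threshold is unidentified; its posterior
  # must not concentrate. (It is not exactly uniform: for any single noise
  # realisation the true posterior — confirmed against an independent JAGS
  # fit — piles some mass near the range edges where a short spurious
  # segment can chase local noise.)
  d <- withr::with_seed(23, tibble::tibble(
    d0 = runif(300, 10, 1000), k_dev = rnorm(300, 1, 0.5)
  ))
  fit <- fit_changepoint(d, chains = 3, iterations = 3000, seed = 23)
  s <- tidy(fit, conf_level = 0.9)
  tau <- s[s$term == "tau", ]
  span <- diff(range(d$d0))
  expect_gt((tau$conf.high - tau$conf.low) / span, 0.5)
  draws <- changepoint_draws(fit)$tau
  expect_gt(mean(draws < min(d$d0) + span / 2), 0.1)
  expect_gt(mean(draws > min(d$d0) + span / 2), 0.1)
  # and both slopes cover zero: no signal is invented
  for (term in c("beta1", "beta2")) {
    row <- s[s$term == term, ]
    expect_true(row$conf.low <= 0 && 0 <= row$conf.high)
  }
})

test_that("tau credible intervals narrow as the sample grows", {
  width <- vapply(c(150, 1200), function(n) {
    d <- make_piecewise_data(n, seed = 29)
    s <- tidy(fit_changepoint(d, chains = 2, iterations = 2000, seed = 29))
    tau <- s[s$term == "tau", ]
    tau$conf.high - tau$conf.low
  }, numeric(1))
  expect_lt(width[2], width[1])
})

test_that("the disjoint parameterisation exposes a second intercept and fits a jump", {
  d <- withr::with_seed(31, {
    x <- runif(300, 10, 1000)
    y <- ifelse(x <= 50, 3 - 0.05 * x, 0.5) + rnorm(300, 0, 0.2)
    tibble::tibble(d0 = x, k_dev = y)
  })
  fit <- fit_changepoint(d, chains = 2, iterations = 2000, seed = 31,
                         joined = FALSE)
  s <- tidy(fit)
  expect_true("alpha2" %in% s$term)
  expect_lt(abs(s$estimate[s$term == "alpha2"] - 0.5), 0.3)
})

test_that("the sampler agrees with an independent JAGS fit of the same model", {
  skip_if_not_installed("rjags")
  d <- make_piecewise_data(200, tau = 60, alpha = 2.5, beta1 = -0.045,
                           beta2 = 0, sigma = 0.25, seed = 37)
  fit <- fit_changepoint(d, chains = 3, iterations = 3000, seed = 37)
  ours <- tidy(fit)

  model_str <- "
    model {
      for (i in 1:n) {
        s[i] <- step(tau - x[i])
        mu[i] <- alpha + beta1 * (x[i] * s[i] + tau * (1 - s[i])) +
                 beta2 * (x[i] - tau) * (1 - s[i])
        y[i] ~ dnorm(mu[i], prec)
      }
      tau ~ dunif(xlo, xhi)
      alpha ~ dnorm(0, 1e-4)
      beta1 ~ dnorm(0, 1e-4)
      beta2 ~ dnorm(0, 1e-4)
      sigma ~ dunif(0, 100)
      prec <- pow(sigma, -2)
    }"
  jm <- rjags::jags.model(
    textConnection(model_str),
    data = list(x = d$d0, y = d$k_dev, n = nrow(d),
                xlo = min(d$d0), xhi = max(d$d0)),
    inits = list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = 37),
    n.chains = 2, quiet = TRUE
  )
  stats::update(jm, 2000)
  post <- rjags::coda.samples(jm, c("tau", "beta1", "beta2"), n.iter = 6000)
  jags_med <- apply(do.call(rbind, post), 2, median)

  expect_lt(abs(ours$estimate[ours$term == "tau"] - jags_med[["tau"]]), 2)
  expect_lt(abs(ours$estimate[ours$term == "beta1"] - jags_med[["beta1"]]),
            0.005)
  expect_lt(abs(ours$estimate[ours$term == "beta2"] - jags_med[["beta2"]]),
            0.002)
})
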