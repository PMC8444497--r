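#' Bayesian two-segment change-point regression
#'
#' Fits the piecewise-linear Gaussian model used to locate the parent
#' diameter above which deviation from Murray's Law plateaus:
#' \deqn{y_i \sim N(\mu(x_i), \sigma^2)}
#' with, in the default joined (continuous) parameterisation,
#' \deqn{\mu(x) = \alpha + \beta_1 \min(x, \tau) + \beta_2 \max(x - \tau, 0)}
#' so the two segments meet at the change point \eqn{\tau}. With
#' `joined = FALSE` the second segment gets its own intercept
#' \eqn{\alpha_2} and the mean jumps at \eqn{\tau}.
#'
#' Priors: \eqn{\tau} uniform on the observed `x` range; intercept and
#' slopes diffuse normal scaled to the data (`N(mean(y), (10 sd(y))^2)` and
#' `N(0, (10 sd(y)/sd(x))^2)`); \eqn{\sigma} half-normal with scale
#' `10 sd(y)`. Sampling is by seeded random-walk Metropolis-within-Gibbs
#' over \eqn{(\tau, \alpha, \beta_1, \beta_2, \log\sigma)} with per-
#' coordinate proposal scales adapted towards a 0.44 acceptance rate during
#' warm-up only (the first third of each chain, discarded). Rows are sorted
#' internally by `(x, y)` before fitting, so summaries do not depend on the
#' input row order.
#'
#' @param data A data frame; typically a `V1` variant table (analyses run
#'   on raw, untruncated, unbinned deviations).
#' @param x,y Names of the predictor and response columns (defaults `"d0"`
#'   in microns and `"k_dev"`, the absolute deviation of the junction
#'   exponent from 3).
#' @param chains Number of MCMC chains (default 3).
#' @param iterations Iterations per chain including warm-up (default 9000).
#' @param seed Integer seed; every chain's randomness derives from it.
#' @param joined If `TRUE` (default) the segments are continuous at the
#'   change point.
#' @param warmup Warm-up iterations discarded from each chain; defaults to
#'   `iterations %/% 3`.
#' @return A `veinlaw_cpt` object holding the retained posterior draws
#'   (`tau`, `alpha`, `beta1`, `beta2`, and `alpha2` when disjoint,
#'   `sigma`), the data, and sampler settings. Summarise with [tidy()] /
#'   [glance()], plot with [autoplot()].
#' @examples
#' \donttest{
#' sim <- simulate_venation(synthetic_truth(n_bifurcations = 300, seed = 7))
#' fit <- sim |> solve_junctions() |> make_variant("V1") |>
#'   fit_changepoint(chains = 2, iterations = 1500, seed = 7)
#' tidy(fit)
#' }
#' @export
fit_changepoint <- function(data, x = "d0", y = "k_dev", chains = 3,
                            iterations = 9000, seed = 1, joined = TRUE,
                            warmup = NULL) {
  if (!x %in% names(data) || !y %in% names(data)) {
    abort(sprintf("`data` must have columns `%s` and `%s`", x, y))
  }
  dat <- tibble::tibble(x = as.numeric(data[[x]]), y = as.numeric(data[[y]]))
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (nrow(dat) < 40) abort("need at least 40 complete (x, y) rows")
  if (length(unique(dat$x)) < 10) {
    abort("need at least 10 distinct x values (degenerate predictor)")
  }
  warmup <- warmup %||% (iterations %/% 3)
  if (warmup >= iterations) abort("`warmup` must be smaller than `iterations`")
  # canonical internal ordering: summaries invariant to input permutation
  dat <- dat[order(dat$x, dat$y), , drop = FALSE]

  xr <- range(dat$x)
  sy <- sd(dat$y); sx <- sd(dat$x)
  if (sy == 0) sy <- 1  # constant response: fall back to unit prior scale
  prior <- list(
    tau_lo = xr[1], tau_hi = xr[2],
    alpha_mean = mean(dat$y), alpha_sd = 10 * sy,
    beta_sd = 10 * sy / sx,
    sigma_scale = 10 * sy
  )
  par_names <- if (joined) {
    c("tau", "alpha", "beta1", "beta2", "sigma")
  } else {
    c("tau", "alpha", "beta1", "alpha2", "beta2", "sigma")
  }

  chain_seeds <- withr::with_seed(seed, sample.int(2^31 - 2, chains))
  draws <- vector("list", chains)
  accept <- matrix(NA_real_, chains, 2,
                   dimnames = list(NULL, c("tau", "log_sigma")))
  # overdispersed tau starts so split-Rhat can expose mode disagreement
  tau_inits <- quantile(dat$x, (seq_len(chains)) / (chains + 1), names = FALSE)
  for (ch in seq_len(chains)) {
    run <- withr::with_seed(chain_seeds[ch], {
      run_mwg_chain(dat$x, dat$y, prior, joined, iterations, warmup,
                    tau_init = tau_inits[ch])
    })
    draws[[ch]] <- run$draws
    accept[ch, ] <- run$accept
  }

  fit <- structure(list(
    draws = draws,            # list of (iterations - warmup) x npar matrices
    par_names = par_names,
    data = dat,
    chains = chains, iterations = iterations, warmup = warmup,
    seed = seed, joined = joined, prior = prior,
    accept = accept
  ), class = "veinlaw_cpt")
  fit$diagnostics <- cpt_diagnostics(fit)
  fit
}

# One Metropolis-within-Gibbs chain over (tau, coefficients, log sigma).
# tau and log sigma move by Gaussian random-walk Metropolis with proposal
# scales adapted towards a 0.44 acceptance rate during warm-up only; the
# linear coefficients are drawn exactly from their conjugate normal
# conditional given (tau, sigma), a proper Gibbs step. One tau proposal in
# ten is an independence draw from the uniform prior (constant proposal
# density, so the acceptance ratio is the plain posterior ratio): the
# change-point posterior can be multimodal, and a purely local walk with
# adapted steps cannot cross between modes.
run_mwg_chain <- function(x, y, prior, joined, iterations, warmup,
                          tau_init = median(x)) {
  n <- length(x)
  design <- if (joined) {
    function(tau) cbind(1, pmin(x, tau), pmax(x - tau, 0))
  } else {
    function(tau) {
      lo <- as.numeric(x <= tau)
      cbind(lo, lo * x, 1 - lo, (1 - lo) * (x - tau))
    }
  }
  coef_names <- if (joined) c("alpha", "beta1", "beta2")
                else c("alpha", "beta1", "alpha2", "beta2")
  m0 <- if (joined) c(prior$alpha_mean, 0, 0)
        else c(prior$alpha_mean, 0, prior$alpha_mean, 0)
  v0 <- if (joined) c(prior$alpha_sd, prior$beta_sd, prior$beta_sd)^2
        else c(prior$alpha_sd, prior$beta_sd, prior$alpha_sd, prior$beta_sd)^2

  # log joint in (tau, log sigma) with coefficients held fixed
  log_post <- function(tau, beta, log_sigma) {
    if (tau < prior$tau_lo || tau > prior$tau_hi) return(-Inf)
    sigma <- exp(log_sigma)
    mu <- drop(design(tau) %*% beta)
    -n * log_sigma - 0.5 * sum((y - mu)^2) / sigma^2 +
      sum(dnorm(beta, m0, sqrt(v0), log = TRUE)) +
      # half-normal prior on sigma, plus the log-sigma Jacobian
      dnorm(sigma, 0, prior$sigma_scale, log = TRUE) + log_sigma
  }
  draw_coefs <- function(tau, log_sigma) {
    X <- design(tau)
    prec <- crossprod(X) / exp(2 * log_sigma) + diag(1 / v0)
    ch <- chol(prec)
    m <- backsolve(ch, forwardsolve(t(ch),
                   drop(crossprod(X, y)) / exp(2 * log_sigma) + m0 / v0))
    m + backsolve(ch, rnorm(length(m)))
  }

  tau <- tau_init
  log_sigma <- log(max(sd(y), 1e-6))
  beta <- draw_coefs(tau, log_sigma)
  lp_cur <- log_post(tau, beta, log_sigma)
  scales <- c(tau = (prior$tau_hi - prior$tau_lo) / 10, log_sigma = 0.3)
  acc <- c(tau = 0, log_sigma = 0)
  acc_win <- c(tau = 0, log_sigma = 0)
  par_names <- c("tau", coef_names, "sigma")
  n_keep <- iterations - warmup
  draws <- matrix(NA_real_, n_keep, length(par_names),
                  dimnames = list(NULL, par_names))

  for (it in seq_len(iterations)) {
    jump <- runif(1) < 0.1
    tau_prop <- if (jump) runif(1, prior$tau_lo, prior$tau_hi)
                else tau + rnorm(1, 0, scales[["tau"]])
    lp_prop <- log_post(tau_prop, beta, log_sigma)
    if (is.finite(lp_prop) && log(runif(1)) < lp_prop - lp_cur) {
      tau <- tau_prop; lp_cur <- lp_prop
      if (!jump) {
        acc[["tau"]] <- acc[["tau"]] + 1
        acc_win[["tau"]] <- acc_win[["tau"]] + 1
      }
    }
    beta <- draw_coefs(tau, log_sigma)
    lp_cur <- log_post(tau, beta, log_sigma)
    ls_prop <- log_sigma + rnorm(1, 0, scales[["log_sigma"]])
    lp_prop <- log_post(tau, beta, ls_prop)
    if (is.finite(lp_prop) && log(runif(1)) < lp_prop - lp_cur) {
      log_sigma <- ls_prop; lp_cur <- lp_prop
      acc[["log_sigma"]] <- acc[["log_sigma"]] + 1
      acc_win[["log_sigma"]] <- acc_win[["log_sigma"]] + 1
    }
    if (it <= warmup && it %% 50 == 0) {
      rate <- acc_win / c(45, 50)  # ~10% of tau proposals are prior jumps
      scales <- scales * exp(pmin(pmax(rate - 0.44, -0.5), 0.5))
      acc_win[] <- 0
    }
    if (it > warmup) {
      draws[it - warmup, ] <- c(tau, beta, exp(log_sigma))
    }
  }
  list(draws = draws, accept = acc / iterations)
}

# Split-Rhat and effective sample size per parameter.
cpt_diagnostics <- function(fit) {
  pn <- colnames(fit$draws[[1]])
  rhat <- vapply(pn, function(par) {
    split_rhat(lapply(fit$draws, function(d) d[, par]))
  }, numeric(1))
  ess <- vapply(pn, function(par) {
    ml <- coda::mcmc.list(lapply(fit$draws, function(d) coda::mcmc(d[, par])))
    as.numeric(coda::effectiveSize(ml))
  }, numeric(1))
  converged <- all(is.na(rhat) | rhat < 1.05)
  list(rhat = rhat, ess = ess, converged = converged)
}

split_rhat <- function(chains) {
  halves <- unlist(lapply(chains, function(ch) {
    h <- length(ch) %/% 2
    list(ch[seq_len(h)], ch[(h + 1):(2 * h)])
  }), recursive = FALSE)
  m <- length(halves); n <- length(halves[[1]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (!is.finite(W) || W == 0) return(NA_real_)  # degenerate (constant) draws
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' @export
print.veinlaw_cpt <- function(x, ...) {
  cat(sprintf(
    "Two-segment change-point fit (%s at tau)\n%d chains x %d iterations (%d warm-up), seed %s\n",
    if (x$joined) "joined" else "disjoint",
    x$chains, x$iterations, x$warmup, format(x$seed)
  ))
  if (!x$diagnostics$converged) {
    cat("WARNING: convergence not reached (max split-Rhat >= 1.05)\n")
  }
  print(tidy(x), ...)
  invisible(x)
}

#' Tidy posterior summaries of a change-point fit
#'
#' One row per model parameter with posterior median and mean, equal-tailed
#' credible interval, split-Rhat and effective sample size. Deterministic
#' given the retained draws.
#'
#' @param x A `veinlaw_cpt` object from [fit_changepoint()].
#' @param conf_level Credible-interval mass (default 0.95).
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate` (posterior median),
#'   `mean`, `conf.low`, `conf.high`, `rhat`, `ess`.
#' @method tidy veinlaw_cpt
#' @export
tidy.veinlaw_cpt <- function(x, conf_level = 0.95, ...) {
  pooled <- do.call(rbind, x$draws)
  if (nrow(pooled) == 0) abort("fit contains no retained draws")
  alpha <- 1 - conf_level
  purrr::map_dfr(colnames(pooled), function(par) {
    v <- pooled[, par]
    tibble::tibble(
      term = par,
      estimate = median(v),
      mean = mean(v),
      conf.low = quantile(v, alpha / 2, names = FALSE),
      conf.high = quantile(v, 1 - alpha / 2, names = FALSE),
      rhat = x$diagnostics$rhat[[par]],
      ess = x$diagnostics$ess[[par]]
    )
  })
}

#' One-line summary of a change-point fit
#'
#' @param x A `veinlaw_cpt` object.
#' @param ... Unused.
#' @return A one-row tibble: `n`, `chains`, `iterations`, `warmup`,
#'   `joined`, `converged`, `max_rhat`, `tau_median`.
#' @method glance veinlaw_cpt
#' @export
glance.veinlaw_cpt <- function(x, ...) {
  pooled <- do.call(rbind, x$draws)
  tibble::tibble(
    n = nrow(x$data),
    chains = x$chains, iterations = x$iterations, warmup = x$warmup,
    joined = x$joined,
    converged = x$diagnostics$converged,
    max_rhat = suppressWarnings(max(x$diagnostics$rhat, na.rm = TRUE)),
    tau_median = median(pooled[, "tau"])
  )
}

#' Extract posterior draws from a change-point fit
#'
#' @param fit A `veinlaw_cpt` object.
#' @return A tibble of retained draws with `chain` and `iteration` columns.
#' @export
changepoint_draws <- function(fit) {
  purrr::map_dfr(seq_along(fit$draws), function(ch) {
    d <- tibble::as_tibble(fit$draws[[ch]])
    d$chain <- ch
    d$iteration <- seq_len(nrow(d))
    d
  })
}

#' Plot a change-point fit over the data
#'
#' Scatter of the (possibly log-scaled) data with the posterior-median
#' piecewise mean and a shaded credible band for the change point.
#'
#' @param object A `veinlaw_cpt` object.
#' @param log_x Log-scale the x axis (diameters span orders of magnitude).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot veinlaw_cpt
#' @export
autoplot.veinlaw_cpt <- function(object, log_x = TRUE, ...) {
  s <- tidy(object)
  est <- setNames(s$estimate, s$term)
  xs <- seq(min(object$data$x), max(object$data$x), length.out = 400)
  mu <- if (object$joined) {
    est[["alpha"]] + est[["beta1"]] * pmin(xs, est[["tau"]]) +
      est[["beta2"]] * pmax(xs - est[["tau"]], 0)
  } else {
    ifelse(xs <= est[["tau"]], est[["alpha"]] + est[["beta1"]] * xs,
           est[["alpha2"]] + est[["beta2"]] * (xs - est[["tau"]]))
  }
  tau_ci <- s[s$term == "tau", c("conf.low", "conf.high")]
  p <- ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::annotate("rect", xmin = tau_ci$conf.low, xmax = tau_ci$conf.high,
                      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "orange") +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_line(data = tibble::tibble(x = xs, y = mu),
                       colour = "firebrick", linewidth = 1) +
    ggplot2::geom_vline(xintercept = est[["tau"]], linetype = "dashed") +
    ggplot2::labs(x = "parent diameter d0 (microns)",
                  y = "deviation |k - 3|",
                  title = sprintf("Change point at %.1f microns (95%% CI %.1f-%.1f)",
                                  est[["tau"]], tau_ci$conf.low, tau_ci$conf.high))
  if (log_x) p <- p + ggplot2::scale_x_log10()
  p
}
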