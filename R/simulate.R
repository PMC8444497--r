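#' Ground-truth parameters for the synthetic venation generator
#'
#' Bundles and validates the parameters of [simulate_venation()]. Defaults
#' emulate the statistical structure of a large lepidopteran wing-venation
#' survey: about 2,700 measured bifurcations, parent diameters spanning
#' 10-1000 microns (log-uniform), a true junction exponent of 3 (Murray's
#' Law), and measurement/biological dispersion that grows linearly as the
#' parent diameter falls below a ~50-micron threshold and is flat above it.
#'
#' @param n_bifurcations Number of forks to generate.
#' @param k_true True junction exponent used to construct child diameters.
#' @param tau_true Threshold diameter (microns) below which diameter noise
#'   grows.
#' @param sigma_plateau Log-scale diameter noise SD above the threshold.
#' @param sigma_slope Additional noise SD per micron below the threshold:
#'   at parent diameter `d0 < tau_true` the per-diameter log-noise SD is
#'   `sigma_plateau + sigma_slope * (tau_true - d0)`.
#' @param d0_range Range of parent diameters (microns); drawn log-uniform.
#' @param asym_frac Fraction of forks perturbed into asymmetric (mixed)
#'   geometry by inflating the wider child just above the parent.
#' @param angle_children_mean,angle_children_sd Truncated-normal parameters
#'   (degrees, on `[0, 180)`) for the child-child bifurcation angle.
#' @param angle_pc_mean,angle_pc_sd Truncated-normal parameters (degrees)
#'   for each parent-child angular difference.
#' @param noise `"multiplicative"` (log-normal factors on each diameter,
#'   the default: measurement error on a micrograph scales with the
#'   structure) or `"additive"` (normal, SD proportional to the diameter).
#' @param seed Integer seed; the generated table is byte-identical per seed.
#' @return A `veinlaw_truth` list.
#' @export
synthetic_truth <- function(n_bifurcations = 2696, k_true = 3,
                            tau_true = 50, sigma_plateau = 0.03,
                            sigma_slope = 0.006, d0_range = c(10, 1000),
                            asym_frac = 0.125,
                            angle_children_mean = 30, angle_children_sd = 15,
                            angle_pc_mean = 10, angle_pc_sd = 7.5,
                            noise = c("multiplicative", "additive"),
                            seed = 1) {
  noise <- match.arg(noise)
  if (n_bifurcations < 1) abort("`n_bifurcations` must be >= 1")
  if (sigma_plateau < 0 || sigma_slope < 0 || angle_children_sd < 0 ||
      angle_pc_sd < 0) {
    abort("all noise SDs must be >= 0")
  }
  if (asym_frac < 0 || asym_frac > 1) abort("`asym_frac` must be in [0, 1]")
  if (length(d0_range) != 2 || d0_range[1] <= 0 ||
      d0_range[2] <= d0_range[1]) {
    abort("`d0_range` must be an increasing positive pair")
  }
  if (tau_true < d0_range[1] || tau_true > d0_range[2]) {
    abort("`tau_true` must lie within `d0_range`")
  }
  structure(list(
    n_bifurcations = as.integer(n_bifurcations), k_true = k_true,
    tau_true = tau_true, sigma_plateau = sigma_plateau,
    sigma_slope = sigma_slope, d0_range = d0_range, asym_frac = asym_frac,
    angle_children_mean = angle_children_mean,
    angle_children_sd = angle_children_sd,
    angle_pc_mean = angle_pc_mean, angle_pc_sd = angle_pc_sd,
    noise = noise, seed = as.integer(seed)
  ), class = "veinlaw_truth")
}

rtruncnorm_01_180 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  lo <- pnorm(0, mean, sd); hi <- pnorm(180 - 1e-9, mean, sd)
  qnorm(runif(n, lo, hi), mean, sd)
}

SUPERFAMILIES <- c(
  Gelechioidea = 0.30, Noctuoidea = 0.15, Tortricoidea = 0.12,
  Pyraloidea = 0.10, Geometroidea = 0.08, Yponomeutoidea = 0.07,
  Tineoidea = 0.06, Papilionoidea = 0.05, Bombycoidea = 0.04,
  Sesioidea = 0.03
)

#' Generate a synthetic venation measurement table
#'
#' Builds a table of bifurcation measurements with known ground truth.
#' For each fork the parent diameter is drawn log-uniform over
#' `truth$d0_range`; a split fraction `u ~ Uniform(0.2, 0.8)` sets ideal
#' children `d1 = d0 u^(1/k_true)`, `d2 = d0 (1-u)^(1/k_true)`, which
#' satisfy the junction equation exactly; each of the three diameters is
#' then perturbed by log-normal noise whose SD depends on the parent
#' diameter (flat above `tau_true`, growing linearly below it). A random
#' `asym_frac` subset has its wider child inflated just above the parent,
#' producing asymmetric (mixed) geometry. The size-dependent dispersion is
#' placed on the diameters — not on `k` — so that the exponent solver, not
#' the generator, produces the `k` distribution. Angles come from the
#' configured truncated normals and taxon labels are drawn from a fixed
#' superfamily frequency table.
#'
#' @param truth A [synthetic_truth()] object.
#' @return A tibble in the canonical measurement schema (see
#'   [read_measurements()]) plus per-row ground-truth columns `true_u`,
#'   `true_sigma` (the log-noise SD applied) and `asym_perturbed`.
#'   Identical `truth` (including seed) gives a byte-identical table.
#' @examples
#' simulate_venation(synthetic_truth(n_bifurcations = 10))
#' @export
simulate_venation <- function(truth) {
  if (!inherits(truth, "veinlaw_truth")) {
    abort("`truth` must come from synthetic_truth()")
  }
  withr::with_seed(truth$seed, {
    n <- truth$n_bifurcations
    # specimens carry 1-3 forks each
    forks_per <- sample(1:3, size = n, replace = TRUE, prob = c(.2, .3, .5))
    spec_of_fork <- rep(seq_len(n), forks_per)[seq_len(n)]
    fork_index <- stats::ave(spec_of_fork, spec_of_fork,
                             FUN = seq_along)
    n_spec <- max(spec_of_fork)
    spec_ids <- sprintf("SYN%05d", seq_len(n_spec))
    superfam <- sample(names(SUPERFAMILIES), n_spec, replace = TRUE,
                       prob = SUPERFAMILIES)

    lo <- log(truth$d0_range[1]); hi <- log(truth$d0_range[2])
    d0_ideal <- exp(runif(n, lo, hi))
    u <- runif(n, 0.2, 0.8)
    d1_ideal <- d0_ideal * u^(1 / truth$k_true)
    d2_ideal <- d0_ideal * (1 - u)^(1 / truth$k_true)
    sig <- truth$sigma_plateau +
      truth$sigma_slope * pmax(0, truth$tau_true - d0_ideal)
    jitter3 <- function(d) {
      if (truth$noise == "multiplicative") d * exp(rnorm(n, 0, sig))
      else d + rnorm(n, 0, sig * d)
    }
    d0 <- jitter3(d0_ideal); d1 <- jitter3(d1_ideal); d2 <- jitter3(d2_ideal)
    d0 <- pmax(d0, 1e-6); d1 <- pmax(d1, 1e-6); d2 <- pmax(d2, 1e-6)

    asym <- runif(n) < truth$asym_frac
    if (any(asym)) {
      wider_is_1 <- d1 >= d2
      infl <- exp(runif(n, 0.01, 0.12))
      d1[asym & wider_is_1] <- d0[asym & wider_is_1] * infl[asym & wider_is_1]
      d2[asym & !wider_is_1] <- d0[asym & !wider_is_1] * infl[asym & !wider_is_1]
    }

    wing_length <- signif(0.05 * tapply(d0, spec_of_fork, max)^0.9 *
                            exp(rnorm(n_spec, 0, 0.2)), 4)

    tibble::tibble(
      specimen_id = spec_ids[spec_of_fork],
      taxon_superfamily = superfam[spec_of_fork],
      taxon_family = NA_character_,
      order_label = "Lepidoptera",
      wing_length = as.numeric(wing_length[as.character(spec_of_fork)]),
      fork_index = as.integer(fork_index),
      d0 = d0, d1 = d1, d2 = d2,
      angle_children = rtruncnorm_01_180(n, truth$angle_children_mean,
                                         truth$angle_children_sd),
      angle_parent_child1 = rtruncnorm_01_180(n, truth$angle_pc_mean,
                                              truth$angle_pc_sd),
      angle_parent_child2 = rtruncnorm_01_180(n, truth$angle_pc_mean,
                                              truth$angle_pc_sd),
      true_u = u,
      true_sigma = sig,
      asym_perturbed = asym
    )
  })
}

#' Change-point parameter-recovery experiment
#'
#' For each seeded replicate: simulate a measurement table, solve the
#' junction exponents, build the raw (`V1`) variant, fit the two-segment
#' change-point model of `|k - 3|` on `d0`, and record whether the credible
#' interval for the threshold covers the generator's `tau_true` and whether
#' the plateau-slope interval covers 0. This is the package's end-to-end
#' validation harness: high coverage says the whole pipeline can recover a
#' known conformity threshold from data like those it was designed for.
#'
#' @param truth A [synthetic_truth()] object (its `seed` is replaced by
#'   each replicate's seed).
#' @param n_replicates Number of replicates (>= 5).
#' @param seeds Integer vector of per-replicate seeds; defaults to
#'   `truth$seed + 0:(n_replicates-1)`.
#' @param chains,iterations Sampler settings passed to [fit_changepoint()].
#' @param conf_level Credible-interval mass.
#' @return A tibble with one row per replicate: `replicate`, `seed`,
#'   `tau_median`, `tau_low`, `tau_high`, `covers_tau`, `beta2_low`,
#'   `beta2_high`, `beta2_covers_zero`, `converged`. Coverage fractions are
#'   in the `"coverage"` attribute. If `truth$sigma_slope == 0` there is no
#'   threshold signal and `covers_tau` is flagged inapplicable (`NA`).
#' @export
parameter_recovery <- function(truth, n_replicates = 20, seeds = NULL,
                               chains = 3, iterations = 9000,
                               conf_level = 0.95) {
  if (n_replicates < 5) abort("`n_replicates` must be >= 5")
  seeds <- seeds %||% (truth$seed + seq_len(n_replicates) - 1L)
  if (length(seeds) != n_replicates) {
    abort("`seeds` must have length `n_replicates`")
  }
  no_signal <- truth$sigma_slope == 0
  rows <- purrr::map(seq_len(n_replicates), function(i) {
    truth_i <- truth
    truth_i$seed <- as.integer(seeds[i])
    res <- tryCatch({
      v1 <- simulate_venation(truth_i) |>
        solve_junctions() |>
        make_variant("V1")
      fit <- fit_changepoint(v1, chains = chains, iterations = iterations,
                             seed = as.integer(seeds[i]))
      s <- tidy(fit, conf_level = conf_level)
      tau <- s[s$term == "tau", ]
      b2 <- s[s$term == "beta2", ]
      tibble::tibble(
        replicate = i, seed = as.integer(seeds[i]),
        tau_median = tau$estimate,
        tau_low = tau$conf.low, tau_high = tau$conf.high,
        covers_tau = if (no_signal) NA else
          tau$conf.low <= truth$tau_true & truth$tau_true <= tau$conf.high,
        beta2_low = b2$conf.low, beta2_high = b2$conf.high,
        beta2_covers_zero = b2$conf.low <= 0 & 0 <= b2$conf.high,
        converged = fit$diagnostics$converged
      )
    }, error = function(e) {
      abort(sprintf("replicate %d (seed %d) failed: %s",
                    i, seeds[i], conditionMessage(e)))
    })
    res
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "coverage") <- list(
    tau = if (no_signal) NA_real_ else mean(out$covers_tau),
    beta2_zero = mean(out$beta2_covers_zero),
    no_signal = no_signal
  )
  out
}
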