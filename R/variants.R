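#' Build one of the four processed dataset variants
#'
#' A solved measurement table (see [solve_junctions()]) is processed into
#' one of four standard variants that differ in how asymmetric and extreme
#' forks are handled:
#'
#' * `"V1"` — every fork with a computable exponent; degenerate and
#'   uncomputable forks are dropped (and counted).
#' * `"V2"` — `V1` minus mixed (asymmetric) forks.
#' * `"V3"` — `V2` with `k` truncated to `[-14, 20]`.
#' * `"V4"` — `V1` minus mixed and minus both-wider forks (standard
#'   geometry only), with `k` truncated above at `20`.
#'
#' The deviation statistic `k_dev = |k - 3|` — the distance from Murray's
#' Law — is recomputed from the possibly truncated `k`. Full filtering and
#' truncation provenance is recorded and retrievable with
#' [variant_provenance()]; `dropped + retained` always equals the input row
#' count.
#'
#' @param data A solved table carrying columns `k` and `case` (and any
#'   measurement columns, which are passed through).
#' @param variant One of `"V1"`, `"V2"`, `"V3"`, `"V4"`.
#' @return A tibble with the retained rows, a `variant_id` column, and
#'   `k_dev`; provenance counts in the `"provenance"` attribute.
#' @examples
#' simulate_venation(synthetic_truth(n_bifurcations = 50)) |>
#'   solve_junctions() |>
#'   make_variant("V3") |>
#'   variant_provenance()
#' @export
make_variant <- function(data, variant = c("V1", "V2", "V3", "V4")) {
  variant <- match.arg(variant)
  if (!all(c("k", "case") %in% names(data))) {
    abort("`data` must carry `k` and `case` columns; run solve_junctions() first")
  }
  data <- tibble::as_tibble(data)
  if (!"record_id" %in% names(data)) {
    data <- dplyr::mutate(data, record_id = dplyr::row_number(), .before = 1)
  }
  n_input <- nrow(data)
  prov <- list(
    variant_id = variant, n_input = n_input,
    dropped_degenerate = sum(data$case == "degenerate"),
    dropped_uncomputable = sum(data$case == "uncomputable"),
    dropped_mixed = 0L, dropped_both_wider = 0L,
    truncated_low = 0L, truncated_high = 0L
  )
  keep <- data$case %in% c("standard", "both_wider", "mixed") & !is.na(data$k)
  out <- data[keep, , drop = FALSE]

  if (variant %in% c("V2", "V3", "V4")) {
    prov$dropped_mixed <- sum(out$case == "mixed")
    out <- out[out$case != "mixed", , drop = FALSE]
  }
  if (variant == "V4") {
    prov$dropped_both_wider <- sum(out$case == "both_wider")
    out <- out[out$case != "both_wider", , drop = FALSE]
  }
  clip <- switch(variant,
    V1 = c(-Inf, Inf), V2 = c(-Inf, Inf),
    V3 = c(-14, 20), V4 = c(-Inf, 20)
  )
  prov$truncated_low <- sum(out$k < clip[1])
  prov$truncated_high <- sum(out$k > clip[2])
  out$k <- pmin(pmax(out$k, clip[1]), clip[2])

  out <- dplyr::mutate(out, variant_id = variant, k_dev = abs(.data$k - 3))
  prov$n_retained <- nrow(out)
  attr(out, "provenance") <- prov
  out
}

#' Retrieve filtering/truncation provenance from a variant table
#'
#' @param data A tibble returned by [make_variant()].
#' @return A named list of counts: input rows, rows dropped by each rule,
#'   rows truncated at each bound, and rows retained.
#' @export
variant_provenance <- function(data) {
  attr(data, "provenance") %||%
    abort("`data` carries no provenance; was it built by make_variant()?")
}

#' Bin a variant table into sorted groups and take means
#'
#' Rows are stably sorted by the chosen key (parent diameter `d0` or the
#' child-child bifurcation angle), cut into consecutive disjoint bins of
#' exactly `bin_size` rows, and summarised by per-bin arithmetic means.
#' A trailing remainder of fewer than `bin_size` rows is dropped and
#' counted (attribute `"dropped_remainder"`); binning is a display/
#' smoothing device only — analyses run on the unbinned rows.
#'
#' @param data A variant table with columns `k`, `k_dev` and the sort key.
#' @param sort_key `"d0"` or `"angle_children"`.
#' @param bin_size Number of rows per bin (default 20).
#' @return A tibble with one row per bin: `bin`, the mean sort-key value,
#'   `mean_k`, `mean_k_dev`, and `n`. Empty (with a warning) if the input
#'   has fewer than `bin_size` rows.
#' @examples
#' simulate_venation(synthetic_truth(n_bifurcations = 200)) |>
#'   solve_junctions() |>
#'   make_variant("V1") |>
#'   bin_means("d0")
#' @export
bin_means <- function(data, sort_key = c("d0", "angle_children"),
                      bin_size = 20) {
  sort_key <- match.arg(sort_key)
  if (!sort_key %in% names(data)) {
    abort(sprintf("`data` has no `%s` column", sort_key))
  }
  empty <- tibble::tibble(
    bin = integer(), !!paste0("mean_", sort_key) := numeric(),
    mean_k = numeric(), mean_k_dev = numeric(), n = integer()
  )
  usable <- data[!is.na(data[[sort_key]]), , drop = FALSE]
  if (nrow(usable) < bin_size) {
    warn(sprintf("fewer than %d rows with `%s`; returning empty series",
                 bin_size, sort_key))
    attr(empty, "dropped_remainder") <- nrow(usable)
    return(empty)
  }
  ord <- order(usable[[sort_key]])  # stable: ties keep input order
  usable <- usable[ord, , drop = FALSE]
  n_bins <- nrow(usable) %/% bin_size
  n_used <- n_bins * bin_size
  dropped <- nrow(usable) - n_used
  usable <- usable[seq_len(n_used), , drop = FALSE]
  usable$bin <- rep(seq_len(n_bins), each = bin_size)
  out <- usable |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      !!paste0("mean_", sort_key) := mean(.data[[sort_key]]),
      mean_k = mean(.data$k),
      mean_k_dev = mean(.data$k_dev),
      n = dplyr::n(),
      .groups = "drop"
    )
  attr(out, "dropped_remainder") <- dropped
  out
}

#' Plot a binned deviation series
#'
#' Scatter of per-bin mean deviation `|k - 3|` against the bin's mean sort
#' key, the standard way to visualise how conformity to Murray's Law
#' changes with diameter or angle.
#'
#' @param bins A tibble from [bin_means()].
#' @param log_x Log-scale the x axis (sensible for diameters).
#' @return A ggplot object.
#' @export
plot_binned_deviation <- function(bins, log_x = TRUE) {
  key <- grep("^mean_", names(bins), value = TRUE)
  key <- setdiff(key, c("mean_k", "mean_k_dev"))[1]
  p <- ggplot2::ggplot(bins, ggplot2::aes(x = .data[[key]],
                                          y = .data$mean_k_dev)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = sub("^mean_", "bin mean ", key),
                  y = "bin mean |k - 3|")
  if (log_x) p <- p + ggplot2::scale_x_log10()
  p
}

#' Mean junction exponent over a large-diameter slice
#'
#' Summarises `k` over the forks whose parent diameter is at least `d0_min`
#' microns, or over the `top_n` forks with the largest parent diameters —
#' the regimes where conformity to Murray's Law has stabilised. The
#' uncertainty interval is a seeded nonparametric bootstrap percentile CI
#' by default, or a t-interval.
#'
#' @param data A variant table with columns `d0` and `k`.
#' @param d0_min Lower parent-diameter threshold in microns (exclusive with
#'   `top_n`).
#' @param top_n Number of largest-`d0` forks to keep (exclusive with
#'   `d0_min`).
#' @param conf_level Confidence level (default 0.95).
#' @param n_boot Bootstrap resamples (default 10000).
#' @param seed Integer seed for the bootstrap; the global RNG state is left
#'   untouched.
#' @param method `"bootstrap"` (percentile) or `"t"`.
#' @return A one-row tibble: `slice`, `n`, `d0_lo`, `d0_hi`, `mean_k`,
#'   `ci_lower`, `ci_upper`, `method`.
#' @export
summarize_threshold_slice <- function(data, d0_min = NULL, top_n = NULL,
                                      conf_level = 0.95, n_boot = 10000,
                                      seed = 1,
                                      method = c("bootstrap", "t")) {
  method <- match.arg(method)
  if (is.null(d0_min) == is.null(top_n)) {
    abort("supply exactly one of `d0_min` or `top_n`")
  }
  if (nrow(data) == 0) abort("`data` is empty")
  if (!is.null(d0_min)) {
    slice <- data[data$d0 >= d0_min, , drop = FALSE]
    label <- sprintf("d0 >= %g", d0_min)
    if (nrow(slice) == 0) {
      abort(sprintf("no forks with d0 >= %g microns", d0_min))
    }
  } else {
    if (top_n < 1 || top_n > nrow(data)) {
      abort(sprintf("`top_n` must be in [1, %d]", nrow(data)))
    }
    ord <- order(data$d0, decreasing = TRUE)
    slice <- data[ord[seq_len(top_n)], , drop = FALSE]
    label <- sprintf("top %d by d0", top_n)
  }
  kk <- slice$k
  m <- mean(kk)
  alpha <- 1 - conf_level
  if (method == "bootstrap") {
    ci <- withr::with_seed(seed, {
      boots <- vapply(seq_len(n_boot), function(i) {
        mean(kk[sample.int(length(kk), replace = TRUE)])
      }, numeric(1))
      quantile(boots, c(alpha / 2, 1 - alpha / 2), names = FALSE)
    })
  } else {
    se <- sd(kk) / sqrt(length(kk))
    ci <- m + qt(c(alpha / 2, 1 - alpha / 2), df = length(kk) - 1) * se
  }
  d0_range <- range(slice$d0)
  tibble::tibble(
    slice = label, n = length(kk),
    d0_lo = d0_range[1], d0_hi = d0_range[2],
    mean_k = m, ci_lower = ci[1], ci_upper = ci[2], method = method
  )
}
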