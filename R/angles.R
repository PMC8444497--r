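#' Expand records into parent-child angle/diameter pairs
#'
#' Each measured fork with both parent-child angle differences yields two
#' pairs, one per child: the absolute angular difference between the parent
#' and that child vein (degrees) and the child/parent diameter ratio.
#' Records missing either angle are skipped and counted (attribute
#' `"skipped"`). Murray's angle prediction is that the wider child sits at
#' the smaller angle to the parent, i.e. that the two pair variables are
#' anticorrelated.
#'
#' @param data A measurement table with columns `d0`, `d1`, `d2`,
#'   `angle_parent_child1`, `angle_parent_child2`.
#' @return A tibble with columns `record_id`, `child`, `delta_angle`
#'   (degrees) and `child_over_parent` (dimensionless), two rows per
#'   complete record.
#' @export
build_pairs <- function(data) {
  need <- c("d0", "d1", "d2", "angle_parent_child1", "angle_parent_child2")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("`data` lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  data <- tibble::as_tibble(data)
  if (!"record_id" %in% names(data)) {
    data <- dplyr::mutate(data, record_id = dplyr::row_number(), .before = 1)
  }
  complete <- !is.na(data$angle_parent_child1) &
    !is.na(data$angle_parent_child2)
  used <- data[complete, , drop = FALSE]
  out <- dplyr::bind_rows(
    tibble::tibble(record_id = used$record_id, child = 1L,
                   delta_angle = used$angle_parent_child1,
                   child_over_parent = used$d1 / used$d0),
    tibble::tibble(record_id = used$record_id, child = 2L,
                   delta_angle = used$angle_parent_child2,
                   child_over_parent = used$d2 / used$d0)
  ) |>
    dplyr::arrange(.data$record_id, .data$child)
  attr(out, "skipped") <- sum(!complete)
  out
}

#' Summarise parent-child angle/diameter pairs
#'
#' Arithmetic means and population standard deviations of the angular
#' difference and the diameter ratio, plus a fixed-grid 2-D histogram
#' (angle 0-60 degrees by ratio 0.4-1.4, 30 x 30 cells by default; pairs
#' outside the grid are excluded from the histogram only and counted).
#'
#' @param pairs A tibble from [build_pairs()].
#' @param angle_lim,ratio_lim Grid limits for the histogram.
#' @param nbins Cells per axis.
#' @return A list with `stats` (one-row tibble: `n`, `mean_delta_angle`,
#'   `sd_delta_angle`, `mean_ratio`, `sd_ratio`) and `histogram` (tibble of
#'   `angle_mid`, `ratio_mid`, `count`); the number of pairs falling
#'   outside the grid is the histogram's `"outside"` attribute.
#' @export
angle_summary <- function(pairs, angle_lim = c(0, 60),
                          ratio_lim = c(0.4, 1.4), nbins = 30) {
  if (nrow(pairs) == 0) abort("no pairs to summarise")
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  stats <- tibble::tibble(
    n = nrow(pairs),
    mean_delta_angle = mean(pairs$delta_angle),
    sd_delta_angle = pop_sd(pairs$delta_angle),
    mean_ratio = mean(pairs$child_over_parent),
    sd_ratio = pop_sd(pairs$child_over_parent)
  )
  abr <- seq(angle_lim[1], angle_lim[2], length.out = nbins + 1)
  rbr <- seq(ratio_lim[1], ratio_lim[2], length.out = nbins + 1)
  ai <- findInterval(pairs$delta_angle, abr, rightmost.closed = TRUE)
  ri <- findInterval(pairs$child_over_parent, rbr, rightmost.closed = TRUE)
  inside <- ai >= 1 & ai <= nbins & ri >= 1 & ri <= nbins
  counts <- table(factor(ai[inside], levels = seq_len(nbins)),
                  factor(ri[inside], levels = seq_len(nbins)))
  hist <- tidyr::expand_grid(ai = seq_len(nbins), ri = seq_len(nbins)) |>
    dplyr::mutate(
      angle_mid = (abr[.data$ai] + abr[.data$ai + 1]) / 2,
      ratio_mid = (rbr[.data$ri] + rbr[.data$ri + 1]) / 2,
      count = as.integer(counts[cbind(.data$ai, .data$ri)])
    ) |>
    dplyr::select("angle_mid", "ratio_mid", "count")
  attr(hist, "outside") <- sum(!inside)
  list(stats = stats, histogram = hist)
}

#' Rank-correlation test of Murray's angle prediction
#'
#' Murray's Law predicts that the wider child branch leaves the fork at a
#' smaller angle to the parent, so across parent-child pairs the angular
#' difference and the child/parent diameter ratio should be negatively
#' rank-correlated. Computes the Spearman correlation (average ranks for
#' ties, asymptotic p-value) between `delta_angle` and `child_over_parent`.
#'
#' @param pairs A tibble from [build_pairs()] with at least 10 rows.
#' @return A one-row tibble: `rho`, `p_value`, `n`, `method`.
#' @export
murray_angle_test <- function(pairs) {
  if (nrow(pairs) < 10) abort("need at least 10 pairs")
  if (sd(pairs$delta_angle) == 0 || sd(pairs$child_over_parent) == 0) {
    abort("correlation undefined: one of the variables is constant (all tied)")
  }
  ct <- suppressWarnings(
    cor.test(pairs$delta_angle, pairs$child_over_parent,
             method = "spearman", exact = FALSE)
  )
  tibble::tibble(
    rho = unname(ct$estimate),
    p_value = ct$p.value,
    n = nrow(pairs),
    method = "spearman"
  )
}

#' Heatmap of the angle/diameter pair distribution
#'
#' @param summary A list returned by [angle_summary()].
#' @return A ggplot object.
#' @export
plot_angle_heatmap <- function(summary) {
  ggplot2::ggplot(summary$histogram,
                  ggplot2::aes(x = .data$angle_mid, y = .data$ratio_mid,
                               fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "parent-child angle difference (degrees)",
                  y = "child / parent diameter ratio",
                  fill = "pairs")
}
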