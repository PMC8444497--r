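#' Classify the geometry of a bifurcation
#'
#' A fork where a parent tube of internal diameter `d0` splits into children
#' `d1`, `d2` falls into exactly one geometric case, which determines whether
#' the junction-exponent equation `d0^k = d1^k + d2^k` has a real root:
#'
#' * `"standard"` — both children narrower than the parent; a unique root
#'   `k > 0` exists.
#' * `"both_wider"` — both children wider; a unique root `k < 0` exists.
#' * `"mixed"` — one child wider, one narrower (an asymmetric fork); no real
#'   root exists and only a best-fit exponent can be reported.
#' * `"degenerate"` — a child diameter exactly equals the parent diameter.
#'
#' The label never depends on the order of the two children.
#'
#' @param d0,d1,d2 Numeric vectors of parent and child internal diameters
#'   (microns, or any common unit — the classification is scale invariant).
#'   All must be strictly positive.
#' @return A character vector of case labels, one per fork.
#' @examples
#' classify_junction(100, 80, 80)
#' classify_junction(c(100, 100), c(110, 105), c(110, 99.9))
#' @export
classify_junction <- function(d0, d1, d2) {
  check_diameters(d0, d1, d2)
  dplyr::case_when(
    d1 == d0 | d2 == d0 ~ "degenerate",
    d1 < d0 & d2 < d0 ~ "standard",
    d1 > d0 & d2 > d0 ~ "both_wider",
    TRUE ~ "mixed"
  )
}

check_diameters <- function(d0, d1, d2) {
  if (length(d0) != length(d1) || length(d0) != length(d2)) {
    abort("`d0`, `d1` and `d2` must have the same length.")
  }
  bad <- !is.finite(d0) | !is.finite(d1) | !is.finite(d2) |
    d0 <= 0 | d1 <= 0 | d2 <= 0
  if (any(bad)) {
    abort(sprintf(
      "all diameters must be finite and > 0 (first offending element: %d)",
      which(bad)[1]
    ))
  }
  invisible(TRUE)
}

#' Solve the junction-exponent equation for measured forks
#'
#' Finds the junction exponent `k` satisfying `d0^k = d1^k + d2^k` for each
#' bifurcation, working on the diameter ratios `a = d1/d0`, `b = d2/d0` so
#' the result is exactly scale invariant. The transcendental function
#' `f(k) = a^k + b^k` is strictly monotone when both ratios lie on the same
#' side of 1, giving a unique bracketed root (positive `k` in the standard
#' case, negative when both children are wider). For mixed (asymmetric)
#' forks `f(k) > 1` for every real `k`, so no exponent satisfies the
#' equation; there `k` is reported as the argmin of `f`, the best-fit
#' exponent, located by root-finding on the derivative of `f` (which is
#' convex with a single stationary point). Symmetric forks (`d1 == d2`) use
#' the closed form `k = log(2) / log(d0/d1)` directly.
#'
#' Forks whose solution magnitude would exceed `k_bound` are reported as
#' `"uncomputable"` (mirroring forks so extreme that standard software
#' cannot evaluate them), and forks with a child exactly equal to the parent
#' as `"degenerate"`; both carry `k = NA`.
#'
#' @inheritParams classify_junction
#' @param tol Residual tolerance for exact roots; roots are polished until
#'   `|a^k + b^k - 1| <= tol` or machine precision is reached.
#' @param k_bound Magnitude cap on `|k|`; beyond it the fork is labelled
#'   `"uncomputable"`.
#' @return A tibble with one row per fork and columns
#'   \describe{
#'     \item{k}{the junction exponent (`NA` for degenerate/uncomputable)}
#'     \item{case}{geometric case, see [classify_junction()]}
#'     \item{k_kind}{`"exact_root"`, `"argmin"` (mixed forks), or `"none"`}
#'     \item{residual}{`|a^k + b^k - 1|` at the returned `k`}
#'     \item{iterations}{number of objective evaluations spent}
#'   }
#' @examples
#' solve_k(1, 2^(-1/3), 2^(-1/3))  # Murray's Law construction, k = 3
#' solve_k(100, 80, 80)
#' solve_k(1, 1.05, 0.999)         # asymmetric: best-fit exponent, no root
#' @seealso [solve_junctions()] to append these columns to a measurement
#'   table, [k_symmetric()] and [k_mixed_argmin()] for the closed forms.
#' @export
solve_k <- function(d0, d1, d2, tol = 1e-12, k_bound = 1e6) {
  check_diameters(d0, d1, d2)
  res <- purrr::pmap(list(d0, d1, d2), function(p, c1, c2) {
    solve_k_one(c1 / p, c2 / p, tol = tol, k_bound = k_bound)
  })
  dplyr::bind_rows(res)
}

#' Append junction-exponent solutions to a measurement table
#'
#' Data-frame-first wrapper around [solve_k()]: takes a table with columns
#' `d0`, `d1`, `d2` and returns it with `k`, `case`, `k_kind`, `residual`
#' and `iterations` columns appended (plus a stable `record_id` if absent,
#' used downstream for filtering provenance).
#'
#' @param data A data frame with numeric columns `d0`, `d1`, `d2`.
#' @inheritParams solve_k
#' @return The input as a tibble with solution columns appended.
#' @examples
#' tibble::tibble(d0 = c(100, 50), d1 = c(80, 45), d2 = c(80, 30)) |>
#'   solve_junctions()
#' @export
solve_junctions <- function(data, tol = 1e-12, k_bound = 1e6) {
  need <- c("d0", "d1", "d2")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("`data` lacks required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  data <- tibble::as_tibble(data)
  if (!"record_id" %in% names(data)) {
    data <- dplyr::mutate(data, record_id = dplyr::row_number(),
                          .before = 1)
  }
  dplyr::bind_cols(data, solve_k(data$d0, data$d1, data$d2,
                                 tol = tol, k_bound = k_bound))
}

# Core scalar solver on ratios a = d1/d0, b = d2/d0.
solve_k_one <- function(a, b, tol = 1e-12, k_bound = 1e6) {
  out <- function(k, case, kind, iter) {
    residual <- if (is.na(k)) NA_real_ else abs(a^k + b^k - 1)
    tibble::tibble(k = k, case = case, k_kind = kind,
                   residual = residual, iterations = iter)
  }
  if (a == 1 || b == 1) {
    return(out(NA_real_, "degenerate", "none", 0L))
  }
  # symmetric fork: closed form, no iteration
  if (a == b) {
    k <- log(2) / log(1 / a)
    if (abs(k) > k_bound) return(out(NA_real_, "uncomputable", "none", 0L))
    case <- if (a < 1) "standard" else "both_wider"
    return(out(k, case, "exact_root", 0L))
  }
  if (a < 1 && b < 1) {
    r <- root_decreasing(a, b, tol, k_bound)
    if (is.na(r$k)) return(out(NA_real_, "uncomputable", "none", r$iter))
    return(out(r$k, "standard", "exact_root", r$iter))
  }
  if (a > 1 && b > 1) {
    # mirror: f(-k) with inverted ratios is the standard problem
    r <- root_decreasing(1 / a, 1 / b, tol, k_bound)
    if (is.na(r$k)) return(out(NA_real_, "uncomputable", "none", r$iter))
    return(out(-r$k, "both_wider", "exact_root", r$iter))
  }
  # mixed: no real root (f > 1 everywhere); report the argmin of f
  if (b > 1) { tmp <- a; a <- b; b <- tmp }  # ensure a > 1 > b
  r <- argmin_mixed(a, b, k_bound)
  if (is.na(r$k)) return(out(NA_real_, "uncomputable", "none", r$iter))
  out(r$k, "mixed", "argmin", r$iter)
}

# Unique positive root of a^k + b^k = 1 for 0 < a, b < 1: f is strictly
# decreasing from f(0) = 2 towards 0, so bracket by geometric growth then
# bisection via uniroot, with one Newton polish for the residual contract.
root_decreasing <- function(a, b, tol, k_bound) {
  la <- log(a); lb <- log(b)
  n_eval <- 0L
  f <- function(k) {
    n_eval <<- n_eval + 1L
    exp(k * la) + exp(k * lb) - 1
  }
  lo <- 0; hi <- 1  # f(0) = 1 > 0
  while (f(hi) > 0) {
    lo <- hi
    hi <- hi * 2
    if (hi > k_bound) return(list(k = NA_real_, iter = n_eval))
  }
  k <- uniroot(f, c(lo, hi), tol = 1e-14)$root
  # Newton polish (derivative is analytic and nonzero at the root)
  fp <- la * exp(k * la) + lb * exp(k * lb)
  if (is.finite(fp) && fp != 0) {
    k2 <- k - f(k) / fp
    if (is.finite(k2) && abs(f(k2)) <= abs(f(k))) k <- k2
  }
  if (abs(k) > k_bound) return(list(k = NA_real_, iter = n_eval))
  list(k = k, iter = n_eval)
}

# Minimiser of f(k) = a^k + b^k for a > 1 > b: f is convex with f' strictly
# increasing, so the argmin is the unique zero of f'. We root-find on a
# rescaled derivative g(k) = la * exp(k (la - lb)) + lb, which has the same
# sign as f'(k) but cannot overflow near the root.
argmin_mixed <- function(a, b, k_bound) {
  la <- log(a); lb <- log(b)  # la > 0 > lb
  n_eval <- 0L
  g <- function(k) {
    n_eval <<- n_eval + 1L
    z <- pmin(k * (la - lb), 700)
    la * exp(z) + lb
  }
  lo <- -1
  while (g(lo) > 0) {
    lo <- lo * 2
    if (-lo > k_bound) return(list(k = NA_real_, iter = n_eval))
  }
  hi <- 1
  while (g(hi) < 0) {
    hi <- hi * 2
    if (hi > k_bound) return(list(k = NA_real_, iter = n_eval))
  }
  k <- uniroot(g, c(lo, hi), tol = 1e-11)$root
  if (abs(k) > k_bound) return(list(k = NA_real_, iter = n_eval))
  list(k = k, iter = n_eval)
}

#' Closed-form junction exponent for a symmetric fork
#'
#' When the two children have equal diameter `d_child`, the equation
#' `d0^k = 2 d_child^k` gives `k = log(2) / log(d0 / d_child)` directly.
#' Used as an independent oracle for the iterative solver.
#'
#' @param d0 Parent diameter (> 0).
#' @param d_child Common child diameter (> 0, different from `d0`).
#' @return The junction exponent, a numeric vector.
#' @examples
#' k_symmetric(1, 0.5)          # 1: diameters halve, areas conserved at k=1
#' k_symmetric(1, 2^(-1/3))     # 3: Murray's Law
#' @export
k_symmetric <- function(d0, d_child) {
  if (any(d0 <= 0) || any(d_child <= 0)) {
    abort("diameters must be > 0")
  }
  if (any(d_child == d0)) {
    abort("`d_child` must differ from `d0` (degenerate fork)")
  }
  log(2) / log(d0 / d_child)
}

#' Closed-form best-fit exponent for a mixed fork
#'
#' For ratios `a = d1/d0 > 1 > b = d2/d0`, the sum `f(k) = a^k + b^k`
#' exceeds 1 for every real `k`, so the junction equation has no solution.
#' Its unique minimiser has the closed form
#' `k* = log(log(1/b) / log(a)) / log(a/b)`, used as an independent oracle
#' for the numeric argmin returned by [solve_k()] on mixed forks.
#'
#' @param a Ratio of the wider child to the parent (> 1).
#' @param b Ratio of the narrower child to the parent (in (0, 1)).
#' @return The minimising exponent, a numeric vector.
#' @examples
#' k_mixed_argmin(1.1, 0.6)
#' k_mixed_argmin(1.5, 1/1.5)  # 0 by symmetry of f about k = 0
#' @export
k_mixed_argmin <- function(a, b) {
  if (any(a <= 1) || any(b <= 0) || any(b >= 1)) {
    abort("need a > 1 > b > 0")
  }
  log(log(1 / b) / log(a)) / log(a / b)
}
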