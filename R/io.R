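# Canonical measurement schema. One row = one measured bifurcation.
# Units: diameters in microns, angles in degrees, wing length in mm.
CANONICAL_COLUMNS <- c(
  "specimen_id", "taxon_superfamily", "taxon_family", "order_label",
  "wing_length", "fork_index", "d0", "d1", "d2",
  "angle_children", "angle_parent_child1", "angle_parent_child2"
)
REQUIRED_COLUMNS <- c("specimen_id", "taxon_superfamily", "order_label",
                      "fork_index", "d0", "d1", "d2")
NUMERIC_COLUMNS <- c("wing_length", "d0", "d1", "d2", "angle_children",
                     "angle_parent_child1", "angle_parent_child2")
ANGLE_COLUMNS <- c("angle_children", "angle_parent_child1",
                   "angle_parent_child2")
ORDER_LEVELS <- c("Lepidoptera", "Trichoptera")

#' Read a bifurcation measurement table
#'
#' Reads a CSV of per-fork vein measurements into the canonical schema and
#' validates every row. Validation is total: each input row is either
#' accepted or rejected with a located diagnostic (row number, field,
#' reason), and `accepted + rejected` always equals the number of rows read.
#' Rejected rows are dropped from the result, reported via a warning, and
#' available in full through [measurement_problems()].
#'
#' The canonical schema has columns `specimen_id`, `taxon_superfamily`,
#' `taxon_family` (optional), `order_label` (`"Lepidoptera"` or
#' `"Trichoptera"`), `wing_length` (mm, optional), `fork_index` (1-3),
#' `d0`, `d1`, `d2` (internal cavity diameters, microns), and the optional
#' angle columns `angle_children`, `angle_parent_child1`,
#' `angle_parent_child2` (degrees, in `[0, 180)`). Missing optional values
#' are empty cells. Files from other sources can be mapped onto this schema
#' by passing a named `dialect` vector (`c(canonical_name = "file_column")`).
#'
#' @param path Path to a CSV file (UTF-8, `.` decimal).
#' @param dialect Either `"canonical"` (default) or a named character vector
#'   mapping canonical column names to the file's column names.
#' @return A tibble of validated records in file order, one row per accepted
#'   bifurcation, with a `record_id` column numbering the original file rows.
#'   The rejected-row diagnostics are attached as the `"problems"` attribute.
#' @examples
#' path <- tempfile(fileext = ".csv")
#' write_table(simulate_venation(synthetic_truth(n_bifurcations = 5)), path)
#' read_measurements(path)
#' @export
read_measurements <- function(path, dialect = "canonical") {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path))
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!is.character(dialect)) {
    abort("`dialect` must be \"canonical\" or a named character vector")
  }
  if (length(dialect) > 1 || !identical(unname(dialect), "canonical")) {
    if (is.null(names(dialect)) || any(names(dialect) == "")) {
      abort("a dialect mapping must be a fully named character vector")
    }
    missing_src <- setdiff(unname(dialect), names(raw))
    if (length(missing_src) > 0) {
      abort(paste0("dialect refers to absent column(s): ",
                   paste(missing_src, collapse = ", ")))
    }
    raw <- raw[, unname(dialect), drop = FALSE]
    names(raw) <- names(dialect)
  }
  missing_req <- setdiff(REQUIRED_COLUMNS, names(raw))
  if (length(missing_req) > 0) {
    abort(paste0("missing required column(s): ",
                 paste(missing_req, collapse = ", ")))
  }
  for (col in setdiff(CANONICAL_COLUMNS, names(raw))) {
    raw[[col]] <- NA_character_
  }
  raw <- raw[, CANONICAL_COLUMNS, drop = FALSE]
  validate_rows(raw)
}

# Row-by-row validation against the record invariants. Returns accepted rows
# (typed) with rejected-row diagnostics in the "problems" attribute.
validate_rows <- function(raw) {
  n <- nrow(raw)
  problems <- list()
  note <- function(row, field, reason) {
    problems[[length(problems) + 1L]] <<-
      tibble::tibble(row = row, field = field, reason = reason)
  }

  parse_num <- function(col) {
    x <- raw[[col]]
    out <- suppressWarnings(as.numeric(x))
    bad <- !is.na(x) & x != "" & is.na(out)
    for (i in which(bad)) note(i, col, "unparseable number")
    out[x == "" | is.na(x)] <- NA_real_
    list(value = out, bad = bad)
  }

  nums <- lapply(setNames(NUMERIC_COLUMNS, NUMERIC_COLUMNS), parse_num)
  fk <- parse_num("fork_index")

  reject <- rep(FALSE, n)
  for (col in NUMERIC_COLUMNS) reject <- reject | nums[[col]]$bad
  reject <- reject | fk$bad

  for (col in c("d0", "d1", "d2")) {
    v <- nums[[col]]$value
    miss <- is.na(v) & !nums[[col]]$bad
    for (i in which(miss)) note(i, col, "missing required diameter")
    nonpos <- !is.na(v) & v <= 0
    for (i in which(nonpos)) note(i, col, "diameter must be > 0")
    reject <- reject | miss | nonpos
  }
  for (col in ANGLE_COLUMNS) {
    v <- nums[[col]]$value
    bad <- !is.na(v) & (v < 0 | v >= 180)
    for (i in which(bad)) note(i, col, "angle outside [0, 180)")
    reject <- reject | bad
  }
  fkv <- fk$value
  badfk <- (!is.na(fkv) & (!fkv %in% 1:3)) | (is.na(fkv) & !fk$bad)
  for (i in which(badfk)) note(i, "fork_index", "fork_index must be 1, 2 or 3")
  reject <- reject | badfk

  badord <- !is.na(raw$order_label) & !raw$order_label %in% ORDER_LEVELS
  for (i in which(badord)) {
    note(i, "order_label",
         paste0("order_label must be one of: ",
                paste(ORDER_LEVELS, collapse = ", ")))
  }
  reject <- reject | badord

  # at most one row per (specimen, fork): duplicates beyond the first rejected
  key <- paste(raw$specimen_id, fkv, sep = "\r")
  dup <- duplicated(key) & !reject
  for (i in which(dup)) note(i, "fork_index", "duplicate (specimen_id, fork_index)")
  reject <- reject | dup

  out <- tibble::tibble(
    record_id = seq_len(n),
    specimen_id = raw$specimen_id,
    taxon_superfamily = raw$taxon_superfamily,
    taxon_family = raw$taxon_family,
    order_label = raw$order_label,
    wing_length = nums$wing_length$value,
    fork_index = as.integer(fkv),
    d0 = nums$d0$value,
    d1 = nums$d1$value,
    d2 = nums$d2$value,
    angle_children = nums$angle_children$value,
    angle_parent_child1 = nums$angle_parent_child1$value,
    angle_parent_child2 = nums$angle_parent_child2$value
  )[!reject, , drop = FALSE]

  probs <- if (length(problems) > 0) {
    dplyr::arrange(dplyr::bind_rows(problems), .data$row)
  } else {
    tibble::tibble(row = integer(), field = character(), reason = character())
  }
  if (sum(reject) > 0) {
    warn(sprintf(
      "%d of %d row(s) rejected during validation; see measurement_problems()",
      sum(reject), n
    ))
  }
  attr(out, "problems") <- probs
  attr(out, "n_read") <- n
  out
}

#' Retrieve validation diagnostics from a measurement table
#'
#' @param data A tibble returned by [read_measurements()].
#' @return A tibble with columns `row`, `field`, `reason`, one row per
#'   located validation problem.
#' @export
measurement_problems <- function(data) {
  attr(data, "problems") %||%
    tibble::tibble(row = integer(), field = character(), reason = character())
}

#' Write a measurement or result table to CSV
#'
#' Writes any of the package's tabular payloads (measurement records, solved
#' exponent tables, variant tables, binned series) as RFC-4180 CSV with full
#' floating-point round-trip precision; empty cells encode missing optional
#' values. `read_measurements(write_table(x))` reproduces `x`
#' field-for-field.
#'
#' @param data A nonempty data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_table <- function(data, path) {
  if (!is.data.frame(data) || nrow(data) == 0) {
    abort("`data` must be a data frame with at least one row")
  }
  # 17 significant digits guarantee exact double round-trips
  out <- dplyr::mutate(data, dplyr::across(
    dplyr::where(is.double),
    function(x) {
      dplyr::if_else(is.na(x), NA_character_, sprintf("%.17g", x))
    }
  ))
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}
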