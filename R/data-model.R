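#' Construct a methylation dataset
#'
#' Bundles an n-sites-by-m-individuals matrix of methylation levels with
#' site/individual identifiers and (optionally) per-individual chronological
#' ages. Sites are rows, individuals are columns; column \code{j} of
#' \code{values} belongs to \code{individual_ids[j]} and \code{ages[j]}.
#'
#' @param values Numeric matrix, sites in rows, individuals in columns.
#'   A data frame whose first column holds site identifiers (remaining
#'   columns numeric) is also accepted.
#' @param site_ids Character vector of unique site labels. Defaults to the
#'   rownames of \code{values} (or its first column when a data frame).
#' @param individual_ids Character vector of unique individual labels.
#'   Defaults to the column names.
#' @param ages Optional numeric vector of chronological ages in years,
#'   strictly positive, aligned with the columns. Attach later with
#'   [attach_ages()] if not yet known.
#'
#' @return An object of class \code{methylation_dataset}: a list with
#'   elements \code{values}, \code{site_ids}, \code{individual_ids},
#'   \code{ages} (possibly \code{NULL}), \code{n} (sites), \code{m}
#'   (individuals).
#' @export
#' @examples
#' x <- matrix(rnorm(6), 2, 3, dimnames = list(c("cg1", "cg2"), c("a", "b", "c")))
#' methylation_dataset(x, ages = c(25, 40, 60))
methylation_dataset <- function(values, site_ids = NULL, individual_ids = NULL,
                                ages = NULL) {
  if (is.data.frame(values)) {
    site_ids <- site_ids %||% as.character(values[[1]])
    mat <- as.matrix(values[-1])
    storage.mode(mat) <- "double"
    individual_ids <- individual_ids %||% colnames(values)[-1]
    values <- mat
  }
  if (!is.matrix(values) || !is.numeric(values)) {
    rlang::abort("`values` must be a numeric matrix (sites x individuals).",
                 class = "upmclock_error_format")
  }
  site_ids <- as.character(site_ids %||% rownames(values) %||% paste0("site_", seq_len(nrow(values))))
  individual_ids <- as.character(individual_ids %||% colnames(values) %||% paste0("ind_", seq_len(ncol(values))))
  if (length(site_ids) != nrow(values))
    rlang::abort("`site_ids` length must equal nrow(values).", class = "upmclock_error_format")
  if (length(individual_ids) != ncol(values))
    rlang::abort("`individual_ids` length must equal ncol(values).", class = "upmclock_error_format")
  if (anyDuplicated(site_ids))
    rlang::abort("Site identifiers must be unique.", class = "upmclock_error_validation")
  if (anyDuplicated(individual_ids))
    rlang::abort("Individual identifiers must be unique.", class = "upmclock_error_validation")
  if (anyNA(values) || any(!is.finite(values)))
    rlang::abort("Methylation values must be finite and non-missing.",
                 class = "upmclock_error_validation")
  dimnames(values) <- list(site_ids, individual_ids)
  ds <- structure(
    list(values = values, site_ids = site_ids, individual_ids = individual_ids,
         ages = NULL, n = nrow(values), m = ncol(values)),
    class = "methylation_dataset"
  )
  if (!is.null(ages)) ds <- set_ages(ds, ages)
  ds
}

`%||%` <- function(a, b) if (is.null(a)) b else a

set_ages <- function(ds, ages) {
  ages <- as.numeric(ages)
  if (length(ages) != ds$m)
    rlang::abort(sprintf("`ages` must have one entry per individual (%d).", ds$m),
                 class = "upmclock_error_validation")
  if (anyNA(ages) || any(!is.finite(ages)) || any(ages <= 0))
    rlang::abort("Ages must be finite and strictly positive (years).",
                 class = "upmclock_error_validation")
  ds$ages <- stats::setNames(ages, ds$individual_ids)
  ds
}

#' @export
print.methylation_dataset <- function(x, ...) {
  cat(sprintf("<methylation_dataset> %d sites x %d individuals\n", x$n, x$m))
  if (is.null(x$ages)) {
    cat("  ages: not attached\n")
  } else {
    cat(sprintf("  ages: %.1f-%.1f years\n", min(x$ages), max(x$ages)))
  }
  invisible(x)
}

#' Read a methylation matrix from a delimited file
#'
#' Expects a header row of individual identifiers and a first column of site
#' identifiers; every remaining cell must be numeric. Returns a dataset with
#' ages unset; attach them with [attach_ages()].
#'
#' @param path Path to a CSV/TSV file.
#' @param delimiter Field delimiter, default tab.
#' @param transpose If \code{TRUE} the file is individuals-in-rows /
#'   sites-in-columns and is transposed on read.
#' @return A [methylation_dataset()] without ages.
#' @export
read_methylation_matrix <- function(path, delimiter = "\t", transpose = FALSE) {
  if (!file.exists(path))
    rlang::abort(sprintf("File not found: %s", path), class = "upmclock_error_io")
  raw <- readr::read_delim(path, delim = delimiter, col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE, show_col_types = FALSE)
  if (ncol(raw) < 2)
    rlang::abort("Matrix file needs a site-id column plus at least one individual column.",
                 class = "upmclock_error_format")
  row_ids <- as.character(raw[[1]])
  col_ids <- colnames(raw)[-1]
  cells <- as.matrix(raw[-1])
  suppressWarnings(num <- matrix(as.numeric(cells), nrow(cells), ncol(cells)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    rlang::abort(
      sprintf("Non-numeric cell '%s' at site '%s', individual '%s'.",
              cells[bad[1], bad[2]], row_ids[bad[1]], col_ids[bad[2]]),
      class = "upmclock_error_parse"
    )
  }
  dimnames(num) <- list(row_ids, col_ids)
  if (transpose) num <- t(num)
  methylation_dataset(num)
}

#' Read a two-column individual/age table
#'
#' @param path Path to a delimited file with columns (individual_id, age).
#' @param delimiter Field delimiter, default tab.
#' @return A named numeric vector of ages keyed by individual id.
#' @export
read_ages <- function(path, delimiter = "\t") {
  if (!file.exists(path))
    rlang::abort(sprintf("File not found: %s", path), class = "upmclock_error_io")
  tab <- readr::read_delim(path, delim = delimiter, col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE, show_col_types = FALSE)
  if (ncol(tab) < 2)
    rlang::abort("Age file must have two columns: individual_id, age.",
                 class = "upmclock_error_format")
  ids <- as.character(tab[[1]])
  suppressWarnings(ages <- as.numeric(tab[[2]]))
  bad <- which(is.na(ages) | !is.finite(ages) | ages <= 0)
  if (length(bad))
    rlang::abort(sprintf("Invalid age '%s' for individual '%s' (must be a positive number).",
                         as.character(tab[[2]])[bad[1]], ids[bad[1]]),
                 class = "upmclock_error_validation")
  dup <- ids[duplicated(ids)]
  if (length(dup))
    rlang::abort(sprintf("Duplicate individual id(s) in age table: %s",
                         paste(unique(dup), collapse = ", ")),
                 class = "upmclock_error_validation")
  stats::setNames(ages, ids)
}

#' Attach ages to a dataset and validate it for model fitting
#'
#' Aligns the age map to the dataset's column order and enforces the fitting
#' preconditions: every individual has an age, at least 2 sites and 3
#' individuals (the pacemaker fit estimates one free time per individual, so
#' smaller inputs are unidentifiable).
#'
#' @param ds A [methylation_dataset()].
#' @param ages Named numeric vector (as from [read_ages()]), or an unnamed
#'   vector already aligned to the dataset's columns.
#' @return The validated dataset with \code{ages} set. Idempotent: passing a
#'   dataset whose ages are already attached (with \code{ages} omitted)
#'   returns it unchanged.
#' @export
attach_ages <- function(ds, ages = NULL) {
  stopifnot(inherits(ds, "methylation_dataset"))
  if (is.null(ages)) {
    if (is.null(ds$ages))
      rlang::abort("No ages supplied and none attached.", class = "upmclock_error_validation")
    ages <- ds$ages
  }
  if (!is.null(names(ages))) {
    missing <- setdiff(ds$individual_ids, names(ages))
    if (length(missing))
      rlang::abort(sprintf("No age for individual(s): %s", paste(missing, collapse = ", ")),
                   class = "upmclock_error_validation")
    ages <- ages[ds$individual_ids]
  }
  ds <- set_ages(ds, ages)
  if (ds$n < 2 || ds$m < 3)
    rlang::abort(sprintf(
      "Insufficient data: need >= 2 sites and >= 3 individuals, got %d x %d.",
      ds$n, ds$m), class = "upmclock_error_insufficient")
  ds
}

#' Write a result table to a delimited file
#'
#' Numbers are serialized with full (round-trippable) precision, i.e. more
#' than 10 significant digits survive a write/read cycle.
#'
#' @param rows A data frame / tibble.
#' @param path Output path.
#' @param delimiter Field delimiter, default tab.
#' @return Invisibly, \code{rows}.
#' @export
write_table <- function(rows, path, delimiter = "\t") {
  rows <- tibble::as_tibble(rows)
  readr::write_delim(rows, path, delim = delimiter, progress = FALSE)
  invisible(rows)
}

#' Convert a methylation dataset to a tidy tibble
#'
#' One row per (site, individual) cell, carrying the age when attached.
#'
#' @param x A [methylation_dataset()].
#' @param ... Unused.
#' @return A tibble with columns site_id, individual_id, age, value.
#' @method tidy methylation_dataset
#' @export
tidy.methylation_dataset <- function(x, ...) {
  tibble::tibble(
    site_id = rep(x$site_ids, times = x$m),
    individual_id = rep(x$individual_ids, each = x$n),
    age = if (is.null(x$ages)) NA_real_ else rep(unname(x$ages), each = x$n),
    value = as.vector(x$values)
  )
}
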