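#' Build a serial-dilution CT table
#'
#' A dilution table is the sole experimental input of the workflow: a long
#' tibble with one row per primer x dilution cell, columns `primer`
#' (character), `dilution` (relative initial concentration in (0, 1],
#' undiluted = 1) and `ct` (threshold cycle; `NA` marks undetectable
#' product). The constructor validates the grid, completes absent cells with
#' `NA`, optionally applies CT censoring, and orders rows by primer (input
#' order) and decreasing dilution.
#'
#' @param x A data frame with columns `primer`, `dilution`, `ct`.
#' @param ct_cutoff Optional censoring threshold in cycles: CT values strictly
#'   greater than the cutoff are set to `NA` (undetectable product). Use
#'   `NULL` to leave values as supplied.
#' @return A tibble of class `dilution_table` with columns
#'   `primer`, `dilution`, `ct`, containing a complete primer x dilution grid.
#' @examples
#' df <- tidyr::expand_grid(primer = c("a", "b"), dilution = c(1, 0.1, 0.01))
#' df$ct <- 20 - log2(df$dilution) + rep(c(0, 2), each = 3)
#' dilution_table(df)
#' @export
dilution_table <- function(x, ct_cutoff = NULL) {
  if (!is.data.frame(x)) {
    abort("`x` must be a data frame with columns primer, dilution, ct.")
  }
  x <- as_tibble(x)
  missing_cols <- setdiff(c("primer", "dilution", "ct"), names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing column(s): ", paste(missing_cols, collapse = ", "), "."))
  }
  x <- select(x, "primer", "dilution", "ct")
  x$primer <- as.character(x$primer)
  if (!is.numeric(x$dilution)) {
    abort("`dilution` must be numeric relative concentrations.", class = "qpcreff_format_error")
  }
  x$ct <- as.numeric(x$ct)
  if (anyNA(x$dilution) || any(x$dilution <= 0) || any(x$dilution > 1)) {
    abort("Dilution levels must lie in (0, 1] (undiluted = 1).",
          class = "qpcreff_format_error")
  }
  if (any(is.na(x$primer) | x$primer == "")) {
    abort("Primer ids must be non-empty strings.", class = "qpcreff_format_error")
  }
  if (nrow(distinct(x, .data$primer, .data$dilution)) < nrow(x)) {
    dup <- x[duplicated(x[c("primer", "dilution")]), , drop = FALSE]
    abort(paste0("Duplicate (primer, dilution) cell(s), e.g. ",
                 dup$primer[1], " @ ", dup$dilution[1], "."),
          class = "qpcreff_format_error")
  }
  levels <- sort(unique(x$dilution), decreasing = TRUE)
  if (length(levels) < 2) {
    abort("At least 2 dilution levels are required.", class = "qpcreff_input_error")
  }
  bad_ct <- !is.na(x$ct) & (!is.finite(x$ct) | x$ct <= 0)
  if (any(bad_ct)) {
    abort("CT values must be finite and > 0 (or NA for undetectable).",
          class = "qpcreff_format_error")
  }
  primer_order <- unique(x$primer)
  x <- tidyr::complete(x,
    primer = primer_order,
    dilution = levels,
    fill = list(ct = NA_real_)
  )
  x <- arrange(x,
    factor(.data$primer, levels = primer_order),
    dplyr::desc(.data$dilution)
  )
  if (!is.null(ct_cutoff)) x <- censor_ct(x, ct_cutoff)
  new_dilution_table(x)
}

new_dilution_table <- function(x) {
  class(x) <- unique(c("dilution_table", class(tibble())))
  x
}

#' Censor undetectable CT values
#'
#' Applies the detectability rule cellwise: CT values strictly greater than
#' `ct_cutoff` cycles indicate undetectable product and are replaced by `NA`.
#' Idempotent: applying the rule twice equals applying it once.
#'
#' @param table A [dilution_table()] (or data frame with a `ct` column).
#' @param ct_cutoff Censoring threshold in cycles (default 40).
#' @return The table with censored `ct` values.
#' @export
censor_ct <- function(table, ct_cutoff = 40) {
  stopifnot(is.numeric(ct_cutoff), length(ct_cutoff) == 1, ct_cutoff > 0)
  table$ct[!is.na(table$ct) & table$ct > ct_cutoff] <- NA_real_
  table
}

#' Dilution levels of a table
#'
#' @param table A [dilution_table()].
#' @return Numeric vector of dilution levels, strictly decreasing.
#' @export
dilution_levels <- function(table) {
  sort(unique(table$dilution), decreasing = TRUE)
}

#' Primer ids of a table
#'
#' @param table A [dilution_table()].
#' @return Character vector of primer ids in input order.
#' @export
primer_ids <- function(table) unique(table$primer)

#' @export
print.dilution_table <- function(x, ...) {
  nlev <- length(dilution_levels(x))
  np <- length(primer_ids(x))
  cat(sprintf("<dilution_table: %d primers x %d dilution levels, %d censored cell(s)>\n",
              np, nlev, sum(is.na(x$ct))))
  NextMethod()
}
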