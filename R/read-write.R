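#' Read a serial-dilution CT table from CSV/TSV
#'
#' Two layouts are accepted. Long (the canonical on-disk form): columns
#' `primer`, `dilution`, `ct`. Wide: one row per primer; the first column
#' holds the primer id and every remaining column is named by its numeric
#' dilution level (e.g. `1, 0.1, 0.01, 0.001`). The delimiter is sniffed from
#' the file extension (`.csv` comma, anything else tab) unless `delim` is
#' given. CT values above `ct_cutoff` and empty/NA cells are treated as
#' missing (undetectable product).
#'
#' @param path Path to a CSV or TSV file.
#' @param layout `"auto"` (detect from column names), `"long"` or `"wide"`.
#' @param ct_cutoff Censoring threshold in cycles (default 40); values
#'   strictly above it become `NA`.
#' @param delim Field delimiter; default sniffed from the extension.
#' @return A [dilution_table()].
#' @export
read_dilution_table <- function(path, layout = c("auto", "long", "wide"),
                                ct_cutoff = 40, delim = NULL) {
  layout <- match.arg(layout)
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  delim <- delim %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE, trim_ws = TRUE,
                           na = c("", "NA", "na", "NaN"))
  if (layout == "auto") {
    layout <- if (all(c("primer", "dilution", "ct") %in% tolower(names(raw)))) {
      "long"
    } else {
      "wide"
    }
  }
  if (layout == "long") {
    names(raw) <- tolower(names(raw))
    if (!all(c("primer", "dilution", "ct") %in% names(raw))) {
      abort("Long layout requires columns primer, dilution, ct.",
            class = "qpcreff_format_error")
    }
    long <- raw
  } else {
    if (ncol(raw) < 3) {
      abort("Wide layout requires a primer column plus >= 2 dilution columns.",
            class = "qpcreff_input_error")
    }
    lev <- suppressWarnings(as.numeric(names(raw)[-1]))
    if (anyNA(lev)) {
      abort("Wide layout column names must be numeric dilution levels.",
            class = "qpcreff_format_error")
    }
    long <- tidyr::pivot_longer(raw, -1, names_to = "dilution", values_to = "ct")
    names(long)[1] <- "primer"
    long$dilution <- as.numeric(long$dilution)
    long$ct <- as.numeric(long$ct)
  }
  dilution_table(long, ct_cutoff = ct_cutoff)
}

#' Write a result report to CSV
#'
#' Writes any of the package's result tables (efficiency estimates,
#' reliability report, cluster assignment, selection trace, adjusted CT,
#' CoV comparison, or a dilution table itself) as a plain CSV with a stable
#' column order. Missing values are serialized as empty fields; numbers are
#' written with round-trip precision, so reading the file back reproduces the
#' values exactly.
#'
#' @param report A data frame result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  if (!is.data.frame(report)) abort("`report` must be a data frame.")
  out <- as_tibble(report)
  # list-columns (e.g. per-primer residual vectors) are not serialisable
  out <- out[, !vapply(out, is.list, logical(1)), drop = FALSE]
  # doubles are written with 17 significant digits so that reading the file
  # back reproduces them bit-exactly
  out <- mutate(out, dplyr::across(
    dplyr::where(is.double),
    function(v) ifelse(is.na(v), NA_character_,
                       formatC(v, digits = 17, format = "g"))
  ))
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read back a report written by [write_report()]
#'
#' @param path CSV path.
#' @return A tibble; empty fields become `NA`.
#' @export
read_report <- function(path) {
  # base read.csv: correctly rounded double parsing, so written reports
  # round-trip bit-exactly
  as_tibble(utils::read.csv(path, na.strings = c("", "NA"),
                            check.names = FALSE))
}
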