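#' Table of measurements from several methods
#'
#' A \code{method_table} holds one numeric column per measurement method and
#' one row per subject, after listwise deletion of rows with missing or
#' non-numeric cells in the selected columns. It is the input for the ICC
#' (which needs all k methods at once) and the source of method pairs for
#' the pairwise statistics.
#'
#' @param data A data.frame of numeric method columns (one per method).
#' @param subject_ids Optional vector of subject labels; defaults to row
#'   numbers of the retained rows.
#' @param n_dropped Number of rows removed during cleaning (recorded for
#'   reporting).
#'
#' @return An object of class \code{"method_table"} with elements
#'   \code{data} (data.frame), \code{subject_ids}, \code{n},
#'   \code{methods} (column names) and \code{n_dropped}.
#' @export
method_table <- function(data, subject_ids = NULL, n_dropped = 0L) {
  data <- as.data.frame(data)
  if (ncol(data) < 1L) stop("a method_table needs at least one column")
  nm <- names(data)
  if (any(!nzchar(nm)) || anyNA(nm)) stop("method names must be non-empty")
  if (anyDuplicated(nm)) {
    stop("duplicate method names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  for (j in nm) {
    data[[j]] <- as.numeric(data[[j]])
    if (!all(is.finite(data[[j]]))) {
      stop("column '", j, "' contains non-finite values after cleaning")
    }
  }
  if (nrow(data) < 1L) stop("no complete rows remain")
  if (is.null(subject_ids)) subject_ids <- seq_len(nrow(data))
  if (length(subject_ids) != nrow(data)) {
    stop("subject_ids length must equal the number of rows")
  }
  structure(
    list(data = data, subject_ids = subject_ids, n = nrow(data),
         methods = nm, n_dropped = as.integer(n_dropped)),
    class = "method_table"
  )
}

#' Read a method table from CSV, TSV or XLSX
#'
#' Reads tabular measurement data (one column per method, one row per
#' subject). The dialect is inferred from the file extension. Rows with a
#' missing or non-numeric cell in any selected column are dropped listwise
#' and the count is recorded in the returned object. Numbers must use the
#' \code{.} decimal separator; values such as \code{"3,14"} are treated as
#' non-numeric and an error is raised if a selected column parses to
#' nothing but missing values.
#'
#' @param path Path to a \code{.csv}, \code{.tsv}/\code{.txt} (tab) or
#'   \code{.xlsx} file.
#' @param columns Optional character vector naming the columns to keep (in
#'   order); defaults to every numeric-parsable column.
#' @param sheet For xlsx input, sheet name or index (default first sheet).
#'
#' @return A [method_table()].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("bw,h4", "3000,2950", "3200,3180", "2800,2760"), f)
#' tab <- read_method_table(f)
#' tab$n
#' @export
read_method_table <- function(path, columns = NULL, sheet = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    csv = utils::read.csv(path, check.names = FALSE,
                          stringsAsFactors = FALSE, colClasses = "character"),
    tsv = ,
    txt = utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE, colClasses = "character"),
    xlsx = ,
    xls = as.data.frame(readxl::read_excel(path, sheet = sheet,
                                           col_types = "text")),
    stop("unknown file extension '.", ext,
         "': expected .csv, .tsv, .txt or .xlsx")
  )
  if (anyDuplicated(names(raw))) {
    stop("duplicate column names in ", path, ": ",
         paste(unique(names(raw)[duplicated(names(raw))]), collapse = ", "))
  }
  if (!is.null(columns)) {
    missing_cols <- setdiff(columns, names(raw))
    if (length(missing_cols)) {
      stop("requested column(s) not present: ",
           paste(missing_cols, collapse = ", "))
    }
    raw <- raw[, columns, drop = FALSE]
  }
  parsed <- lapply(raw, parse_numeric_column)
  if (is.null(columns)) {
    # keep only columns that are numeric for at least one row
    keep <- vapply(parsed, function(v) any(is.finite(v)), logical(1))
    if (!any(keep)) stop("no numeric columns found in ", path)
    parsed <- parsed[keep]
  } else {
    dead <- names(parsed)[!vapply(parsed, function(v) any(is.finite(v)),
                                  logical(1))]
    if (length(dead)) {
      stop("column(s) contain no parsable numbers (is the decimal ",
           "separator '.'?): ", paste(dead, collapse = ", "))
    }
  }
  mat <- as.data.frame(parsed, check.names = FALSE)
  complete <- stats::complete.cases(mat)
  method_table(mat[complete, , drop = FALSE],
               subject_ids = which(complete),
               n_dropped = sum(!complete))
}

parse_numeric_column <- function(v) {
  v <- trimws(as.character(v))
  v[v == ""] <- NA_character_
  # reject locale decimal commas rather than silently misreading them
  suppressWarnings(out <- as.numeric(v))
  out[!is.finite(out)] <- NA_real_
  out
}

#' @export
print.method_table <- function(x, ...) {
  cat("Method table:", x$n, "subjects x", length(x$methods), "methods\n")
  cat("  methods:", paste(x$methods, collapse = ", "), "\n")
  if (x$n_dropped > 0) {
    cat("  rows dropped (incomplete):", x$n_dropped, "\n")
  }
  invisible(x)
}

#' Extract one method pair from a method table
#'
#' @param table A [method_table()].
#' @param reference Column name of the reference method.
#' @param test Column name of the test method.
#' @param unit_label Optional unit label passed through.
#' @return A [paired_measurements()] object.
#' @export
method_pair <- function(table, reference, test, unit_label = "") {
  stopifnot(inherits(table, "method_table"))
  for (col in c(reference, test)) {
    if (!col %in% table$methods) stop("no such method column: ", col)
  }
  if (identical(reference, test)) {
    stop("reference and test must be different columns")
  }
  paired_measurements(table$data[[reference]], table$data[[test]],
                      unit_label = unit_label)
}
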