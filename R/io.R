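# File I/O: the tool-database CSV and report writers.

#' Read a tool-database CSV
#'
#' Expected header: `study_id, diagnosis, tool, tp, fp, fn, tn` with an
#' optional `cost_usd` column; cells non-negative numbers. A missing
#' required column is a schema error. A malformed row (non-numeric or
#' negative cell) is collected as a row-level error with its file line
#' number and dropped; the remaining rows are returned.
#'
#' @param path Path to a UTF-8 CSV file with a header.
#' @return Data.frame of valid rows, with attribute `"row_errors"` (a
#'   character vector, empty when all rows parsed).
#' @export
read_tool_db <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  db <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- c("study_id", "diagnosis", "tool", "tp", "fp", "fn", "tn")
  missing_cols <- setdiff(required, names(db))
  if (length(missing_cols)) {
    stop("schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  errors <- character(0)
  keep <- logical(nrow(db))
  cells <- c("tp", "fp", "fn", "tn")
  if ("cost_usd" %in% names(db)) cells <- c(cells, "cost_usd")
  num <- lapply(cells, function(col) suppressWarnings(as.numeric(db[[col]])))
  names(num) <- cells
  for (i in seq_len(nrow(db))) {
    line <- i + 1  # header is line 1
    vals <- vapply(c("tp", "fp", "fn", "tn"), function(c) num[[c]][i],
                   numeric(1))
    if (any(is.na(vals))) {
      errors <- c(errors, sprintf("line %d: non-numeric cell", line))
    } else if (any(vals < 0)) {
      errors <- c(errors, sprintf("line %d: negative cell", line))
    } else {
      keep[i] <- TRUE
    }
  }
  out <- db[keep, , drop = FALSE]
  for (col in cells) out[[col]] <- num[[col]][keep]
  out$line <- which(keep) + 1
  rownames(out) <- NULL
  attr(out, "row_errors") <- errors
  out
}

#' Write an evaluated database as CSV or JSON
#'
#' One record per tool with all classical rates and entropy fields; JSON
#' carries full precision, CSV writes plain numbers.
#'
#' @param evaluation A `tool_evaluation` from [evaluate_database()].
#' @param path Output path, or `""` for standard output.
#' @param format `"csv"` or `"json"`.
#' @export
write_evaluation <- function(evaluation, path = "", format = c("json", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(evaluation, "tool_evaluation"))
  if (format == "csv") {
    if (identical(path, "")) {
      utils::write.csv(evaluation$records, stdout(), row.names = FALSE)
    } else {
      utils::write.csv(evaluation$records, path, row.names = FALSE)
    }
  } else {
    txt <- jsonlite::toJSON(evaluation$records, dataframe = "rows",
                            auto_unbox = TRUE, digits = NA, pretty = TRUE,
                            na = "null")
    if (identical(path, "")) cat(txt, "\n") else writeLines(txt, path)
  }
  invisible(path)
}
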