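#' Construct a 2x2 diagnostic confusion table
#'
#' Bundles the four cells of a diagnostic 2x2 table (test result vs disease
#' state) together with its margins. Cells may be real-valued, so tables
#' derived from printed rates (proportional tables) are representable without
#' rounding; integer inputs are preserved exactly.
#'
#' @param tp,fp,fn,tn Non-negative cell counts: true positives, false
#'   positives, false negatives, true negatives. Real values are allowed.
#' @return An object of class `confusion_table`: a list with the four cells
#'   and the derived margins `n` (total), `n_positive` (`tp + fp`),
#'   `n_negative` (`fn + tn`), `n_diseased` (`tp + fn`) and `n_healthy`
#'   (`fp + tn`).
#' @examples
#' confusion_table(tp = 40, fp = 10, fn = 10, tn = 40)
#' @export
confusion_table <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (!all(is.finite(cells))) {
    stop("all four cells must be finite numbers", call. = FALSE)
  }
  if (any(cells < 0)) {
    stop("confusion table cells must be non-negative", call. = FALSE)
  }
  n <- sum(cells)
  if (n <= 0) {
    stop("empty confusion table: total count must be positive", call. = FALSE)
  }
  structure(
    list(
      tp = tp, fp = fp, fn = fn, tn = tn,
      n = n,
      n_positive = tp + fp,
      n_negative = fn + tn,
      n_diseased = tp + fn,
      n_healthy  = fp + tn
    ),
    class = "confusion_table"
  )
}

#' @export
print.confusion_table <- function(x, ...) {
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), nrow = 2, byrow = TRUE,
              dimnames = list(c("test+", "test-"), c("diseased", "healthy")))
  cat("2x2 diagnostic table (n =", format(x$n), ")\n")
  print(m)
  invisible(x)
}

as_confusion_table <- function(x) {
  if (inherits(x, "confusion_table")) return(x)
  if (is.list(x) || is.numeric(x)) {
    x <- as.list(x)
    if (all(c("tp", "fp", "fn", "tn") %in% names(x))) {
      return(confusion_table(x$tp, x$fp, x$fn, x$tn))
    }
  }
  stop("cannot interpret input as a confusion table", call. = FALSE)
}
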