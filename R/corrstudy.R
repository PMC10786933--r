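# Batch evaluation of a tool database and correlation of classical
# diagnostic metrics with entropy removal, with Fisher-z contrasts between
# correlation strengths.

CORR_METRICS <- c("sensitivity", "specificity", "ppv", "npv",
                  "log_dor", "youden")

#' Evaluate every tool in a database
#'
#' Computes classical metrics and the entropy report for each 2x2 row of a
#' tool database. Malformed rows (non-numeric or negative cells, zero
#' total) and rows with an all-zero margin are excluded with a reason
#' rather than aborting the batch.
#'
#' @param db Data.frame with columns `tp, fp, fn, tn` (identifier columns
#'   `study_id, diagnosis, tool` and `cost_usd` are carried through when
#'   present), e.g. from [read_tool_db()] or [random_tool_db()].
#' @return A list of class `tool_evaluation` with `records` (a data.frame
#'   of all metrics per usable row) and `excluded` (row index + reason).
#' @export
evaluate_database <- function(db) {
  stopifnot(is.data.frame(db))
  need <- c("tp", "fp", "fn", "tn")
  missing_cols <- setdiff(need, names(db))
  if (length(missing_cols)) {
    stop("database is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(db) == 0) stop("database has no rows", call. = FALSE)

  records <- vector("list", nrow(db))
  excluded <- list()
  for (i in seq_len(nrow(db))) {
    cells <- suppressWarnings(as.numeric(db[i, need]))
    reason <- NULL
    if (any(is.na(cells))) reason <- "non-numeric cell"
    else if (any(cells < 0)) reason <- "negative cell"
    else if (sum(cells) == 0) reason <- "empty table (n = 0)"
    else {
      t <- confusion_table(cells[1], cells[2], cells[3], cells[4])
      if (t$n_positive == 0 || t$n_negative == 0 ||
          t$n_diseased == 0 || t$n_healthy == 0) {
        reason <- "all-zero margin"
      }
    }
    if (!is.null(reason)) {
      excluded[[length(excluded) + 1]] <- data.frame(row = i, reason = reason)
      next
    }
    r <- classical_metrics(t)
    e <- entropy_removal(t)
    records[[i]] <- data.frame(
      row = i,
      study_id = if ("study_id" %in% names(db)) db$study_id[i] else NA,
      diagnosis = if ("diagnosis" %in% names(db)) db$diagnosis[i] else NA,
      tool = if ("tool" %in% names(db)) db$tool[i] else NA,
      tp = cells[1], fp = cells[2], fn = cells[3], tn = cells[4],
      sensitivity = r$sensitivity, specificity = r$specificity,
      ppv = r$ppv, npv = r$npv, prevalence = r$prevalence,
      youden = r$youden, dor = r$dor, log_dor = r$log_dor,
      dor_corrected = r$dor_corrected,
      parent_entropy = e$parent_entropy,
      removal_bits = e$removal_bits,
      removal_percent = e$removal_percent,
      cost_usd = if ("cost_usd" %in% names(db))
        suppressWarnings(as.numeric(db$cost_usd[i])) else NA_real_,
      stringsAsFactors = FALSE
    )
    if (!is.na(records[[i]]$cost_usd) && records[[i]]$cost_usd > 0) {
      records[[i]]$removal_percent_per_usd <-
        cost_efficiency(e$removal_percent, records[[i]]$cost_usd)
    } else {
      records[[i]]$removal_percent_per_usd <- NA_real_
    }
  }
  structure(
    list(
      records = do.call(rbind, records[!vapply(records, is.null, logical(1))]),
      excluded = if (length(excluded)) do.call(rbind, excluded)
                 else data.frame(row = integer(0), reason = character(0))
    ),
    class = "tool_evaluation"
  )
}

#' @export
print.tool_evaluation <- function(x, ...) {
  cat(sprintf("Evaluated %d tools (%d excluded)\n",
              nrow(x$records), nrow(x$excluded)))
  invisible(x)
}

#' Pearson product-moment correlation with p-value
#'
#' Thin wrapper over [stats::cor.test()] returning `(r, p, n)`; pairs with
#' a non-finite member are dropped, and zero variance in either variable
#' yields an `NA` correlation flag instead of an error.
#'
#' @param x,y Numeric vectors of equal length (>= 3 usable pairs).
#' @return List with `r` (or `rho`), `p`, `n`.
#' @export
pearson_cor <- function(x, y) {
  cor_guard(x, y, function(x, y) {
    ct <- stats::cor.test(x, y, method = "pearson")
    list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
  }, flag = c("r", "p"))
}

#' Spearman rank correlation with p-value
#'
#' Pearson correlation of mid-ranks (average ranks for ties); the p-value
#' uses the t approximation (via [stats::cor.test()] with ties present).
#'
#' @inheritParams pearson_cor
#' @return List with `rho`, `p`, `n`.
#' @export
spearman_cor <- function(x, y) {
  cor_guard(x, y, function(x, y) {
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
  }, flag = c("rho", "p"))
}

cor_guard <- function(x, y, f, flag) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) {
    stop("need at least 3 finite pairs", call. = FALSE)
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    out <- stats::setNames(as.list(c(NA_real_, NA_real_)), flag)
    out$n <- length(x)
    return(out)
  }
  f(x, y)
}

#' Compare two independent correlation coefficients (Fisher z)
#'
#' Transforms each correlation with Fisher's z (`atanh`) and compares
#' \deqn{z = \frac{z_1 - z_2}{\sqrt{1/(n_1-3) + 1/(n_2-3)}}}
#' with a two-sided normal p-value. Antisymmetric: swapping the arguments
#' negates `z`.
#'
#' @param r1,r2 Correlations, strictly inside (-1, 1).
#' @param n1,n2 Sample sizes (> 3).
#' @return List with `z` and `p`.
#' @export
compare_correlations <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1) {
    stop("Fisher transform is infinite at |r| = 1", call. = FALSE)
  }
  if (n1 <= 3 || n2 <= 3) stop("need n > 3 in both samples", call. = FALSE)
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Compare two dependent correlations sharing a variable (Steiger)
#'
#' Steiger's test for `cor(x1, y)` vs `cor(x2, y)` measured on the same
#' sample of size `n`, accounting for the correlation `r12` between the
#' two competing variables. The appropriate test when several metrics are
#' each correlated against the same entropy-removal column.
#'
#' @param r1y,r2y Correlations of each variable with the shared variable.
#' @param r12 Correlation between the two competing variables.
#' @param n Common sample size (> 3).
#' @return List with `z` and `p`.
#' @export
compare_correlations_dependent <- function(r1y, r2y, r12, n) {
  if (abs(r1y) >= 1 || abs(r2y) >= 1) {
    stop("Fisher transform is infinite at |r| = 1", call. = FALSE)
  }
  if (n <= 3) stop("need n > 3", call. = FALSE)
  rbar2 <- ((r1y + r2y) / 2)^2
  f <- (1 - r12) / (2 * (1 - rbar2))
  if (f > 1) f <- 1
  h <- (1 - f * rbar2) / (1 - rbar2)
  z <- (atanh(r1y) - atanh(r2y)) * sqrt((n - 3) / (2 * (1 - r12) * h))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Correlate classical metrics with entropy removal across a database
#'
#' Evaluates every tool, then correlates each classical metric
#' (sensitivity, specificity, PPV, NPV, base-10 logged diagnostic odds
#' ratio, Youden's index) with the percent entropy removal, by Pearson and
#' Spearman, and contrasts every pair of metrics' Pearson correlations by
#' Fisher z. Rows where a metric is undefined are dropped pairwise for
#' that metric only, with the per-metric `n` reported.
#'
#' @param db Tool database data.frame (see [evaluate_database()]), or a
#'   `tool_evaluation` object.
#' @param dependent If `TRUE`, the pairwise contrasts use Steiger's
#'   dependent-correlation test (the correlations share the
#'   entropy-removal variable); default `FALSE` uses the
#'   independent-samples Fisher z.
#' @param plots_dir Optional directory: writes one scatterplot (metric vs
#'   entropy removal) per metric, as PDF, when `ggplot2` is available.
#' @return An object of class `correlation_report`: `metrics` (data.frame
#'   with `pearson_r, pearson_p, spearman_rho, spearman_p, n` per metric),
#'   `z_comparisons` (pairwise contrasts), `n_tools`, `n_excluded`,
#'   `dependent`.
#' @export
run_study <- function(db, dependent = FALSE, plots_dir = NULL) {
  ev <- if (inherits(db, "tool_evaluation")) db else evaluate_database(db)
  rec <- ev$records
  if (is.null(rec) || nrow(rec) < 3) {
    stop("insufficient data: need at least 3 usable tools", call. = FALSE)
  }
  y <- rec$removal_percent

  met <- lapply(CORR_METRICS, function(m) {
    x <- rec[[m]]
    pe <- pearson_cor(x, y)
    sp <- spearman_cor(x, y)
    data.frame(metric = m,
               pearson_r = pe$r, pearson_p = pe$p,
               spearman_rho = sp$rho, spearman_p = sp$p,
               n = pe$n, stringsAsFactors = FALSE)
  })
  met <- do.call(rbind, met)

  pairs <- utils::combn(CORR_METRICS, 2)
  zcmp <- lapply(seq_len(ncol(pairs)), function(k) {
    m1 <- pairs[1, k]; m2 <- pairs[2, k]
    i1 <- match(m1, met$metric); i2 <- match(m2, met$metric)
    r1 <- met$pearson_r[i1]; r2 <- met$pearson_r[i2]
    if (is.na(r1) || is.na(r2)) {
      return(data.frame(metric1 = m1, metric2 = m2,
                        z = NA_real_, p = NA_real_))
    }
    cmp <- if (dependent) {
      ok <- is.finite(rec[[m1]]) & is.finite(rec[[m2]]) & is.finite(y)
      r12 <- stats::cor(rec[[m1]][ok], rec[[m2]][ok])
      compare_correlations_dependent(r1, r2, r12, sum(ok))
    } else {
      compare_correlations(r1, met$n[i1], r2, met$n[i2])
    }
    data.frame(metric1 = m1, metric2 = m2, z = cmp$z, p = cmp$p,
               stringsAsFactors = FALSE)
  })
  zcmp <- do.call(rbind, zcmp)

  if (!is.null(plots_dir)) write_study_plots(rec, plots_dir)

  structure(
    list(metrics = met, z_comparisons = zcmp,
         n_tools = nrow(rec), n_excluded = nrow(ev$excluded),
         dependent = dependent),
    class = "correlation_report"
  )
}

write_study_plots <- function(rec, dir) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    warning("ggplot2 not available; skipping plots", call. = FALSE)
    return(invisible())
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (m in CORR_METRICS) {
    df <- data.frame(metric_value = rec[[m]],
                     removal_percent = rec$removal_percent)
    p <- ggplot2::ggplot(df,
                         ggplot2::aes(x = metric_value,
                                      y = removal_percent)) +
      ggplot2::geom_point(alpha = 0.5) +
      ggplot2::labs(x = m, y = "entropy removal (%)")
    ggplot2::ggsave(file.path(dir, paste0("removal_vs_", m, ".pdf")),
                    p, width = 5, height = 4)
  }
  invisible()
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("Correlation study: %d tools (%d excluded); %s contrasts\n",
              x$n_tools, x$n_excluded,
              if (x$dependent) "dependent (Steiger)" else "Fisher z"))
  m <- x$metrics
  for (i in seq_len(nrow(m))) {
    cat(sprintf("  %-12s Pearson r = %6.3f  Spearman rho = %6.3f  (n = %d)\n",
                m$metric[i], m$pearson_r[i], m$spearman_rho[i], m$n[i]))
  }
  invisible(x)
}

report_to_list <- function(x) {
  list(
    n_tools = x$n_tools,
    n_excluded = x$n_excluded,
    dependent = x$dependent,
    metrics = x$metrics,
    z_comparisons = x$z_comparisons
  )
}
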