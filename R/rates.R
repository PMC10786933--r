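# Classical diagnostic accuracy metrics and the algebra linking rates,
# predictive values, prevalence and 2x2 counts.

#' Classical diagnostic metrics of a 2x2 table
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, predictive values
#' `ppv = tp/(tp+fp)`, `npv = tn/(tn+fn)`, prevalence `(tp+fn)/n`, Youden's
#' index (sensitivity + specificity - 1) and the diagnostic odds ratio
#' `DOR = (tp*tn)/(fp*fn)`. A rate with a zero denominator is returned as
#' `NA` rather than raising an error. When any cell is zero the DOR is
#' computed after adding 0.5 to all four cells (Haldane-Anscombe
#' continuity correction) and flagged via `dor_corrected`; this keeps the
#' logged DOR finite for correlation analyses. `log_dor` is the base-10
#' logarithm of the DOR.
#'
#' @inheritParams parent_entropy
#' @return An object of class `rate_set`: a list with `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `prevalence`, `youden`, `dor`, `log_dor`
#'   and the logical `dor_corrected`.
#' @examples
#' classical_metrics(confusion_table(40, 10, 10, 40))
#' @export
classical_metrics <- function(t) {
  t <- as_confusion_table(t)
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- rate(t$tp, t$n_diseased)
  spec <- rate(t$tn, t$n_healthy)
  ppv  <- rate(t$tp, t$n_positive)
  npv  <- rate(t$tn, t$n_negative)
  prev <- t$n_diseased / t$n

  youden <- if (is.na(sens) || is.na(spec)) NA_real_ else sens + spec - 1

  cells <- c(t$tp, t$fp, t$fn, t$tn)
  corrected <- any(cells == 0)
  cc <- if (corrected) cells + 0.5 else cells
  dor <- (cc[1] * cc[4]) / (cc[2] * cc[3])

  structure(
    list(
      sensitivity = sens, specificity = spec,
      ppv = ppv, npv = npv,
      prevalence = prev,
      youden = youden,
      dor = dor, log_dor = log10(dor),
      dor_corrected = corrected
    ),
    class = "rate_set"
  )
}

#' @export
print.rate_set <- function(x, ...) {
  pct <- function(v) if (is.na(v)) "undefined" else sprintf("%.2f%%", 100 * v)
  cat("Sensitivity:", pct(x$sensitivity),
      " Specificity:", pct(x$specificity), "\n")
  cat("PPV:", pct(x$ppv), " NPV:", pct(x$npv),
      " Prevalence:", pct(x$prevalence), "\n")
  cat(sprintf("Youden's index: %s  DOR: %s%s (log10 %s)\n",
              ifelse(is.na(x$youden), "undefined", sprintf("%.4f", x$youden)),
              sprintf("%.4g", x$dor),
              if (isTRUE(x$dor_corrected)) " [continuity-corrected]" else "",
              sprintf("%.4g", x$log_dor)))
  invisible(x)
}

#' Infer prevalence from sensitivity, specificity and PPV
#'
#' Closed-form inversion of
#' \eqn{PPV = \frac{sens \cdot p}{sens \cdot p + (1-spec)(1-p)}}:
#' \deqn{p = \frac{PPV (1 - spec)}{PPV (1 - spec) + sens (1 - PPV)}}
#' Needed to rebuild a 2x2 table when a study reports only rates.
#'
#' @param sens,spec Sensitivity and specificity, in `[0, 1]`.
#' @param ppv Positive predictive value, in `(0, 1]`.
#' @return The prevalence `p` in `[0, 1]`.
#' @export
prevalence_from_ppv <- function(sens, spec, ppv) {
  check_proportion(sens, "sens"); check_proportion(spec, "spec")
  if (!is.finite(ppv) || ppv <= 0 || ppv > 1) {
    stop("ppv must lie in (0, 1]", call. = FALSE)
  }
  if (spec == 1 && ppv < 1) {
    stop("inconsistent inputs: specificity 1 forces PPV = 1", call. = FALSE)
  }
  den <- ppv * (1 - spec) + sens * (1 - ppv)
  if (den <= 0) {
    stop("no solution: prevalence unidentifiable from this PPV", call. = FALSE)
  }
  ppv * (1 - spec) / den
}

#' Infer prevalence from sensitivity, specificity and NPV
#'
#' Closed-form inversion of the negative-predictive-value formula:
#' \deqn{p = \frac{spec (1 - NPV)}{spec (1 - NPV) + NPV (1 - sens)}}
#'
#' @inheritParams prevalence_from_ppv
#' @param npv Negative predictive value, in `(0, 1]`.
#' @return The prevalence `p` in `[0, 1]`.
#' @export
prevalence_from_npv <- function(sens, spec, npv) {
  check_proportion(sens, "sens"); check_proportion(spec, "spec")
  if (!is.finite(npv) || npv <= 0 || npv > 1) {
    stop("npv must lie in (0, 1]", call. = FALSE)
  }
  if (sens == 1 && npv < 1) {
    stop("inconsistent inputs: sensitivity 1 forces NPV = 1", call. = FALSE)
  }
  den <- spec * (1 - npv) + npv * (1 - sens)
  if (den <= 0) {
    stop("no solution: prevalence unidentifiable from this NPV", call. = FALSE)
  }
  spec * (1 - npv) / den
}

check_proportion <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < 0 || x > 1) {
    stop(name, " must be a proportion in [0, 1]", call. = FALSE)
  }
}

#' Build a (proportional) 2x2 table from rates
#'
#' Inverse of the table-to-rates mapping: `tp = n*sens*p`,
#' `fn = n*(1-sens)*p`, `tn = n*spec*(1-p)`, `fp = n*(1-spec)*(1-p)`.
#' Cells are real-valued; with `n = 1` the table is the joint probability
#' distribution itself. Round-trips with [classical_metrics()].
#'
#' @inheritParams prevalence_from_ppv
#' @param prevalence Disease prevalence, in `[0, 1]`.
#' @param n Total sample size (any positive real; default 1).
#' @return A [confusion_table()].
#' @export
table_from_rates <- function(sens, spec, prevalence, n = 1) {
  check_proportion(sens, "sens"); check_proportion(spec, "spec")
  check_proportion(prevalence, "prevalence")
  if (!is.finite(n) || n <= 0) stop("n must be positive", call. = FALSE)
  confusion_table(
    tp = n * sens * prevalence,
    fp = n * (1 - spec) * (1 - prevalence),
    fn = n * (1 - sens) * prevalence,
    tn = n * spec * (1 - prevalence)
  )
}

#' Rebuild a 2x2 table from printed study rates
#'
#' Reconstructs a proportional 2x2 table from sensitivity, specificity and
#' whichever of prevalence, PPV or NPV is available — the situation when a
#' study prints rates but not raw counts. Prevalence, when supplied, wins;
#' otherwise it is inferred from PPV unless specificity is 1 (which makes
#' PPV degenerate at 1, carrying no prevalence information), in which case
#' NPV is used. If both predictive values are supplied, the unused one is
#' recomputed from the inferred prevalence and a warning is emitted when it
#' disagrees with the supplied value by more than one percentage point.
#'
#' @inheritParams table_from_rates
#' @param ppv,npv Optional predictive values in `(0, 1]`.
#' @param prevalence Optional known prevalence.
#' @return A [confusion_table()] with attribute `"prevalence"`.
#' @examples
#' # helical CT for aortic dissection, from printed rates
#' t <- rates_to_table(sens = 0.9764, spec = 0.9890, ppv = 0.9628)
#' entropy_removal(t)
#' @export
rates_to_table <- function(sens, spec, ppv = NULL, npv = NULL,
                           prevalence = NULL, n = 1) {
  if (is.null(prevalence)) {
    # printed rows sometimes transpose the predictive values: specificity 1
    # forces PPV = 1, so a row printing PPV < 1 with NPV = 1 can only be
    # read with the two values swapped
    if (!is.null(ppv) && !is.null(npv) && spec == 1 && ppv < 1 && npv == 1) {
      warning("specificity 1 forces PPV = 1; treating the supplied PPV ",
              "and NPV as transposed", call. = FALSE)
      tmp <- ppv; ppv <- npv; npv <- tmp
    }
    use_ppv <- !is.null(ppv) && spec < 1
    if (use_ppv) {
      prevalence <- prevalence_from_ppv(sens, spec, ppv)
      if (!is.null(npv)) {
        npv_implied <- spec * (1 - prevalence) /
          (spec * (1 - prevalence) + (1 - sens) * prevalence)
        if (abs(npv_implied - npv) > 0.01) {
          warning(sprintf(
            "supplied NPV (%.4f) differs from NPV implied by PPV-derived prevalence (%.4f)",
            npv, npv_implied), call. = FALSE)
        }
      }
    } else if (!is.null(npv)) {
      prevalence <- prevalence_from_npv(sens, spec, npv)
      if (!is.null(ppv) && spec < 1) {
        ppv_implied <- sens * prevalence /
          (sens * prevalence + (1 - spec) * (1 - prevalence))
        if (abs(ppv_implied - ppv) > 0.01) {
          warning(sprintf(
            "supplied PPV (%.4f) differs from PPV implied by NPV-derived prevalence (%.4f)",
            ppv, ppv_implied), call. = FALSE)
        }
      }
    } else {
      stop("need prevalence, or a usable PPV or NPV, to rebuild the table",
           call. = FALSE)
    }
  }
  t <- table_from_rates(sens, spec, prevalence, n)
  attr(t, "prevalence") <- prevalence
  t
}
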