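# Shannon entropy of the disease-state distribution before and after a test,
# and the entropy removed by conditioning on the test result (the mutual
# information between test result and disease state).

# 0 * log2(0) := 0, the limiting value as p -> 0+; applied to every term.
xlog2x <- function(p) ifelse(p > 0, p * log2(p), 0)

#' Shannon entropy of a discrete distribution
#'
#' \eqn{H = -\sum_i p_i \log_2 p_i} in bits, with a term taken as zero when
#' \eqn{p_i = 0}. Maximal (1 bit for a binary event) at the uniform
#' distribution and zero when the outcome is certain.
#'
#' @param probs Numeric vector of outcome probabilities; each in `[0, 1]`,
#'   summing to 1 (tolerance `1e-9`).
#' @return Entropy in bits.
#' @examples
#' shannon_entropy(c(0.5, 0.5))  # 1 bit
#' shannon_entropy(c(1, 0))      # 0 bits
#' @export
shannon_entropy <- function(probs) {
  if (!is.numeric(probs) || length(probs) == 0 || !all(is.finite(probs))) {
    stop("invalid probability distribution: need finite numeric probabilities",
         call. = FALSE)
  }
  if (any(probs < 0) || any(probs > 1)) {
    stop("invalid probability distribution: probabilities must lie in [0, 1]",
         call. = FALSE)
  }
  if (abs(sum(probs) - 1) > 1e-9) {
    stop("invalid probability distribution: probabilities must sum to 1",
         call. = FALSE)
  }
  -sum(xlog2x(probs))
}

#' Pre-test (parent node) entropy of a diagnostic table
#'
#' Entropy of the disease prior in the decision-tree representation of a 2x2
#' table, computed in the log-difference form
#' \deqn{\frac{FP+TN}{N}(\log_2 N - \log_2(FP+TN)) +
#'       \frac{TP+FN}{N}(\log_2 N - \log_2(TP+FN))}
#' which equals `shannon_entropy()` of the prevalence distribution.
#'
#' @param t A [confusion_table()] (or anything coercible to one).
#' @return Entropy in bits of the pre-test disease distribution.
#' @export
parent_entropy <- function(t) {
  t <- as_confusion_table(t)
  branch_term(t$n_healthy, t$n) + branch_term(t$n_diseased, t$n)
}

# count/total * (log2(total) - log2(count)), zero when count is zero
branch_term <- function(count, total) {
  if (count <= 0 || total <= 0) return(0)
  (count / total) * (log2(total) - log2(count))
}

#' Post-test (child node) entropies of a diagnostic table
#'
#' Entropy of the disease distribution within the test-positive branch
#' (`tp` vs `fp` over `n_positive`) and the test-negative branch (`fn` vs
#' `tn` over `n_negative`). A branch with zero weight has entropy 0 by
#' convention.
#'
#' @inheritParams parent_entropy
#' @return Named numeric vector `c(positive = , negative = )`, in bits.
#' @export
child_entropies <- function(t) {
  t <- as_confusion_table(t)
  pos <- branch_term(t$tp, t$n_positive) + branch_term(t$fp, t$n_positive)
  neg <- branch_term(t$fn, t$n_negative) + branch_term(t$tn, t$n_negative)
  c(positive = pos, negative = neg)
}

#' Entropy removed by a diagnostic test
#'
#' The reduction in Shannon entropy of the disease-state distribution
#' achieved by conditioning on the test result: the pre-test (parent)
#' entropy minus the weighted average of the two post-test (child)
#' entropies, with weights `n_positive/n` and `n_negative/n`. This equals
#' the mutual information between test result and disease state. Also
#' reported as a percentage of the pre-test entropy (0 when the pre-test
#' entropy is 0).
#'
#' @inheritParams parent_entropy
#' @return An object of class `entropy_report`: a list with
#'   `parent_entropy`, `child_entropy_positive`, `child_entropy_negative`,
#'   `removal_bits` and `removal_percent`.
#' @examples
#' entropy_removal(confusion_table(40, 10, 10, 40))  # 0.278 bits, 27.81%
#' entropy_removal(confusion_table(50, 0, 0, 50))    # perfect test: 100%
#' @export
entropy_removal <- function(t) {
  t <- as_confusion_table(t)
  parent <- parent_entropy(t)
  kids <- child_entropies(t)
  weighted_child <- (t$n_positive / t$n) * kids[["positive"]] +
    (t$n_negative / t$n) * kids[["negative"]]
  bits <- parent - weighted_child
  # mutual information is non-negative; absorb float cancellation only
  if (bits < 0 && bits > -1e-12) bits <- 0
  pct <- if (parent > 0) 100 * bits / parent else 0
  structure(
    list(
      parent_entropy = parent,
      child_entropy_positive = kids[["positive"]],
      child_entropy_negative = kids[["negative"]],
      removal_bits = bits,
      removal_percent = pct
    ),
    class = "entropy_report"
  )
}

#' @export
print.entropy_report <- function(x, ...) {
  cat(sprintf("Pre-test entropy:    %.6f bits\n", x$parent_entropy))
  cat(sprintf("Post-test entropy:   %.6f (test+) / %.6f (test-) bits\n",
              x$child_entropy_positive, x$child_entropy_negative))
  cat(sprintf("Entropy removal:     %.6f bits (%.2f%%)\n",
              x$removal_bits, x$removal_percent))
  invisible(x)
}

#' Entropy removed per unit cost
#'
#' Cost-efficiency of a diagnostic test: percent of pre-test entropy removed
#' per currency unit (for example, percent per US dollar when `cost` is a
#' Medicare fee in USD).
#'
#' @param removal_percent Percent of pre-test entropy removed, as from
#'   [entropy_removal()].
#' @param cost Positive cost of the test in any fixed currency unit.
#' @return `removal_percent / cost`.
#' @export
cost_efficiency <- function(removal_percent, cost) {
  if (!is.numeric(cost) || length(cost) != 1 || !is.finite(cost) || cost <= 0) {
    stop("invalid cost: must be a single positive number", call. = FALSE)
  }
  removal_percent / cost
}
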