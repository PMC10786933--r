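# Independent oracles used across the suite.

# absolute-difference assertion (expect_equal's tolerance is relative,
# which is the wrong scale for quantities that can sit near zero)
expect_within <- function(actual, expected, tol, label = NULL) {
  expect_lt(max(abs(actual - expected)), tol, label = label)
}

# Brute-force mutual information of the 2x2 joint distribution, in bits.
# Deliberately independent of the package's parent/child entropy route.
mi_oracle <- function(tp, fp, fn, tn) {
  joint <- matrix(c(tp, fp, fn, tn), nrow = 2, byrow = TRUE) /
    (tp + fp + fn + tn)
  pr <- rowSums(joint)  # test result margin
  pc <- colSums(joint)  # disease margin
  s <- 0
  for (i in 1:2) for (j in 1:2) {
    if (joint[i, j] > 0) {
      s <- s + joint[i, j] * log2(joint[i, j] / (pr[i] * pc[j]))
    }
  }
  s
}

# Random non-empty tables with counts across several orders of magnitude.
random_tables <- function(n, seed) {
  set.seed(seed)
  out <- vector("list", n)
  i <- 0
  while (i < n) {
    cells <- stats::rpois(4, lambda = sample(c(2, 20, 200, 2000), 4,
                                             replace = TRUE))
    if (sum(cells) == 0) next
    i <- i + 1
    out[[i]] <- cells
  }
  out
}

# Full-factorial 3-feature spec with well-separated per-stratum outcome
# rates; the generating rule is f1 OR f2 OR f3 (in that hierarchy).
threefeat_spec <- function(per_stratum = 625) {
  strata <- list()
  for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
    rate <- if (a == 1) 0.92 else if (b == 1) 0.80 else if (cc == 1) 0.70
            else 0.05
    strata[[length(strata) + 1]] <- list(
      pattern = c(f1 = a, f2 = b, f3 = cc),
      count = per_stratum,
      positives = round(per_stratum * rate))
  }
  algorithm_spec("threefeat", c("f1", "f2", "f3"), strata)
}

threefeat_rule <- function(d) ifelse(d$f1 == 1 | d$f2 == 1 | d$f3 == 1, 1, 0)

write_fixture_db <- function(path, extra_rows = NULL) {
  rows <- c(
    "study_id,diagnosis,tool,tp,fp,fn,tn",
    "s1,pneumothorax,chest_us,40,10,10,40",
    "s2,pneumothorax,cxr,30,5,25,45",
    "s3,dissection,ct,48,2,2,48",
    extra_rows
  )
  writeLines(rows, path)
  path
}
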