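two_stratum_spec <- function() {
  algorithm_spec(
    "toy", "f1",
    list(list(pattern = c(f1 = 1), count = 50, positives = 40),
         list(pattern = c(f1 = 0), count = 50, positives = 10)))
}

test_that("spec validation enforces pattern and count invariants", {
  expect_error(algorithm_spec("x", "f1", list()), "empty spec")
  expect_error(
    algorithm_spec("x", c("f1", "f2"),
                   list(list(pattern = c(f1 = 1), count = 5, positives = 1))),
    "every feature")
  expect_error(
    algorithm_spec("x", "f1",
                   list(list(pattern = c(f1 = 1), count = 5, positives = 6))),
    "positives")
  expect_error(
    algorithm_spec("x", "f1",
                   list(list(pattern = c(f1 = 1), count = 5, positives = 1),
                        list(pattern = c(f1 = 1), count = 3, positives = 0))),
    "mutually exclusive")
})

test_that("deterministic cohorts reproduce spec counts exactly", {
  one <- algorithm_spec(
    "pure", "f1",
    list(list(pattern = c(f1 = 1), count = 10, positives = 10)))
  co <- generate_cohort(one, "deterministic", seed = 1)
  expect_equal(nrow(co), 10)
  expect_true(all(co$f1 == 1))
  expect_true(all(co$outcome == 1))

  co2 <- generate_cohort(two_stratum_spec(), "deterministic", seed = 9)
  tab <- table(factor(co2$f1, c(1, 0)), factor(co2$outcome, c(1, 0)))
  expect_equal(as.vector(tab), c(40, 10, 10, 40))  # tp, fn, fp, tn
  # cross-check with the metrics module
  r <- entropy_removal(confusion_table(tp = 40, fp = 10, fn = 10, tn = 40))
  expect_equal(r$removal_bits, 0.278072, tolerance = 1e-6)
})

test_that("cohort generation is seed-reproducible and seed-sensitive", {
  spec <- two_stratum_spec()
  a <- generate_cohort(spec, "sampled", seed = 7)
  b <- generate_cohort(spec, "sampled", seed = 7)
  expect_identical(a, b)
  # byte-identical CSV under the same seed
  f1 <- tempfile(); f2 <- tempfile()
  utils::write.csv(a, f1, row.names = FALSE)
  utils::write.csv(b, f2, row.names = FALSE)
  expect_identical(readLines(f1), readLines(f2))
  d <- generate_cohort(spec, "sampled", seed = 8)
  expect_false(identical(a$outcome, d$outcome) &&
                 identical(a$f1, d$f1))
  # row order is shuffled, not stratum blocks
  expect_gt(length(rle(generate_cohort(spec, "deterministic",
                                       seed = 3)$f1)$lengths), 4)
})

test_that("sampled-mode stratum positives are calibrated Binomial draws", {
  spec <- algorithm_spec(
    "cal", "f1",
    list(list(pattern = c(f1 = 1), count = 50, positives = 20)))
  pos <- vapply(1:300, function(s) {
    sum(generate_cohort(spec, "sampled", seed = s)$outcome)
  }, numeric(1))
  breaks <- c(-1, 14:25, 51)
  obs <- as.vector(table(cut(pos, breaks)))
  expected_p <- diff(stats::pbinom(breaks, 50, 0.4))
  gof <- suppressWarnings(stats::chisq.test(obs, p = expected_p))
  expect_gt(gof$p.value, 0.01)
})

test_that("bootstrap resampling is seeded and preserves proportions", {
  spec <- two_stratum_spec()
  co <- generate_cohort(spec, "deterministic", seed = 2)
  one_rec <- co[1, , drop = FALSE]
  attr(one_rec, "spec_name") <- "single"
  boot1 <- bootstrap_resample(one_rec, 5, seed = 3)
  expect_equal(nrow(boot1), 5)
  expect_true(all(boot1$f1 == one_rec$f1[1]))
  expect_match(attr(boot1, "spec_name"), ":bootstrap$")
  expect_identical(bootstrap_resample(co, 30, seed = 4),
                   bootstrap_resample(co, 30, seed = 4))

  # mean f1 proportion across seeded resamples within 3 SE of the source
  props <- vapply(1:200, function(s) {
    mean(bootstrap_resample(co, 100, seed = s)$f1)
  }, numeric(1))
  se <- sqrt(0.5 * 0.5 / 100) / sqrt(200)
  expect_lt(abs(mean(props) - 0.5), 3 * se)

  expect_error(bootstrap_resample(co[0, ], 10, seed = 1), "empty")
})

test_that("builtin specs mirror the named rules and drive tree fits", {
  sbs <- builtin_spec("step_by_step")
  expect_equal(sbs$features[1], "ill_appearing")
  p2 <- builtin_spec("pecarn_under2")
  expect_true("altered_mental_status" %in% p2$features)
  expect_match(p2$metadata$counts, "illustrative")
  expect_error(builtin_spec("nope"), "step_by_step")

  # placeholder rates make the headline feature dominate the fit
  tr <- fit_tree(generate_cohort(p2, "deterministic", seed = 5))
  expect_equal(tr$root$feature, "altered_mental_status")
  expect_equal(names(which.max(feature_importances(tr))),
               "altered_mental_status")
})

test_that("spec JSON round-trips", {
  spec <- builtin_spec("pecarn_2_and_over")
  path <- tempfile(fileext = ".json")
  write_spec_json(spec, path)
  spec2 <- read_spec_json(path)
  expect_equal(spec2$features, spec$features)
  expect_equal(spec2$strata, spec$strata)
  expect_identical(generate_cohort(spec, "deterministic", seed = 1),
                   structure(generate_cohort(spec2, "deterministic", seed = 1),
                             spec_name = spec$name))
})

test_that("generate -> fit -> importances is deterministic end to end", {
  spec <- threefeat_spec(100)
  fi1 <- feature_importances(fit_tree(generate_cohort(spec, "sampled",
                                                      seed = 12)))
  fi2 <- feature_importances(fit_tree(generate_cohort(spec, "sampled",
                                                      seed = 12)))
  expect_identical(fi1, fi2)
})

test_that("random tool databases have no degenerate margins", {
  db <- random_tool_db(100, seed = 6)
  expect_equal(nrow(db), 100)
  expect_true(all(db$tp + db$fp > 0))
  expect_true(all(db$fn + db$tn > 0))
  expect_true(all(db$tp + db$fn > 0))
  expect_true(all(db$fp + db$tn > 0))
  expect_identical(db, random_tool_db(100, seed = 6))
})
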