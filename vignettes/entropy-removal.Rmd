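---
title: "Entropy removal as a meta-metric for diagnostic tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy removal as a meta-metric for diagnostic tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diagentropy)
```

## The model

A diagnostic test applied to a population is a one-split decision tree.
The parent node is the untested population, whose uncertainty is the
Shannon entropy of the disease prior,

$$H = -\sum_i p_i \log_2 p_i \quad \text{(bits)},$$

with $p \log_2 p := 0$ at $p = 0$ (the limiting value). The two child
nodes are the test-positive subpopulation (TP true positives against FP
false positives) and the test-negative one (FN against TN). **Entropy
removal** is the parent entropy minus the weighted mean of the child
entropies, the weights being the fractions of positive and negative
tests:

$$\Delta H \;=\; H_\text{parent} - \tfrac{n_+}{N} H_\text{child}^{+} -
\tfrac{n_-}{N} H_\text{child}^{-}.$$

This quantity is exactly the mutual information $I(\text{test};
\text{disease})$ of the 2×2 joint distribution — the package's test suite
checks the identity against a brute-force mutual-information computation
to $10^{-12}$ bits on a thousand random tables. Consequences we rely on:
$0 \le \Delta H \le \min(H_\text{parent}, H_\text{test margin})$, and
$\Delta H$ is invariant to multiplying all four cells by any positive
constant, so tables built from rates (cells that are probabilities rather
than counts) are treated identically to count tables.

We report removal both in bits and as a percentage of the parent entropy
— the pre-test uncertainty is "all the entropy there is" about the
diagnosis, so the percentage reads as *the share of diagnostic
uncertainty the test eliminates*. When the parent entropy is zero
(degenerate prior) the percentage is defined as 0: there was nothing to
remove.

```{r}
entropy_removal(confusion_table(40, 10, 10, 40))
```

## Rebuilding tables from printed rates

Many studies print sensitivity, specificity and predictive values but not
raw counts. Sensitivity and specificity alone do not fix the table — the
prevalence is missing — but either predictive value pins it down in
closed form; `prevalence_from_ppv()` and `prevalence_from_npv()` invert
the standard Bayes relations, and `rates_to_table()` assembles the
proportional table

$$tp = s\,p,\quad fn = (1-s)\,p,\quad tn = c\,(1-p),\quad fp = (1-c)(1-p).$$

Two degenerate branches need care. When specificity is 1, the forward
formula forces PPV = 1 regardless of prevalence, so PPV carries no
prevalence information and NPV must be used (symmetrically for
sensitivity 1 and NPV). When both predictive values are supplied we infer
prevalence from PPV, recompute the other value, and warn if it disagrees
by more than one percentage point — printed rates are rounded to two
decimals, so a larger gap signals an inconsistent row rather than
rounding. One published pattern is handled explicitly: a row printing
specificity = 100% together with PPV < 100% and NPV = 100% is arithmetically
impossible except as a transposition of the two predictive values, and
`rates_to_table()` swaps them with a warning. Reconstruction from
two-decimal rates reproduces printed removal percentages to within about
half a percentage point, which is the tolerance the acceptance tests use.

## The decision-tree inducer

`fit_tree()` grows a binary tree on 0/1 features by greedy information
gain: at each node the feature whose split removes the most label entropy
is chosen, and growth stops on purity, exhausted features, non-positive
gain, or the optional `max_depth` / `min_samples` limits. Impurity is
Shannon entropy in bits throughout — the same currency as the 2×2
analysis, so a depth-1 tree on a test-vs-disease dataset reproduces
`entropy_removal()` of the corresponding table exactly. Gini impurity is
deliberately not offered.

Importance accounting follows the standard weighted-decrease scheme with
node weights normalised so the root has weight 1 (the weight of a node is
the probability of reaching it):

$$ni_j = w_j C_j - w_{left(j)} C_{left(j)} - w_{right(j)} C_{right(j)},
\qquad fi_i = \frac{\sum_{j \text{ splits on } i} ni_j}{\sum_k ni_k}.$$

Three identities tie the accounting together and are enforced in the
tests: $\sum_i fi_i = 1$ whenever a split occurred; $\sum_j ni_j$
telescopes to the root entropy minus the leaf-weighted entropy (the
tree's total removal); and $ni_j / w_j$ equals the entropy removal of the
2×2 table induced by the node's split — every internal node is itself a
"diagnostic test" for its subpopulation.

Determinism choices, since reproducibility matters more than any one
convention: equal-gain ties go to the earliest feature in column order,
and an exactly 50/50 leaf is labelled 0 (absence) — the conservative call
for outcomes coded "1 = condition present". Both totals are reported:
`total_removal_bits` (absolute) and `total_removal_percent` (share of
root entropy), labelled explicitly because summaries in the literature do
not always state which denominator a percentage uses. Accuracy is
training-set accuracy unless the caller holds data out; with
fully-binary features and no depth limit the fitted tree reaches the
per-stratum majority rule, so training accuracy equals the best
achievable under the generating noise.

## The synthetic cohort generator

Clinical decision-rule papers typically publish stratum counts — how many
patients triggered each rule feature and how many of those had the
outcome — rather than patient-level data. `algorithm_spec()` captures
exactly that: mutually exclusive feature patterns, each with a patient
count and a positive-outcome count. `generate_cohort()` reconstructs a
per-patient binary dataset from it in two modes:

- **deterministic** — the spec's counts are reproduced exactly (the mode
  to use when the counts *are* the data);
- **sampled** — stratum sizes stay fixed but each outcome is an
  independent Bernoulli draw at the stratum rate, which is the right
  model for studying estimator behaviour under sampling noise. A
  chi-square calibration test in the suite confirms the per-stratum
  positive counts are Binomial across seeds.

Row order is always shuffled under the caller's mandatory seed so nothing
downstream can silently rely on stratum blocks; the same seed yields a
byte-identical cohort. `bootstrap_resample()` draws uniformly with
replacement for resampling experiments.

What the generator emulates is the *stratified count structure* of
published cohorts — it does not model feature correlations beyond the
strata, covariate drift, missingness, or non-binary severity, so a tree
recovered perfectly from these cohorts shows the inducer works, not that
a rule will transport to new hospitals. The built-in templates
(`builtin_spec()`: Step-by-Step febrile infants, PECARN under-2 and
2-and-over head injury) carry the published rules' feature lists but
**illustrative placeholder counts**, chosen so the rule's known leading
feature (ill appearance; altered mental status) dominates; the source
studies' counts are not reproduced and the templates are flagged
accordingly in their metadata.

The recovery study used in the acceptance tests runs at 5,000 patients:
eight equal strata over three features with outcome rates 0.92 / 0.80 /
0.70 against a 0.05 floor. The rates are separated enough that the
expected information-gain ordering (f1, then f2 under f1 = 0, then f3) has
a comfortable margin at 625 patients per stratum, and the fitted tree's
predictions agree with the generating rule's Bayes-optimal labels on
99%+ of records across seeds.

## The correlation study

`run_study()` evaluates every tool in a database, then correlates each
classical metric with the percent entropy removal. Conventions:

- the diagnostic odds ratio is log₁₀-transformed before correlating (its
  relationship with removal is exponential; the base only rescales the
  variable, so it cannot change either correlation, but it is fixed and
  documented);
- a DOR with any zero cell gets the Haldane–Anscombe +0.5 correction and
  is flagged, keeping the logged value finite rather than dropping the
  row;
- rows where a metric is undefined are dropped pairwise for that metric
  only, with per-metric `n` reported;
- correlation strengths are contrasted with the independent-samples
  Fisher z by default. The correlations in fact share the removal
  variable, so Steiger's dependent test is available
  (`dependent = TRUE`); the independent contrast is kept as the default
  because it is the convention such comparisons usually follow, and the
  dependent option documents the statistical caveat.

On databases simulated by `random_tool_db()` (sizes 50–2000, prevalence
0.05–0.6, sensitivity and specificity 0.55–0.999, degenerate margins
rejected), the two composite metrics — Youden's index and logged DOR —
correlate with entropy removal far more strongly (Spearman ≈ 0.98) than
any single rate does (≤ 0.77), with Youden narrowly ahead of logged DOR
under this generator. Which of the two leads depends on the joint
distribution of prevalence and accuracy in the database, so the suite
asserts the robust ordering (composites ≫ simple rates), not a winner.

## Numerical choices and limitations

- All entropy terms use the $0 \log 0 = 0$ convention; a zero-weight
  branch has entropy 0.
- Removal in bits is clamped at 0 only against floating-point
  cancellation (magnitude < 1e-12); genuine negatives cannot occur.
- Real-valued cells are accepted throughout, so rate-derived tables never
  round; integer inputs stay exact.
- Problem sizes in the tests — 1000 random tables for the
  mutual-information identity, 5000 patients for tree recovery, 623 tools
  for the correlation study — were chosen as the smallest sizes at which
  each property is comfortably stable across seeds.
- Entropy removal is a population-level summary: it inherits the
  prevalence of the study that produced the table, and comparisons across
  tables at very different prevalences mix prevalence effects with
  accuracy effects. No confidence intervals are attached to removal
  (point values only); bootstrap machinery is available for callers who
  want them empirically.
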