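# Synthetic binary patient cohorts reconstructed from the stratum/outcome
# counts that clinical decision-rule papers publish, plus bootstrap
# resampling. Every feature is 0/1 ("0 for absence, 1 for presence") and
# the outcome is 0/1, so cohorts plug straight into fit_tree().

#' Describe a decision algorithm as stratified binary counts
#'
#' An algorithm specification lists the algorithm's binary features and a
#' set of mutually exclusive patient strata; each stratum fixes a value for
#' every feature and carries the number of patients in that stratum and how
#' many of them had a positive outcome. A per-patient binary dataset can
#' then be reconstructed exactly ([generate_cohort()]) — the stratified
#' count-reconstruction analogue of bootstrapping a published cohort.
#'
#' @param name Identifier for the algorithm.
#' @param features Character vector of binary feature names (unique).
#' @param strata List of strata; each a list with `pattern` (named 0/1
#'   vector or list covering every feature), `count` (patients in the
#'   stratum) and `positives` (patients with a positive outcome,
#'   `<= count`).
#' @param metadata Free-form provenance notes (list).
#' @return An object of class `algorithm_spec`.
#' @examples
#' spec <- algorithm_spec(
#'   "toy", "f1",
#'   list(list(pattern = c(f1 = 1), count = 50, positives = 40),
#'        list(pattern = c(f1 = 0), count = 50, positives = 10)))
#' @export
algorithm_spec <- function(name, features, strata, metadata = list()) {
  stopifnot(is.character(name), length(name) == 1)
  features <- as.character(features)
  if (length(features) == 0 || anyDuplicated(features)) {
    stop("features must be a non-empty set of unique names", call. = FALSE)
  }
  if (length(strata) == 0) stop("empty spec: need at least one stratum",
                                call. = FALSE)
  seen <- character(0)
  strata <- lapply(strata, function(s) {
    pat <- unlist(s$pattern)
    if (!setequal(names(pat), features)) {
      stop("each stratum pattern must assign a value to every feature",
           call. = FALSE)
    }
    pat <- pat[features]
    if (!all(pat %in% c(0, 1))) {
      stop("pattern values must be 0 or 1", call. = FALSE)
    }
    key <- paste(pat, collapse = "")
    if (key %in% seen) stop("strata patterns must be mutually exclusive",
                            call. = FALSE)
    seen <<- c(seen, key)
    count <- s$count; pos <- s$positives
    if (!is.finite(count) || count < 0 || count != round(count)) {
      stop("stratum count must be a non-negative integer", call. = FALSE)
    }
    if (!is.finite(pos) || pos < 0 || pos > count || pos != round(pos)) {
      stop("positives must be an integer in [0, count]", call. = FALSE)
    }
    list(pattern = pat, count = as.integer(count), positives = as.integer(pos))
  })
  structure(list(name = name, features = features, strata = strata,
                 metadata = metadata),
            class = "algorithm_spec")
}

#' @export
print.algorithm_spec <- function(x, ...) {
  n <- sum(vapply(x$strata, `[[`, integer(1), "count"))
  cat(sprintf("Algorithm spec '%s': %d features, %d strata, %d patients\n",
              x$name, length(x$features), length(x$strata), n))
  if (length(x$metadata)) {
    cat("Metadata:", paste(names(x$metadata), unlist(x$metadata),
                           sep = "=", collapse = "; "), "\n")
  }
  invisible(x)
}

#' Generate a binary patient cohort from an algorithm spec
#'
#' Reconstructs a per-patient dataset from the stratum counts. In
#' `deterministic` mode the cohort reproduces the spec's counts exactly:
#' each stratum contributes `count` records of which the first `positives`
#' are labeled 1. In `sampled` mode stratum sizes are kept fixed but each
#' record's outcome is an independent Bernoulli draw at the stratum's
#' outcome rate `positives/count`. Row order is always shuffled (seeded)
#' so downstream code cannot depend on stratum blocks; the same seed gives
#' an identical cohort.
#'
#' @param spec An [algorithm_spec()].
#' @param mode `"deterministic"` or `"sampled"`.
#' @param seed Integer seed (required; drives the shuffle and any draws).
#' @return A data.frame with one 0/1 column per feature plus `outcome`,
#'   carrying attributes `spec_name` and `seed`.
#' @export
generate_cohort <- function(spec, mode = c("deterministic", "sampled"),
                            seed) {
  stopifnot(inherits(spec, "algorithm_spec"))
  mode <- match.arg(mode)
  if (missing(seed) || !is.numeric(seed)) {
    stop("an integer seed is required", call. = FALSE)
  }
  total <- sum(vapply(spec$strata, `[[`, integer(1), "count"))
  if (total == 0) stop("spec has no patients", call. = FALSE)

  rows <- matrix(0, nrow = total, ncol = length(spec$features),
                 dimnames = list(NULL, spec$features))
  outcome <- integer(total)
  at <- 0
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  for (s in spec$strata) {
    if (s$count == 0) next
    idx <- at + seq_len(s$count)
    rows[idx, ] <- matrix(s$pattern, nrow = s$count, ncol = length(s$pattern),
                          byrow = TRUE)
    outcome[idx] <- if (mode == "deterministic") {
      rep(c(1L, 0L), c(s$positives, s$count - s$positives))
    } else {
      stats::rbinom(s$count, 1L, s$positives / s$count)
    }
    at <- at + s$count
  }
  perm <- sample.int(total)
  out <- as.data.frame(rows[perm, , drop = FALSE])
  out$outcome <- outcome[perm]
  rownames(out) <- NULL
  attr(out, "spec_name") <- spec$name
  attr(out, "seed") <- seed
  out
}

# run code under a fixed RNG seed without clobbering the caller's stream
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Bootstrap-resample a cohort
#'
#' Draws `n` records uniformly with replacement from an existing cohort.
#'
#' @param cohort A cohort data.frame (as from [generate_cohort()]).
#' @param n Number of records to draw.
#' @param seed Integer seed.
#' @return A cohort data.frame of `n` rows; `spec_name` is preserved with
#'   a `":bootstrap"` marker appended.
#' @export
bootstrap_resample <- function(cohort, n, seed) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0) {
    stop("empty cohort", call. = FALSE)
  }
  if (!is.numeric(n) || n <= 0) stop("n must be positive", call. = FALSE)
  if (missing(seed) || !is.numeric(seed)) {
    stop("an integer seed is required", call. = FALSE)
  }
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  idx <- sample.int(nrow(cohort), size = n, replace = TRUE)
  out <- cohort[idx, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "spec_name") <- paste0(attr(cohort, "spec_name") %||% "cohort",
                                   ":bootstrap")
  attr(out, "seed") <- seed
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Built-in decision-algorithm templates
#'
#' Structural templates mirroring the decision variables of well-known
#' pediatric clinical decision rules: the Step-by-Step approach to febrile
#' infants and the PECARN head-injury rules for children under 2 and 2 and
#' over. The feature lists follow the published rules; the stratum counts
#' are ILLUSTRATIVE placeholders (flagged in `metadata$counts`), chosen so
#' that the rule's known leading feature dominates — they are not the
#' source studies' patient counts, which these templates do not reproduce.
#'
#' Strata are decision-list style: each stratum corresponds to the first
#' rule feature the patient triggers (all earlier features absent), plus a
#' none-triggered stratum.
#'
#' @param name One of `"step_by_step"`, `"pecarn_under2"`,
#'   `"pecarn_2_and_over"`.
#' @return An [algorithm_spec()].
#' @examples
#' builtin_spec("pecarn_under2")
#' @export
builtin_spec <- function(name) {
  specs <- list(
    step_by_step = list(
      features = c("ill_appearing", "age_21_days_or_less", "leukocyturia",
                   "procalcitonin_high", "crp_or_anc_high"),
      # (count, positives) per triggered stratum; outcome = serious
      # bacterial infection
      counts = list(c(60, 38), c(70, 28), c(120, 42), c(90, 22),
                    c(160, 24), c(1500, 15))
    ),
    pecarn_under2 = list(
      features = c("altered_mental_status", "palpable_skull_fracture",
                   "loc_5s_or_more", "severe_mechanism",
                   "occipital_parietal_temporal_hematoma",
                   "not_acting_normally"),
      counts = list(c(90, 40), c(80, 26), c(110, 18), c(150, 14),
                    c(130, 10), c(120, 7), c(3000, 9))
    ),
    pecarn_2_and_over = list(
      features = c("altered_mental_status", "signs_of_basilar_skull_fracture",
                   "loc_history", "vomiting", "severe_mechanism",
                   "severe_headache"),
      counts = list(c(110, 52), c(70, 24), c(140, 20), c(180, 16),
                    c(160, 11), c(90, 5), c(3200, 10))
    )
  )
  if (!name %in% names(specs)) {
    stop("unknown spec '", name, "'; available: ",
         paste(names(specs), collapse = ", "), call. = FALSE)
  }
  tpl <- specs[[name]]
  k <- length(tpl$features)
  strata <- vector("list", k + 1)
  for (j in seq_len(k)) {
    pat <- stats::setNames(rep(0, k), tpl$features)
    pat[j] <- 1
    strata[[j]] <- list(pattern = pat, count = tpl$counts[[j]][1],
                        positives = tpl$counts[[j]][2])
  }
  strata[[k + 1]] <- list(pattern = stats::setNames(rep(0, k), tpl$features),
                          count = tpl$counts[[k + 1]][1],
                          positives = tpl$counts[[k + 1]][2])
  algorithm_spec(
    name, tpl$features, strata,
    metadata = list(
      counts = "illustrative placeholders, not source-study counts",
      structure = "decision-list strata: first triggered feature"
    )
  )
}

#' Read / write algorithm specs as JSON
#'
#' JSON form: `{name, features: [...], strata: [{pattern: {feature: 0|1},
#' count, positives}], metadata}`.
#'
#' @param path File path.
#' @return `read_spec_json()` returns an [algorithm_spec()].
#' @export
read_spec_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  strata <- lapply(obj$strata, function(s) {
    list(pattern = unlist(s$pattern), count = s$count,
         positives = s$positives)
  })
  algorithm_spec(obj$name, unlist(obj$features), strata,
                 metadata = obj$metadata %||% list())
}

#' @rdname read_spec_json
#' @param spec An [algorithm_spec()].
#' @export
write_spec_json <- function(spec, path) {
  obj <- list(
    name = spec$name,
    features = spec$features,
    strata = lapply(spec$strata, function(s) {
      list(pattern = as.list(s$pattern), count = s$count,
           positives = s$positives)
    }),
    metadata = spec$metadata
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Simulate a database of diagnostic tools
#'
#' Draws `n_tools` random 2x2 tables for exercising batch evaluation and
#' the correlation study without any external database. Per tool, a study
#' size, prevalence, sensitivity and specificity are drawn and the four
#' cells sampled from the corresponding multinomial; draws with an empty
#' margin (all-positive or all-negative tests, no diseased or no healthy
#' subjects) are rejected so every classical rate is defined.
#'
#' @param n_tools Number of tools (rows).
#' @param seed Integer seed.
#' @param size_range Study-size range (uniform integer draw).
#' @return A data.frame with columns `study_id, diagnosis, tool, tp, fp,
#'   fn, tn`.
#' @export
random_tool_db <- function(n_tools, seed, size_range = c(50, 2000)) {
  if (!is.numeric(n_tools) || n_tools < 1) {
    stop("n_tools must be at least 1", call. = FALSE)
  }
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  draw_row <- function() {
    repeat {
      n <- sample(size_range[1]:size_range[2], 1)
      prev <- stats::runif(1, 0.05, 0.6)
      sens <- stats::runif(1, 0.55, 0.999)
      spec <- stats::runif(1, 0.55, 0.999)
      p <- c(sens * prev, (1 - spec) * (1 - prev),
             (1 - sens) * prev, spec * (1 - prev))
      cells <- as.vector(stats::rmultinom(1, n, p))
      tp <- cells[1]; fp <- cells[2]; fn <- cells[3]; tn <- cells[4]
      if ((tp + fp) > 0 && (fn + tn) > 0 && (tp + fn) > 0 && (fp + tn) > 0) {
        return(c(tp, fp, fn, tn))
      }
    }
  }
  cells <- t(vapply(seq_len(n_tools), function(i) draw_row(), numeric(4)))
  data.frame(
    study_id = sprintf("study_%04d", seq_len(n_tools)),
    diagnosis = sprintf("dx_%03d", ((seq_len(n_tools) - 1) %% 267) + 1),
    tool = sprintf("tool_%04d", seq_len(n_tools)),
    tp = cells[, 1], fp = cells[, 2], fn = cells[, 3], tn = cells[, 4],
    stringsAsFactors = FALSE
  )
}
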