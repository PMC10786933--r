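# Entropy-criterion binary decision-tree induction over binary clinical
# features, with node importance ni_j = w_j C_j - w_l C_l - w_r C_r and
# feature importances fi_i = sum of ni over splits on i / sum of all ni.
# Node weights w are normalized so the root has weight 1 (probability of
# reaching the node); impurity C is Shannon entropy of the node's label
# distribution, in bits.

entropy_binary <- function(n1, n0) {
  n <- n1 + n0
  if (n == 0) return(0)
  branch_term(n1, n) + branch_term(n0, n)
}

#' Fit an entropy-criterion binary decision tree
#'
#' Greedy top-down induction on a dataset of binary (0/1) features and a
#' binary outcome. At each node the feature maximizing information gain —
#' the decrease in Shannon entropy of the label distribution, weighted by
#' the split proportions — is chosen; induction stops when a node is pure,
#' no features remain, the best gain is not positive, or an optional depth
#' or minimum-size limit is hit. Left child takes feature value 0, right
#' child value 1. Ties in gain go to the earliest feature in column order,
#' and a leaf whose labels split exactly 50/50 is labeled 0 (absence), so
#' fitting is deterministic for a fixed input.
#'
#' @param data A data.frame whose feature columns contain only 0/1 and
#'   which has a 0/1 outcome column.
#' @param outcome Name of the outcome column (default `"outcome"`).
#' @param max_depth Optional maximum tree depth (`Inf` = unlimited).
#' @param min_samples Minimum number of records a node must hold to be
#'   split (default 1, i.e. no constraint beyond purity/gain).
#' @return An object of class `dx_tree`: a list with `root` (nested node
#'   list with fields `feature`, `w`, `impurity`, `importance`, `n_records`,
#'   `children` or `leaf_label`), `feature_importances` (named vector
#'   summing to 1 whenever any split occurred), `total_removal_bits`,
#'   `total_removal_percent`, `feature_names` and `n`.
#' @examples
#' d <- data.frame(f1 = c(1, 1, 0, 0), outcome = c(1, 1, 0, 0))
#' fit_tree(d)
#' @export
fit_tree <- function(data, outcome = "outcome", max_depth = Inf,
                     min_samples = 1) {
  if (!is.data.frame(data) || nrow(data) == 0) {
    stop("empty dataset: need at least one record", call. = FALSE)
  }
  if (!outcome %in% names(data)) {
    stop("outcome column '", outcome, "' not found", call. = FALSE)
  }
  features <- setdiff(names(data), outcome)
  if (length(features) == 0) stop("need at least one feature", call. = FALSE)
  x <- as.matrix(data[features])
  y <- data[[outcome]]
  if (!all(x %in% c(0, 1)) || !all(y %in% c(0, 1))) {
    stop("all feature and outcome values must be 0 or 1", call. = FALSE)
  }
  storage.mode(x) <- "double"

  n_root <- nrow(x)
  root <- grow_node(x, y, features, depth = 0, n_root = n_root,
                    max_depth = max_depth, min_samples = min_samples)
  fi <- collect_feature_importances(root, features)
  total_ni <- sum_node_importances(root)
  parent_bits <- root$impurity
  structure(
    list(
      root = root,
      feature_importances = fi,
      total_removal_bits = total_ni,
      total_removal_percent = if (parent_bits > 0) 100 * total_ni / parent_bits else 0,
      feature_names = features,
      n = n_root
    ),
    class = "dx_tree"
  )
}

grow_node <- function(x, y, features, depth, n_root, max_depth, min_samples) {
  n <- length(y)
  n1 <- sum(y)
  imp <- entropy_binary(n1, n - n1)
  node <- list(
    w = n / n_root,
    n_records = n,
    impurity = imp,
    feature = NULL,
    importance = NULL,
    children = NULL,
    leaf_label = NULL
  )

  make_leaf <- function(node) {
    # majority label; exact tie -> 0 (absence), the conservative call
    node$leaf_label <- if (n1 > n - n1) 1L else 0L
    node
  }

  if (imp == 0 || length(features) == 0 || depth >= max_depth ||
      n < min_samples) {
    return(make_leaf(node))
  }

  best_gain <- 0
  best_feat <- NULL
  for (f in features) {  # column order => deterministic tie-break
    right <- x[, f] == 1
    nr <- sum(right); nl <- n - nr
    if (nr == 0 || nl == 0) next
    imp_l <- entropy_binary(sum(y[!right]), nl - sum(y[!right]))
    imp_r <- entropy_binary(sum(y[right]),  nr - sum(y[right]))
    gain <- imp - (nl / n) * imp_l - (nr / n) * imp_r
    if (gain > best_gain + 1e-15) {
      best_gain <- gain
      best_feat <- f
    }
  }
  if (is.null(best_feat)) return(make_leaf(node))

  right <- x[, best_feat] == 1
  remaining <- setdiff(features, best_feat)
  left_child <- grow_node(x[!right, , drop = FALSE], y[!right], remaining,
                          depth + 1, n_root, max_depth, min_samples)
  right_child <- grow_node(x[right, , drop = FALSE], y[right], remaining,
                           depth + 1, n_root, max_depth, min_samples)
  node$feature <- best_feat
  node$children <- list(left = left_child, right = right_child)
  node$importance <- node$w * node$impurity -
    left_child$w * left_child$impurity -
    right_child$w * right_child$impurity
  node
}

collect_feature_importances <- function(root, features) {
  ni <- stats::setNames(numeric(length(features)), features)
  walk <- function(node) {
    if (is.null(node$children)) return(invisible())
    ni[node$feature] <<- ni[node$feature] + node$importance
    walk(node$children$left)
    walk(node$children$right)
  }
  walk(root)
  total <- sum(ni)
  if (total > 0) ni / total else ni
}

sum_node_importances <- function(node) {
  if (is.null(node$children)) return(0)
  node$importance +
    sum_node_importances(node$children$left) +
    sum_node_importances(node$children$right)
}

#' Importance of a single tree node
#'
#' \eqn{ni_j = w_j C_j - w_{left(j)} C_{left(j)} - w_{right(j)} C_{right(j)}}
#' with weights normalized so the root has weight 1. Equals the node's
#' entropy removal scaled by the probability of reaching it: `ni_j / w_j`
#' is [entropy_removal()] of the node's induced 2x2 table.
#'
#' @param node An internal node of a fitted [fit_tree()] tree.
#' @return The node importance, a non-negative number.
#' @export
node_importance <- function(node) {
  if (is.null(node$children)) {
    stop("node importance is undefined for a leaf", call. = FALSE)
  }
  node$w * node$impurity -
    node$children$left$w * node$children$left$impurity -
    node$children$right$w * node$children$right$impurity
}

#' Feature importances of a fitted tree
#'
#' \eqn{fi_i = \sum_{j\ splits\ on\ i} ni_j / \sum_k ni_k} over all internal
#' nodes. Features never split on get importance 0; the importances sum to
#' 1 whenever the tree made at least one split. A tree with no splits
#' returns an all-zero map.
#'
#' @param tree A fitted [fit_tree()] object.
#' @return Named numeric vector of importances, one per feature.
#' @export
feature_importances <- function(tree) {
  stopifnot(inherits(tree, "dx_tree"))
  tree$feature_importances
}

#' Predict outcomes from a fitted tree
#'
#' Routes each record down the tree by its feature values (left on 0,
#' right on 1) and returns the leaf label.
#'
#' @param object A fitted [fit_tree()] object.
#' @param newdata A data.frame supplying every feature on the followed
#'   root-to-leaf path.
#' @param ... Unused.
#' @return Integer vector of 0/1 predicted labels.
#' @export
predict.dx_tree <- function(object, newdata, ...) {
  if (!is.data.frame(newdata) || nrow(newdata) == 0) {
    stop("newdata must be a non-empty data.frame", call. = FALSE)
  }
  vapply(seq_len(nrow(newdata)), function(i) {
    node <- object$root
    while (is.null(node$leaf_label)) {
      f <- node$feature
      if (!f %in% names(newdata)) {
        stop("record is missing feature '", f, "'", call. = FALSE)
      }
      v <- newdata[[f]][i]
      if (is.na(v) || !v %in% c(0, 1)) {
        stop("feature '", f, "' must be 0 or 1", call. = FALSE)
      }
      node <- if (v == 1) node$children$right else node$children$left
    }
    node$leaf_label
  }, integer(1))
}

#' Prediction accuracy of a fitted tree on a dataset
#'
#' @inheritParams fit_tree
#' @param tree A fitted [fit_tree()] object.
#' @return Fraction of records whose predicted label matches the outcome.
#' @export
accuracy <- function(tree, data, outcome = "outcome") {
  if (!is.data.frame(data) || nrow(data) == 0) {
    stop("empty dataset", call. = FALSE)
  }
  mean(predict(tree, data) == data[[outcome]])
}

#' @export
print.dx_tree <- function(x, ...) {
  cat(sprintf("Entropy decision tree: %d records, %d features\n",
              x$n, length(x$feature_names)))
  cat(sprintf("Root entropy %.4f bits; removal %.4f bits (%.2f%%)\n",
              x$root$impurity, x$total_removal_bits, x$total_removal_percent))
  fi <- sort(x$feature_importances, decreasing = TRUE)
  fi <- fi[fi > 0]
  if (length(fi)) {
    cat("Feature importances:\n")
    for (f in names(fi)) cat(sprintf("  %-30s %.4f\n", f, fi[[f]]))
  } else {
    cat("No splits (root is a leaf).\n")
  }
  invisible(x)
}

# --- JSON serialization of fitted trees (CLI interchange format) ---------

node_to_list <- function(node) {
  out <- list(w = node$w, impurity_bits = node$impurity,
              n_records = node$n_records)
  if (is.null(node$children)) {
    out$leaf_label <- node$leaf_label
  } else {
    out$feature <- node$feature
    out$importance <- node$importance
    out$children <- list(left = node_to_list(node$children$left),
                         right = node_to_list(node$children$right))
  }
  out
}

#' Write a fitted tree to JSON
#'
#' Nested-node JSON with `feature, w, impurity_bits, importance,
#' children | leaf_label` per node and the feature-importance map at top
#' level. Read back with [read_tree_json()].
#'
#' @param tree A fitted [fit_tree()] object.
#' @param path Output file path.
#' @export
write_tree_json <- function(tree, path) {
  obj <- list(
    feature_names = tree$feature_names,
    n = tree$n,
    total_removal_bits = tree$total_removal_bits,
    total_removal_percent = tree$total_removal_percent,
    feature_importances = as.list(tree$feature_importances),
    root = node_to_list(tree$root)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

list_to_node <- function(lst) {
  node <- list(w = lst$w, n_records = lst$n_records,
               impurity = lst$impurity_bits,
               feature = NULL, importance = NULL,
               children = NULL, leaf_label = NULL)
  if (!is.null(lst$leaf_label)) {
    node$leaf_label <- as.integer(lst$leaf_label)
  } else {
    node$feature <- lst$feature
    node$importance <- lst$importance
    node$children <- list(left = list_to_node(lst$children$left),
                          right = list_to_node(lst$children$right))
  }
  node
}

#' Read a fitted tree from JSON
#'
#' @param path Path to a file written by [write_tree_json()].
#' @return A `dx_tree` object.
#' @export
read_tree_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  structure(
    list(
      root = list_to_node(obj$root),
      feature_importances = unlist(obj$feature_importances),
      total_removal_bits = obj$total_removal_bits,
      total_removal_percent = obj$total_removal_percent,
      feature_names = unlist(obj$feature_names),
      n = obj$n
    ),
    class = "dx_tree"
  )
}
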