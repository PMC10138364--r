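#' Gini impurity of a class-proportion vector
#'
#' `1 - sum(p_j^2)` over the class proportions of a node: 0 for a pure node
#' and maximal (approaching `1 - 1/c`) at uniform proportions.
#'
#' @param proportions Numeric vector of class proportions, each in
#'   \[0, 1\], summing to 1 (tolerance 1e-9).
#' @return Impurity value in \[0, 1).
#' @export
gini <- function(proportions) {
  p <- as.numeric(proportions)
  if (any(p < 0 | p > 1)) stop("proportions must lie in [0, 1]")
  if (abs(sum(p) - 1) > 1e-9) stop("proportions must sum to 1")
  1 - sum(p^2)
}

.gini_counts <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  1 - sum((counts / n)^2)
}

# majority class of a count vector with tie-break by class_priority
# (higher priority wins), then by order of appearance
.majority <- function(counts, class_priority) {
  mx <- max(counts)
  cand <- names(counts)[counts == mx]
  if (length(cand) > 1 && !is.null(class_priority)) {
    pr <- class_priority[cand]
    pr[is.na(pr)] <- -Inf
    cand <- cand[order(-pr)]
  }
  cand[1]
}

# Greedy binary CART-style learner with Gini split criterion and
# pre-pruning: depth cap and a minimum number of samples per leaf.
# Categorical columns split as one-hot equality tests (x == value),
# numeric columns on thresholds (x <= value). Deterministic: ties broken
# by column order, then candidate order.
fit_decision_tree <- function(x, y, max_depth = 3, min_samples = 6,
                              class_priority = NULL,
                              max_numeric_candidates = 64) {
  stopifnot(is.data.frame(x), nrow(x) == length(y))
  y <- as.character(y)
  classes <- unique(y)
  if (nrow(x) < min_samples) {
    stop("need at least min_samples (", min_samples, ") records, got ", nrow(x))
  }
  grow <- function(idx, depth) {
    counts <- table(factor(y[idx], levels = classes))
    node_gini <- .gini_counts(counts)
    leaf <- list(type = "leaf",
                 action = .majority(counts, class_priority),
                 counts = as.list(as.integer(counts)),
                 classes = classes)
    if (depth >= max_depth || node_gini == 0 ||
        length(idx) < 2 * min_samples) {
      return(leaf)
    }
    best <- NULL
    best_impurity <- node_gini - 1e-12
    n <- length(idx)
    for (col in names(x)) {
      v <- x[[col]][idx]
      if (is.numeric(v)) {
        u <- sort(unique(v))
        if (length(u) < 2) next
        thr <- (u[-1] + u[-length(u)]) / 2
        if (length(thr) > max_numeric_candidates) {
          thr <- unique(stats::quantile(v, probs = seq_len(max_numeric_candidates) /
                                          (max_numeric_candidates + 1),
                                        names = FALSE, type = 1))
        }
        for (t in thr) {
          left <- v <= t
          nl <- sum(left)
          if (nl < min_samples || n - nl < min_samples) next
          imp <- (nl * .gini_counts(table(factor(y[idx][left], levels = classes))) +
                  (n - nl) * .gini_counts(table(factor(y[idx][!left], levels = classes)))) / n
          if (imp < best_impurity - 1e-12) {
            best_impurity <- imp
            best <- list(variable = col, op = "le", value = t, left = left)
          }
        }
      } else {
        vals <- unique(as.character(v))
        for (val in vals) {
          left <- as.character(v) == val
          nl <- sum(left)
          if (nl < min_samples || n - nl < min_samples) next
          imp <- (nl * .gini_counts(table(factor(y[idx][left], levels = classes))) +
                  (n - nl) * .gini_counts(table(factor(y[idx][!left], levels = classes)))) / n
          if (imp < best_impurity - 1e-12) {
            best_impurity <- imp
            best <- list(variable = col, op = "eq", value = val, left = left)
          }
        }
      }
    }
    if (is.null(best)) return(leaf)
    list(type = "split",
         variable = best$variable, op = best$op, value = best$value,
         left = grow(idx[best$left], depth + 1),
         right = grow(idx[!best$left], depth + 1))
  }
  structure(list(root = grow(seq_len(nrow(x)), 0),
                 classes = classes,
                 max_depth = max_depth, min_samples = min_samples),
            class = "gini_tree")
}

.tree_route <- function(node, row, path = character(0)) {
  if (node$type == "leaf") {
    return(list(action = node$action, path = path, counts = node$counts))
  }
  v <- row[[node$variable]]
  go_left <- if (node$op == "le") {
    !is.na(v) && as.numeric(v) <= node$value
  } else {
    !is.na(v) && as.character(v) == node$value
  }
  branch <- if (go_left) node$left else node$right
  test <- sprintf("%s %s %s%s", node$variable,
                  if (node$op == "le") "<=" else "==",
                  node$value, if (go_left) "" else " [no]")
  .tree_route(branch, row, c(path, test))
}

# predict class labels for each row of a data.frame
predict_decision_tree <- function(tree, newdata) {
  stopifnot(inherits(tree, "gini_tree"))
  vapply(seq_len(nrow(newdata)), function(i) {
    .tree_route(tree$root, newdata[i, , drop = FALSE])$action
  }, character(1))
}

tree_depth <- function(node) {
  if (node$type == "leaf") return(0L)
  1L + max(tree_depth(node$left), tree_depth(node$right))
}

tree_leaf_supports <- function(node) {
  if (node$type == "leaf") return(sum(unlist(node$counts)))
  c(tree_leaf_supports(node$left), tree_leaf_supports(node$right))
}

#' Serialize a fitted Gini tree to JSON
#'
#' @param tree A fitted tree (from [fit_tree()] or [train_pose_model()]).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_tree_json <- function(tree, path) {
  stopifnot(inherits(tree, c("gini_tree", "care_tree", "pose_model")))
  jsonlite::write_json(unclass(tree), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a Gini tree from JSON
#'
#' @param path JSON path written by [write_tree_json()].
#' @param class S3 class to restore (default `"gini_tree"`).
#' @return The deserialized tree.
#' @export
read_tree_json <- function(path, class = "gini_tree") {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  obj$classes <- unlist(obj$classes)
  if (!is.null(obj$feature_names)) obj$feature_names <- unlist(obj$feature_names)
  structure(obj, class = class)
}
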