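#' Multiclass confusion matrix
#'
#' Rows are actual classes, columns predicted classes; the diagonal counts
#' correct predictions.
#'
#' @param actual,predicted Label vectors of equal length.
#' @param classes Class label order; defaults to the sorted union.
#' @return Integer matrix of class `confusion_matrix`.
#' @export
confusion <- function(actual, predicted, classes = NULL) {
  actual <- as.character(actual); predicted <- as.character(predicted)
  if (length(actual) != length(predicted)) {
    stop("actual and predicted must have equal length")
  }
  classes <- classes %||% sort(unique(c(actual, predicted)))
  unknown <- setdiff(unique(c(actual, predicted)), classes)
  if (length(unknown) > 0) {
    stop("unknown label(s): ", paste(unknown, collapse = ", "))
  }
  cm <- table(factor(actual, levels = classes),
              factor(predicted, levels = classes))
  cm <- matrix(as.integer(cm), nrow = length(classes),
               dimnames = list(actual = classes, predicted = classes))
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

#' Per-class precision, recall and F1 (one-vs-rest)
#'
#' `precision = diag / column sum`, `recall = diag / row sum`,
#' `F1 = 2PR / (P + R)`. An empty denominator yields 0 with the
#' `undefined` flag set for that class instead of an error.
#'
#' @param cm A [confusion()] matrix.
#' @return Data frame with columns `class`, `precision`, `recall`, `f1`,
#'   `undefined`.
#' @export
precision_recall_f1 <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  m <- unclass(cm)
  d <- diag(m)
  col_sum <- colSums(m)
  row_sum <- rowSums(m)
  precision <- ifelse(col_sum > 0, d / col_sum, 0)
  recall <- ifelse(row_sum > 0, d / row_sum, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  data.frame(class = rownames(m), precision = precision, recall = recall,
             f1 = f1,
             undefined = col_sum == 0 | row_sum == 0 | precision + recall == 0,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' F1 score from precision and recall
#'
#' Harmonic mean `2PR / (P + R)`; 0 when both are 0.
#'
#' @param precision,recall Numeric vectors in \[0, 1\].
#' @return F1 values.
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall > 0,
         2 * precision * recall / (precision + recall), 0)
}

#' Macro-averaged F1
#'
#' Unweighted mean of the per-class F1 scores: every class counts equally
#' regardless of its size.
#'
#' @param per_class_f1 Numeric vector of per-class F1 values.
#' @return Macro F1.
#' @export
macro_f1 <- function(per_class_f1) {
  if (length(per_class_f1) == 0) stop("need at least one per-class F1 value")
  mean(as.numeric(per_class_f1))
}

#' Weighted-averaged F1
#'
#' `sum(w_i * F1_i)` with `w_i = k_i / N`, the class share of the N
#' evaluated samples; larger classes weigh more. (The weights already sum
#' to one, so no further division by the number of classes is applied.)
#'
#' @param per_class_f1 Numeric vector of per-class F1 values.
#' @param class_counts Per-class sample counts `k_i`, aligned with
#'   `per_class_f1`.
#' @param n_total Total sample count `N`; defaults to `sum(class_counts)`
#'   and must equal it.
#' @return Weighted F1.
#' @export
weighted_f1 <- function(per_class_f1, class_counts, n_total = sum(class_counts)) {
  if (length(per_class_f1) != length(class_counts)) {
    stop("per_class_f1 and class_counts must have equal length")
  }
  if (sum(class_counts) != n_total) {
    stop("class counts must sum to n_total")
  }
  sum((class_counts / n_total) * as.numeric(per_class_f1))
}

# midrank AUC via the Mann-Whitney statistic
.auc_midrank <- function(pos_scores, neg_scores) {
  n1 <- length(pos_scores); n0 <- length(neg_scores)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(c(pos_scores, neg_scores), ties.method = "average")
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' One-vs-rest ROC AUC per class
#'
#' Trapezoidal AUC of the one-vs-rest ROC for each class, computed as the
#' midrank Mann-Whitney statistic (the two are equivalent, including tie
#' handling). A class lacking positives or negatives gets `NA` with the
#' `undefined` flag.
#'
#' @param actual Label vector.
#' @param scores Numeric matrix of per-class scores, columns named by
#'   class.
#' @return Data frame with columns `class`, `auc`, `undefined`.
#' @export
roc_auc_ovr <- function(actual, scores) {
  actual <- as.character(actual)
  stopifnot(is.matrix(scores) || is.data.frame(scores))
  scores <- as.matrix(scores)
  if (is.null(colnames(scores))) stop("scores must have class column names")
  if (nrow(scores) != length(actual)) {
    stop("scores must have one row per label")
  }
  if (any(!is.finite(scores))) stop("scores must be finite")
  res <- lapply(colnames(scores), function(cls) {
    pos <- actual == cls
    auc <- .auc_midrank(scores[pos, cls], scores[!pos, cls])
    data.frame(class = cls, auc = auc, undefined = is.na(auc),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Round half-up at a given number of decimals
#'
#' Reporting convention for comparisons against published 4-decimal
#' tables: metrics are computed at full precision and rounded half-up
#' only at report time (base `round()` rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded values.
#' @export
round_half_up <- function(x, digits = 4) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
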