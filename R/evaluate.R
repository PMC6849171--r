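# ---------------------------------------------------------------------------
# Evaluation: per-class and support-weighted precision / recall / F-measure
# from confusion matrices, chance-corrected agreement (Cohen's and weighted
# kappa), and cross-question summary statistics.
#
# Conventions: P = TP/(TP+FP), R = TP/(TP+FN); a 0/0 ratio is reported as 0
# and flagged degenerate; F = 0 when P + R = 0. Weighted averages use
# actual-class supports (confusion-matrix row sums). Summary statistics use
# the sample (n-1) standard deviation. Percentages are rounded half-up to
# one decimal for reporting.
# ---------------------------------------------------------------------------

#' Build a confusion matrix from actual and predicted labels
#'
#' @param actual,predicted vectors of equal length (coerced to character).
#' @param classes ordered class labels; defaults to the sorted union.
#' @return object of class `confusion_matrix`: a square integer matrix with
#'   actual labels in rows and predicted in columns.
#' @export
confusion_matrix <- function(actual, predicted, classes = NULL) {
  stopifnot(length(actual) == length(predicted))
  actual <- as.character(actual); predicted <- as.character(predicted)
  if (is.null(classes)) classes <- sort(unique(c(actual, predicted)))
  m <- table(factor(actual, levels = classes),
             factor(predicted, levels = classes))
  structure(unclass(as.matrix(m)), dimnames = list(actual = classes,
                                                   predicted = classes),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> (rows = actual, cols = predicted)\n")
  print(unclass(x))
  invisible(x)
}

.check_cm <- function(cm) {
  stopifnot(is.matrix(cm), nrow(cm) == ncol(cm))
  if (sum(cm) <= 0) stop("confusion matrix has no observations", call. = FALSE)
}

#' Harmonic mean of precision and recall
#'
#' @param p,r values in \[0, 1\].
#' @return `2pr/(p+r)`, or 0 when `p + r = 0`.
#' @export
f_measure <- function(p, r) {
  stopifnot(all(p >= 0 & p <= 1), all(r >= 0 & r <= 1))
  ifelse(p + r == 0, 0, 2 * p * r / (p + r))
}

#' Per-class precision, recall and F-measure
#'
#' @param cm a `confusion_matrix` (actual in rows, predicted in columns).
#' @return data frame with one row per class: `class`, `tp`, `fp`, `fn`,
#'   `support`, `precision`, `recall`, `f`, and a `degenerate` flag set when
#'   a 0/0 ratio was reported as 0.
#' @export
class_metrics <- function(cm) {
  .check_cm(cm)
  classes <- rownames(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  p <- ifelse(tp + fp == 0, 0, tp / (tp + fp))
  r <- ifelse(tp + fn == 0, 0, tp / (tp + fn))
  data.frame(class = classes, tp = as.numeric(tp), fp = as.numeric(fp),
             fn = as.numeric(fn), support = as.numeric(rowSums(cm)),
             precision = as.numeric(p), recall = as.numeric(r),
             f = as.numeric(f_measure(p, r)),
             degenerate = as.vector(tp + fp == 0 | tp + fn == 0),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Support-weighted precision, recall and F-measure
#'
#' Weighted averages of the per-class values, with weights equal to the
#' number of instances actually in each class (row sums). The weighted F is
#' the weighted mean of per-class F values (not the harmonic mean of the
#' weighted P and R).
#'
#' @param cm a `confusion_matrix`.
#' @return named numeric vector `c(precision, recall, f)`.
#' @export
weighted_metrics <- function(cm) {
  m <- class_metrics(cm)
  w <- m$support / sum(m$support)
  c(precision = sum(w * m$precision), recall = sum(w * m$recall),
    f = sum(w * m$f))
}

#' Cohen's kappa from an agreement table
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement `p_o` the
#' diagonal proportion and expected agreement `p_e` from the product of the
#' marginals. When `p_e = 1` (both raters constant and identical) kappa is
#' undefined and returned as `NA` with a warning.
#'
#' @param at square matrix of counts, rater 1 in rows, rater 2 in columns.
#' @return kappa in \[-1, 1\], or `NA` when undefined.
#' @export
cohen_kappa <- function(at) {
  .check_cm(at)
  n <- sum(at)
  po <- sum(diag(at)) / n
  pe <- sum(rowSums(at) * colSums(at)) / n^2
  if (abs(1 - pe) < .Machine$double.eps * 4) {
    warning("expected agreement is 1; kappa undefined")
    return(NA_real_)
  }
  (po - pe) / (1 - pe)
}

#' Agreement weight matrices for weighted kappa
#'
#' Agreement-weight convention: `w[i, i] = 1`, off-diagonal weights decay
#' with the class distance. Linear: `1 - |i - j| / (k - 1)`; quadratic:
#' `1 - (i - j)^2 / (k - 1)^2`.
#'
#' @param k number of classes.
#' @param scheme `"linear"`, `"quadratic"` or `"identity"`.
#' @return k x k symmetric weight matrix with unit diagonal.
#' @export
kappa_weights <- function(k, scheme = c("linear", "quadratic", "identity")) {
  scheme <- match.arg(scheme)
  d <- abs(outer(seq_len(k), seq_len(k), "-"))
  switch(scheme,
         identity = (d == 0) * 1,
         linear = 1 - d / (k - 1),
         quadratic = 1 - d^2 / (k - 1)^2)
}

#' Weighted kappa
#'
#' Discounts near-miss disagreements by an agreement-weight matrix `w`
#' (unit diagonal, symmetric). Computed in the disagreement form
#' `kappa_w = 1 - sum(w' * o) / sum(w' * e)` with `w' = 1 - w`, observed
#' proportions `o` and expected proportions `e` from the marginals. Identity
#' weights reduce to unweighted Cohen's kappa.
#'
#' @param at square agreement table (counts).
#' @param weights agreement-weight matrix, or a scheme name accepted by
#'   [kappa_weights()].
#' @return weighted kappa, or `NA` when undefined.
#' @export
weighted_kappa <- function(at, weights = "linear") {
  .check_cm(at)
  k <- nrow(at)
  if (is.character(weights)) weights <- kappa_weights(k, weights)
  stopifnot(is.matrix(weights), all(dim(weights) == dim(at)),
            all(abs(diag(weights) - 1) < 1e-12),
            isTRUE(all.equal(weights, t(weights))))
  n <- sum(at)
  o <- at / n
  e <- outer(rowSums(at), colSums(at)) / n^2
  wd <- 1 - weights
  denom <- sum(wd * e)
  if (denom < .Machine$double.eps * 4) {
    warning("expected disagreement is 0; weighted kappa undefined")
    return(NA_real_)
  }
  1 - sum(wd * o) / denom
}

#' Round half-up to a number of decimals
#'
#' Reporting convention for percentages (base R `round()` rounds half to
#' even).
#' @param x numeric vector.
#' @param digits decimals.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Summary statistics over per-question metric values
#'
#' @param values data frame with columns `question`, `precision`, `recall`,
#'   `f` (on any consistent scale, e.g. percentages).
#' @return object of class `summary_report`: list with the input table and
#'   a `stats` data frame (mean, sample sd, min, max per metric). With a
#'   single question the sd is `NA` (flagged undefined).
#' @export
summarize_questions <- function(values) {
  stopifnot(is.data.frame(values), nrow(values) >= 1,
            all(c("question", "precision", "recall", "f") %in% names(values)))
  one <- function(v) c(mean = mean(v),
                       sd = if (length(v) > 1) stats::sd(v) else NA_real_,
                       min = min(v), max = max(v))
  stats <- rbind(precision = one(values$precision),
                 recall = one(values$recall),
                 f = one(values$f))
  structure(list(values = values,
                 stats = as.data.frame(stats)),
            class = "summary_report")
}

#' @export
print.summary_report <- function(x, digits = 1, ...) {
  cat("<summary_report> over", nrow(x$values), "question(s)\n")
  print(round_half_up(as.matrix(x$stats), digits))
  invisible(x)
}
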