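#' Mann-Whitney U test
#'
#' Two-sample rank test used to decide whether the ISM scores of mutation-
#' and SNP-carrying sequences differ at a spectral frequency. Returns the
#' min-orientation U statistic together with a two-sided p-value: the exact
#' null distribution is used when both groups have at most 12 observations
#' and there are no ties; otherwise the normal approximation with tie
#' correction and continuity correction.
#'
#' @param group_a,group_b Non-empty numeric vectors.
#' @param exact `"auto"` (the rule above), `"exact"`, or `"approx"`.
#' @return List with `U` (min of the two orientations), `U_a` (number of
#'   (a, b) pairs with a > b, counting ties 1/2), `p` (two-sided), and
#'   `exact` (logical, which path was used).
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
mann_whitney_u <- function(group_a, group_b, exact = c("auto", "exact", "approx")) {
  exact <- match.arg(exact)
  if (!length(group_a) || !length(group_b)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  n_a <- length(group_a)
  n_b <- length(group_b)
  r <- rank(c(group_a, group_b))
  u_a <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  u_b <- n_a * n_b - u_a
  has_ties <- anyDuplicated(c(group_a, group_b)) > 0L
  use_exact <- switch(exact,
    auto = n_a <= 12L && n_b <= 12L && !has_ties,
    exact = TRUE,
    approx = FALSE)
  p <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, alternative = "two.sided",
                       exact = use_exact, correct = TRUE)$p.value)
  if (is.na(p)) p <- 1  # zero-variance rank configuration (all ties)
  list(U = min(u_a, u_b), U_a = u_a, p = p, exact = use_exact && !has_ties)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by summing hypergeometric probabilities no larger than
#' that of the observed table. A table with a zero margin carries no
#' information about association; it yields p = 1 with a warning.
#'
#' @param tab 2x2 matrix (or object coercible to one) of non-negative counts.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("tab must be 2x2", call. = FALSE)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("tab must hold non-negative integers", call. = FALSE)
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("zero margin in 2x2 table; p = 1", call. = FALSE)
    return(1)
  }
  stats::fisher.test(tab, alternative = "two.sided")$p.value
}

#' Confusion counts from predicted and true class labels
#'
#' @param predicted,truth Character vectors of class labels.
#' @param positive The positive class (default `"MUT"`: a deleterious call).
#' @return List with integer `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(predicted, truth, positive = "MUT") {
  if (length(predicted) != length(truth)) {
    stop("predicted and truth lengths differ", call. = FALSE)
  }
  pos_p <- predicted == positive
  pos_t <- truth == positive
  list(TP = sum(pos_p & pos_t), TN = sum(!pos_p & !pos_t),
       FP = sum(pos_p & !pos_t), FN = sum(!pos_p & pos_t))
}

#' Classification metrics from confusion counts
#'
#' Accuracy (TP+TN)/(TP+TN+FP+FN), precision TP/(TP+FP), sensitivity
#' TP/(TP+FN), specificity TN/(TN+FP) and negative predictive value
#' TN/(TN+FN). A metric whose denominator is zero is undefined and reported
#' as `NA`, never silently 0.
#'
#' @param TP,TN,FP,FN Non-negative integer counts, or a single list with
#'   those elements as `TP`.
#' @return Named numeric vector `accuracy`, `precision`, `sensitivity`,
#'   `specificity`, `npv` (NA where undefined).
#' @export
confusion_metrics <- function(TP, TN = NULL, FP = NULL, FN = NULL) {
  if (is.list(TP)) {
    c_ <- TP
    TP <- c_$TP; TN <- c_$TN; FP <- c_$FP; FN <- c_$FN
  }
  counts <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  if (anyNA(counts) || any(counts < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (sum(counts) == 0) stop("all counts are zero", call. = FALSE)
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  c(accuracy = (TP + TN) / sum(counts),
    precision = rate(TP, TP + FP),
    sensitivity = rate(TP, TP + FN),
    specificity = rate(TN, TN + FP),
    npv = rate(TN, TN + FN))
}

#' ROC curve and rank-based AUC
#'
#' The AUC is the rank (Mann-Whitney) estimator: the probability that a
#' randomly chosen positive scores above a randomly chosen negative, ties
#' counted one half. `roc_curve` enumerates all distinct score thresholds;
#' trapezoidal integration of that curve equals the rank estimator.
#'
#' @param scores Numeric scores, higher meaning more mutation-like.
#' @param labels Class labels; both classes must be present.
#' @param positive The positive class (default `"MUT"`).
#' @return `roc_auc`: the AUC in \[0, 1\]. `roc_curve`: data frame with
#'   `threshold`, `fpr`, `tpr`, ordered from (0, 0) to (1, 1).
#' @export
#' @examples
#' roc_auc(c(0.9, 0.8, 0.2, 0.1), c("MUT", "MUT", "SNP", "SNP"))  # 1
roc_auc <- function(scores, labels, positive = "MUT") {
  pos <- labels == positive
  n1 <- sum(pos)
  n2 <- sum(!pos)
  if (n1 == 0L || n2 == 0L) {
    stop("both classes must be present", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' @rdname roc_auc
#' @export
roc_curve <- function(scores, labels, positive = "MUT") {
  pos <- labels == positive
  if (!any(pos) || all(pos)) stop("both classes must be present", call. = FALSE)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1))
  data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Rescale an original SIFT score so that high means deleterious
#'
#' SIFT reports the probability that a substitution is tolerated, so low
#' original scores mean damaging. For comparison with scores oriented the
#' other way the original score is reflected: transformed = 1 - original.
#'
#' @param s Numeric score(s) in \[0, 1\].
#' @return `1 - s`.
#' @export
#' @examples
#' transform_sift_score(c(0.01, 0.88))  # 0.99, 0.12
transform_sift_score <- function(s) {
  if (any(s < 0 | s > 1, na.rm = TRUE)) {
    stop("SIFT score out of [0, 1]", call. = FALSE)
  }
  1 - s
}

#' Binarize a third-party predictor score
#'
#' Original (untransformed) SIFT scores below 0.05 are called mutations
#' (exactly 0.05 is a SNP: the cutoff is strict). PolyPhen-2 probabilistic
#' scores of 0.5 or more are called mutations (the boundary is inclusive on
#' the mutation side).
#'
#' @param score Numeric score(s) in \[0, 1\], on each tool's original scale.
#' @param tool `"SIFT"` or `"PolyPhen-2"`.
#' @return Character vector of `"MUT"` / `"SNP"` calls.
#' @export
binarize_external <- function(score, tool = c("SIFT", "PolyPhen-2")) {
  tool <- match.arg(tool)
  if (any(score < 0 | score > 1, na.rm = TRUE)) {
    stop(tool, " score out of [0, 1]", call. = FALSE)
  }
  if (tool == "SIFT") {
    ifelse(score < 0.05, "MUT", "SNP")
  } else {
    ifelse(score >= 0.5, "MUT", "SNP")
  }
}

#' Read a third-party predictor score table
#'
#' Delimited text with columns `gene`, `substitution`, `score`, `tool`.
#'
#' @param path Path to the table.
#' @return Data frame with those columns (`score` numeric in \[0, 1\]).
#' @export
read_external_scores <- function(path) {
  d <- read_delimited(path, c("gene", "substitution", "score", "tool"))
  d$score <- as.numeric(d$score)
  if (anyNA(d$score) || any(d$score < 0 | d$score > 1)) {
    stop("scores must be numeric in [0, 1]: ", path, call. = FALSE)
  }
  d$substitution <- parse_variant(d$substitution)$substitution
  d[, c("gene", "substitution", "score", "tool")]
}

#' Evaluate predictions against true labels
#'
#' Computes the confusion-matrix metrics, the rank-based AUC of the
#' continuous scores, and the two-sided Fisher exact p-value for
#' independence of the predicted-label x true-label crosstab.
#'
#' @param scores Continuous scores, higher meaning more mutation-like (for
#'   the ISM classifier, the orientation-adjusted deviation scores).
#' @param predicted Predicted class labels (`"MUT"` / `"SNP"`).
#' @param truth True class labels.
#' @return Object of class `ism_evaluation`: a list with `counts`, `metrics`
#'   (accuracy, precision, sensitivity, specificity, npv), `auc`, `fisher_p`
#'   and `n`.
#' @export
evaluate_predictions <- function(scores, predicted, truth) {
  stopifnot(length(scores) == length(truth), length(predicted) == length(truth))
  counts <- confusion_counts(predicted, truth)
  # rows: predicted MUT/SNP; columns: truth MUT/SNP
  tab <- matrix(c(counts$TP, counts$FN, counts$FP, counts$TN), 2L, 2L,
                dimnames = list(predicted = c("MUT", "SNP"),
                                truth = c("MUT", "SNP")))
  structure(
    list(counts = counts,
         metrics = confusion_metrics(counts),
         auc = roc_auc(scores, truth),
         fisher_p = fisher_exact_2x2(tab),
         n = length(truth)),
    class = "ism_evaluation")
}

#' @export
print.ism_evaluation <- function(x, digits = 3, ...) {
  cat("Classification evaluation (n = ", x$n, ")\n", sep = "")
  cat(sprintf("  TP %d  FP %d  FN %d  TN %d\n",
              x$counts$TP, x$counts$FP, x$counts$FN, x$counts$TN))
  m <- x$metrics
  for (k in names(m)) {
    cat(sprintf("  %-12s %s\n", k,
                if (is.na(m[[k]])) "undefined" else format(round(m[[k]], digits))))
  }
  cat(sprintf("  %-12s %s\n", "auc", format(round(x$auc, digits))))
  cat(sprintf("  %-12s %s\n", "fisher p", format.pval(x$fisher_p, digits = digits)))
  invisible(x)
}

#' Write an evaluation report as delimited text
#'
#' One `metric`/`value` pair per row, tab-separated (undefined metrics are
#' written as NA).
#'
#' @param report An `ism_evaluation`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_evaluation <- function(report, path) {
  stopifnot(inherits(report, "ism_evaluation"))
  vals <- c(n = report$n, TP = report$counts$TP, TN = report$counts$TN,
            FP = report$counts$FP, FN = report$counts$FN,
            report$metrics, auc = report$auc, fisher_p = report$fisher_p)
  utils::write.table(data.frame(metric = names(vals), value = unname(unlist(vals))),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
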