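test_that("Mann-Whitney worked examples", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)        # 2/20 orderings at least as extreme
  expect_true(r$exact)
  # identical multisets are perfectly exchangeable
  expect_equal(mann_whitney_u(c(2, 2, 5), c(2, 2, 5))$p, 1.0)
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("exact Mann-Whitney p matches full-permutation enumeration for all group sizes <= 7", {
  set.seed(7)
  for (m in 1:7) {
    for (n in 1:7) {
      a <- sample(seq_len(100), m)  # tie-free by construction
      b <- sample(setdiff(seq_len(100), a), n)
      got <- mann_whitney_u(a, b)
      expect_true(got$exact)
      expect_equal(got$p, enumerate_mwu_p(a, b), tolerance = 1e-12,
                   info = sprintf("m=%d n=%d", m, n))
    }
  }
})

test_that("Mann-Whitney switches to the corrected normal approximation on ties or large groups", {
  with_ties <- mann_whitney_u(c(1, 2, 2, 3), c(2, 4, 5))
  expect_false(with_ties$exact)
  set.seed(8)
  big <- mann_whitney_u(rnorm(20), rnorm(20))
  expect_false(big$exact)
  # approximate p agrees with wilcox.test's corrected normal path
  ref <- stats::wilcox.test(c(1, 2, 2, 3), c(2, 4, 5), exact = FALSE,
                            correct = TRUE)$p.value
  expect_equal(with_ties$p, ref)
})

test_that("Fisher exact worked examples", {
  expect_equal(fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2)), 2 / 252,
               tolerance = 1e-9)
  expect_equal(fisher_exact_2x2(matrix(c(1, 1, 1, 1), 2)), 1.0)
  expect_warning(p <- fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
                 "zero margin")
  expect_equal(p, 1)
})

test_that("Fisher two-sided p matches hypergeometric enumeration for tables with entries <= 8", {
  for (a in 0:8) for (b in 0:8) for (cc in 0:8) for (d in 0:8) {
    tab <- matrix(c(a, cc, b, d), 2)  # rows (a, b), (cc, d)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_2x2(tab), enumerate_fisher_p(tab),
                 tolerance = 1e-9,
                 info = paste(a, b, cc, d))
  }
})

test_that("Fisher p is invariant to transpose and to swapping both rows and columns", {
  tab <- matrix(c(7, 2, 3, 8), 2)
  p <- fisher_exact_2x2(tab)
  expect_equal(fisher_exact_2x2(t(tab)), p)
  expect_equal(fisher_exact_2x2(tab[2:1, 2:1]), p)
})

test_that("confusion metrics follow their defining ratios", {
  m <- confusion_metrics(TP = 2, TN = 3, FP = 1, FN = 1)
  expect_equal(unname(m["accuracy"]), 5 / 7)
  expect_equal(unname(m["precision"]), 2 / 3)
  expect_equal(unname(m["sensitivity"]), 2 / 3)
  expect_equal(unname(m["specificity"]), 3 / 4)
  expect_equal(unname(m["npv"]), 3 / 4)
  # perfect classifier
  expect_true(all(confusion_metrics(TP = 4, TN = 6, FP = 0, FN = 0) == 1))
  # undefined metric reported as NA, not 0
  m0 <- confusion_metrics(TP = 0, TN = 5, FP = 0, FN = 2)
  expect_true(is.na(m0["precision"]))
  expect_false(is.na(m0["accuracy"]))
  expect_error(confusion_metrics(TP = 0, TN = 0, FP = 0, FN = 0), "zero")
})

test_that("accuracy is the prevalence-weighted mix of sensitivity and specificity", {
  set.seed(21)
  for (i in 1:20) {
    counts <- as.list(stats::setNames(sample(1:30, 4, replace = TRUE),
                                      c("TP", "TN", "FP", "FN")))
    m <- confusion_metrics(counts)
    n_pos <- counts$TP + counts$FN
    n_neg <- counts$TN + counts$FP
    expect_equal(unname(m["accuracy"]),
                 (n_pos * m[["sensitivity"]] + n_neg * m[["specificity"]]) /
                   (n_pos + n_neg))
    expect_true(all(m >= 0 & m <= 1, na.rm = TRUE))
  }
})

test_that("AUC equals the rank/U identity and handles separation extremes", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c("MUT", "MUT", "SNP", "SNP")), 1)
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c("SNP", "SNP", "MUT", "MUT")), 0)
  set.seed(31)
  for (i in 1:20) {
    n1 <- sample(3:15, 1); n2 <- sample(3:15, 1)
    scores <- sample(seq_len(200), n1 + n2)  # tie-free
    labels <- c(rep("MUT", n1), rep("SNP", n2))
    u_greater <- mann_whitney_u(scores[1:n1], scores[-(1:n1)])$U_a
    expect_equal(roc_auc(scores, labels), u_greater / (n1 * n2),
                 tolerance = 1e-12)
  }
  expect_error(roc_auc(1:4, rep("MUT", 4)), "both classes")
})

test_that("null AUC concentrates near one half", {
  set.seed(41)
  scores <- rnorm(200)
  labels <- sample(rep(c("MUT", "SNP"), each = 100))
  auc <- roc_auc(scores, labels)
  expect_gt(auc, 0.42)
  expect_lt(auc, 0.58)
})

test_that("trapezoidal integration of the ROC curve equals the rank AUC", {
  set.seed(51)
  scores <- c(rnorm(30, 1), rnorm(40))
  labels <- c(rep("MUT", 30), rep("SNP", 40))
  curve <- roc_curve(scores, labels)
  trap <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) + utils::tail(curve$tpr, -1)) / 2)
  expect_equal(trap, roc_auc(scores, labels), tolerance = 1e-12)
  # independent oracle
  expect_equal(as.numeric(pROC::auc(pROC::roc(labels, scores, levels = c("SNP", "MUT"),
                                              direction = "<", quiet = TRUE))),
               roc_auc(scores, labels), tolerance = 1e-12)
})

test_that("SIFT scores are reflected so that high means deleterious", {
  expect_equal(transform_sift_score(0.01), 0.99)
  expect_equal(transform_sift_score(0.88), 0.12)
  expect_error(transform_sift_score(1.2), "out of")
})

test_that("external-score binarization applies each tool's cutoff convention", {
  expect_equal(binarize_external(c(0.01, 0.05, 0.2), "SIFT"),
               c("MUT", "SNP", "SNP"))  # 0.05 exactly is SNP: strict cutoff
  expect_equal(binarize_external(c(0.49, 0.5, 0.9), "PolyPhen-2"),
               c("SNP", "MUT", "MUT"))  # 0.5 exactly is MUT: inclusive cutoff
})

test_that("evaluation report combines counts, metrics, AUC and Fisher p", {
  truth <- c(rep("MUT", 6), rep("SNP", 6))
  scores <- c(3, 2.5, 2, 1.5, -0.5, -1, 1.2, 0.5, -1, -2, -2.5, -3)
  predicted <- ifelse(scores > 0, "MUT", "SNP")
  rep_ <- evaluate_predictions(scores, predicted, truth)
  expect_s3_class(rep_, "ism_evaluation")
  expect_equal(rep_$counts$TP, 4L)
  expect_equal(rep_$counts$FN, 2L)
  expect_equal(rep_$counts$FP, 2L)
  expect_equal(rep_$counts$TN, 4L)
  expect_equal(unname(rep_$metrics["accuracy"]), 8 / 12)
  expect_equal(rep_$auc, roc_auc(scores, truth))
  expect_equal(rep_$fisher_p,
               fisher_exact_2x2(matrix(c(4, 2, 2, 4), 2)))
  path <- tempfile(fileext = ".tsv")
  write_evaluation(rep_, path)
  d <- read.delim(path)
  expect_equal(d$value[d$metric == "accuracy"], 8 / 12, tolerance = 1e-9)
})
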