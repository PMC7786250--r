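test_that("confusion metrics reproduce hand arithmetic and edge cases", {
  m <- confusion_metrics(tp = 33, fp = 4, tn = 73, fn = 6)
  expect_equal(m$acc, 106 / 116)
  expect_equal(m$sen, 33 / 39)
  expect_equal(m$spe, 73 / 77)
  expect_equal(m$ppv, 33 / 37)
  expect_equal(m$npv, 73 / 79)
  expect_equal(m$mcc, (33 * 73 - 4 * 6) / sqrt(37 * 39 * 77 * 79))

  perfect <- confusion_metrics(tp = 10, fp = 0, tn = 20, fn = 0)
  expect_true(all(unlist(perfect[c("acc", "sen", "spe", "ppv", "npv",
                                   "f1", "mcc")]) == 1))

  deg <- confusion_metrics(tp = 0, fp = 0, tn = 5, fn = 5)
  expect_equal(as.numeric(deg$mcc), 0)
  expect_true(attr(deg$mcc, "mcc_degenerate"))
  expect_error(confusion_metrics(-1, 0, 1, 0), "non-negative")
  expect_true(abs(confusion_metrics(25, 7, 70, 14)$mcc) <= 1)
})

test_that("printed SEN/SPE identify a unique integer confusion matrix", {
  cm <- reconstruct_confusion(sen = 0.64, spe = 0.91, n_pos = 39, n_neg = 77)
  expect_equal(cm, list(tp = 25L, fp = 7L, tn = 70L, fn = 14L))
  expect_error(reconstruct_confusion(0.5, 0.5, 1000, 1000), "unique")
})

test_that("AUC equals all-pairs counting and handles ties", {
  expect_equal(roc_auc(rep(1, 10), rep(c(TRUE, FALSE), 5))$auc, 0.5)
  expect_equal(roc_auc(1:10, c(rep(FALSE, 5), rep(TRUE, 5)))$auc, 1)

  set.seed(31)
  for (k in 1:10) {
    scores <- sample(seq(0, 1, by = 0.05), 30, replace = TRUE)  # with ties
    labels <- sample(c(TRUE, FALSE), 30, replace = TRUE,
                     prob = c(0.4, 0.6))
    if (length(unique(labels)) < 2) next
    expect_equal(roc_auc(scores, labels)$auc, oracle_auc(scores, labels))
  }
  expect_error(roc_auc(1:5, rep(TRUE, 5)), "both classes")
})

test_that("AUC agrees with pROC and is monotone-transform invariant", {
  set.seed(5)
  scores <- rnorm(40); labels <- rep(c(TRUE, FALSE), each = 20)
  ours <- roc_auc(scores, labels)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref)
  expect_equal(roc_auc(exp(3 * scores), labels)$auc, ours)
})

test_that("Youden cutoff maximizes TPR - FPR, lowest threshold on ties", {
  # fully separable: returned cutoff classifies everything correctly
  scores <- c(1:5, 11:15); labels <- rep(c(FALSE, TRUE), each = 5)
  r <- roc_auc(scores, labels)
  cut <- youden_cutoff(r)
  expect_true(all((scores >= cut) == labels))

  # brute-force scan oracle on random data
  set.seed(17)
  for (k in 1:10) {
    s <- round(rnorm(25), 1)
    l <- sample(c(TRUE, FALSE), 25, replace = TRUE)
    if (length(unique(l)) < 2) next
    r <- roc_auc(s, l)
    best_j <- max(r$curve$tpr - r$curve$fpr)
    got <- youden_cutoff(r)
    j_at <- function(t) mean(s[l] >= t) - mean(s[!l] >= t)
    expect_equal(j_at(got), best_j)
    lower <- r$curve$threshold[r$curve$threshold < got]
    expect_true(all(j_at(got) > vapply(lower, j_at, 0) - 1e-12))
  }
})

test_that("LOOCV separates separable data and respects fold hygiene", {
  x <- matrix(c(rnorm(10, 0, 0.1), rnorm(10, 5, 0.1)), ncol = 1)
  y <- rep(c(FALSE, TRUE), each = 10)
  for (clf in c("lr", "rf", "svm")) {
    ev <- loocv_evaluate(x, y, model_config(clf, seed = 3))
    expect_equal(ev$metrics$acc, 1)
    expect_equal(ev$auc, 1)
    expect_length(ev$scores, 20)            # one fold per subject
  }
  expect_error(loocv_evaluate(x, rep(TRUE, 20)), "both classes")
  expect_error(loocv_evaluate(x[1:2, , drop = FALSE], c(TRUE, FALSE)),
               "at least 3")
})

test_that("LOOCV shows no optimistic bias under label permutation", {
  # pooled LOOCV scores of refit classifiers are well known to run
  # pessimistic (the held-out subject's class is underrepresented in its
  # training fold), so the null mean AUC sits at or below chance; what
  # must never happen without leakage is optimism above 0.5
  set.seed(71)
  x <- matrix(rnorm(60), ncol = 2)
  y0 <- rep(c(TRUE, FALSE), each = 15)
  aucs <- vapply(1:200, function(k) {
    y <- sample(y0)
    loocv_evaluate(x, y, model_config("lr", seed = k))$auc
  }, 0)
  expect_lte(mean(aucs), 0.52)
  expect_gt(mean(aucs), 0.25)   # still in the chance regime, not inverted
})

test_that("LOOCV is deterministic under a fixed seed", {
  set.seed(99)
  x <- matrix(rnorm(40), ncol = 2)
  y <- rep(c(TRUE, FALSE), 10)
  a <- loocv_evaluate(x, y, model_config("rf", seed = 7))
  b <- loocv_evaluate(x, y, model_config("rf", seed = 7))
  expect_identical(a$scores, b$scores)
})

test_that("DeLong test handles identical and rank-equivalent scores", {
  set.seed(41)
  s <- rnorm(30); l <- rep(c(TRUE, FALSE), 15)
  same <- delong_test(s, s, l)
  expect_equal(same$delta, 0)
  expect_equal(same$p, 1)

  mono <- delong_test(s, exp(2 * s) + 1, l)
  expect_equal(mono$delta, 0)
  expect_equal(mono$auc_a, mono$auc_b)
  expect_error(delong_test(s, s, rep(TRUE, 30)), "both classes")
})

test_that("DeLong agrees with pROC and a paired bootstrap", {
  set.seed(53)
  n <- 50
  l <- rep(c(TRUE, FALSE), each = n / 2)
  base <- rnorm(n) + 1.2 * l
  sa <- base + rnorm(n, 0, 0.6)
  sb <- base + rnorm(n, 0, 1.1)
  ours <- delong_test(sa, sb, l)

  ref <- pROC::roc.test(pROC::roc(l, sa, quiet = TRUE, direction = "<"),
                        pROC::roc(l, sb, quiet = TRUE, direction = "<"),
                        method = "delong")
  expect_equal(ours$p, as.numeric(ref$p.value), tolerance = 1e-9)

  # stratified paired bootstrap of the AUC difference
  set.seed(54)
  pos <- which(l); neg <- which(!l)
  boot <- vapply(1:10000, function(k) {
    idx <- c(sample(pos, replace = TRUE), sample(neg, replace = TRUE))
    oracle_quick <- function(s) {
      r <- rank(s[idx])
      (sum(r[l[idx]]) - sum(l[idx]) * (sum(l[idx]) + 1) / 2) /
        (sum(l[idx]) * sum(!l[idx]))
    }
    oracle_quick(sa) - oracle_quick(sb)
  }, 0)
  p_boot <- 2 * stats::pnorm(-abs(ours$delta / stats::sd(boot)))
  expect_lt(abs(ours$p - p_boot), 0.03)
})

test_that("DeLong type-I error sits near the nominal 5% level", {
  set.seed(61)
  l <- rep(c(TRUE, FALSE), each = 20)
  rej <- vapply(1:1000, function(k)
    delong_test(rnorm(40), rnorm(40), l)$p < 0.05, NA)
  expect_lt(abs(mean(rej) - 0.05), 0.02)
})

test_that("RF grid search is exhaustive with documented tie-breaks", {
  set.seed(81)
  x <- matrix(c(rnorm(5, 0, 1), rnorm(5, 2, 1)), ncol = 1)
  y <- rep(c(FALSE, TRUE), each = 5)

  # single-combination grid returns that combination
  cfg1 <- model_config("rf", rf_random_state_grid = 4,
                       rf_n_estimators_grid = 50)
  g1 <- rf_grid_search(x, y, cfg1)
  expect_equal(g1$random_state, 4)
  expect_equal(g1$n_estimators, 50)
  expect_equal(nrow(g1$table), 1)

  # the reference grids give an 8 x 10 = 80-row score table whose best row
  # is returned under the smallest-n_estimators-then-random_state tie-break
  g <- rf_grid_search(x, y, model_config("rf"))
  expect_equal(nrow(g$table), 80)
  expect_equal(g$auc, max(g$table$auc))
  ties <- g$table[g$table$auc == g$auc, ]
  ties <- ties[order(ties$n_estimators, ties$random_state), ]
  expect_equal(g$n_estimators, ties$n_estimators[1])
  expect_equal(g$random_state, ties$random_state[1])
})

test_that("time normalization divides by t and log(t + 1)", {
  r <- time_normalized_nwu(0.2, exp(1) - 1)
  expect_equal(r$nwu_per_log_time, 0.2)
  expect_equal(time_normalized_nwu(0.2, 1)$nwu_per_hour, 0.2)
  expect_equal(time_normalized_nwu(0.3, 8)$nwu_per_hour,
               2 * time_normalized_nwu(0.3, 16)$nwu_per_hour)
  expect_error(time_normalized_nwu(0.2, 0), "positive")
})
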