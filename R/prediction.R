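# Classifier training and evaluation for MCE prediction: leave-one-out
# cross-validation over SVM / logistic regression / random forest,
# Mann-Whitney ROC/AUC, Youden cutoff, confusion-matrix metrics including
# the Matthews correlation coefficient, and the paired DeLong AUC test.

#' Classifier configuration
#'
#' @param classifier `"svm"`, `"lr"` or `"rf"`. Library defaults are used
#'   (RBF-kernel SVM with cost 1; binomial GLM; random forest), with the
#'   tree count of the random forest set by `n_estimators`.
#' @param standardize z-score features using training-fold statistics;
#'   `NULL` (default) enables it for the scale-sensitive SVM and LR and
#'   disables it for RF.
#' @param n_estimators trees per random forest (default 100, the tuned
#'   operating point of the reference grid).
#' @param rf_random_state_grid,rf_n_estimators_grid search grids for
#'   [rf_grid_search()]; defaults 2..16 step 2 and 100..1000 step 100.
#' @param seed RNG seed set before each stochastic fit, making LOOCV
#'   deterministic.
#' @return A `model_config` list.
#' @export
model_config <- function(classifier = c("rf", "svm", "lr"),
                         standardize = NULL, n_estimators = 100,
                         rf_random_state_grid = seq(2, 16, by = 2),
                         rf_n_estimators_grid = seq(100, 1000, by = 100),
                         seed = 1L) {
  classifier <- match.arg(classifier)
  if (is.null(standardize)) standardize <- classifier %in% c("svm", "lr")
  if (length(rf_random_state_grid) < 1 || length(rf_n_estimators_grid) < 1)
    stop("hyperparameter grids must be non-empty")
  structure(list(classifier = classifier, standardize = standardize,
                 n_estimators = n_estimators,
                 rf_random_state_grid = rf_random_state_grid,
                 rf_n_estimators_grid = rf_n_estimators_grid,
                 seed = as.integer(seed)),
            class = "model_config")
}

fit_classifier <- function(x, y, config) {
  set.seed(config$seed)
  switch(config$classifier,
    svm = {
      fit <- e1071::svm(x, factor(y, levels = c(FALSE, TRUE)), kernel = "radial",
                        cost = 1, scale = FALSE)
      dv <- attr(stats::predict(fit, x, decision.values = TRUE),
                 "decision.values")[, 1]
      flip <- mean(dv[y]) < mean(dv[!y])
      list(fit = fit, flip = flip)
    },
    lr = {
      df <- data.frame(x); df$.y <- as.numeric(y)
      suppressWarnings(list(fit = stats::glm(.y ~ ., data = df,
                                             family = stats::binomial())))
    },
    rf = list(fit = randomForest::randomForest(
      x, factor(y, levels = c(FALSE, TRUE)), ntree = config$n_estimators)))
}

score_classifier <- function(model, x, config) {
  switch(config$classifier,
    svm = {
      pr <- stats::predict(model$fit, x, decision.values = TRUE)
      dv <- attr(pr, "decision.values")[, 1]
      score <- if (model$flip) -dv else dv
      list(score = score, label = as.logical(pr == "TRUE"))
    },
    lr = {
      p <- stats::predict(model$fit, newdata = data.frame(x),
                          type = "response")
      list(score = as.numeric(p), label = as.numeric(p) >= 0.5)
    },
    rf = {
      p <- stats::predict(model$fit, x, type = "prob")[, "TRUE"]
      list(score = as.numeric(p), label = as.numeric(p) >= 0.5)
    })
}

#' Leave-one-out cross-validated evaluation
#'
#' Runs n folds, each holding out one subject; any feature standardization
#' uses training-fold statistics only, so no information from the held-out
#' subject leaks into its own fold. Metrics and the ROC curve are computed
#' on the pooled held-out scores and predicted labels.
#'
#' @param x numeric feature matrix or data.frame (subjects x features).
#' @param y logical labels (`TRUE` = MCE); both classes must be present,
#'   n >= 3.
#' @param config a [model_config()].
#' @return An `eval_report`: `scores`, `predicted`, `labels`, `confusion`,
#'   `metrics` (acc/sen/spe/ppv/npv/f1/mcc), `roc`, `auc`, `config`.
#' @export
loocv_evaluate <- function(x, y, config = model_config()) {
  x <- as.matrix(x); storage.mode(x) <- "double"
  y <- as.logical(y)
  n <- nrow(x)
  if (n < 3) stop("need at least 3 subjects")
  if (length(unique(y)) < 2) stop("both classes must be present")
  scores <- numeric(n); predicted <- logical(n)
  for (i in seq_len(n)) {
    xtr <- x[-i, , drop = FALSE]; xte <- x[i, , drop = FALSE]
    if (config$standardize) {
      mu <- colMeans(xtr)
      sdv <- apply(xtr, 2, stats::sd); sdv[sdv == 0] <- 1
      xtr <- sweep(sweep(xtr, 2, mu), 2, sdv, "/")
      xte <- sweep(sweep(xte, 2, mu), 2, sdv, "/")
    }
    model <- fit_classifier(xtr, y[-i], config)
    out <- score_classifier(model, xte, config)
    scores[i] <- out$score; predicted[i] <- out$label
  }
  cm <- confusion_from_labels(predicted, y)
  roc <- roc_auc(scores, y)
  structure(list(scores = scores, predicted = predicted, labels = y,
                 confusion = cm, metrics = confusion_metrics(cm),
                 roc = roc$curve, auc = roc$auc, config = config),
            class = "eval_report")
}

confusion_from_labels <- function(predicted, truth) {
  list(tp = sum(predicted & truth), fp = sum(predicted & !truth),
       tn = sum(!predicted & !truth), fn = sum(!predicted & truth))
}

#' Confusion-matrix performance metrics
#'
#' Standard binary metrics with MCE as the positive class, plus the
#' Matthews correlation coefficient
#' `MCC = (tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`; a zero
#' denominator yields MCC 0 with attribute `mcc_degenerate = TRUE`.
#'
#' @param tp true positives, or a list/confusion with elements
#'   `tp, fp, tn, fn`.
#' @param fp,tn,fn counts (ignored when `tp` is a list).
#' @return List: `acc`, `sen`, `spe`, `ppv`, `npv`, `f1`, `mcc`, `n`.
#' @export
confusion_metrics <- function(tp, fp = NULL, tn = NULL, fn = NULL) {
  if (is.list(tp)) { fp <- tp$fp; tn <- tp$tn; fn <- tp$fn; tp <- tp$tp }
  counts <- c(tp, fp, tn, fn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion counts must be non-negative integers")
  n <- sum(counts)
  if (n == 0) stop("empty confusion matrix")
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  sen <- div(tp, tp + fn); ppv <- div(tp, tp + fp)
  denom2 <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom2 == 0) structure(0, mcc_degenerate = TRUE)
         else (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(denom2)
  list(acc = (tp + tn) / n, sen = sen, spe = div(tn, tn + fp),
       ppv = ppv, npv = div(tn, tn + fn),
       f1 = if (is.na(sen) || is.na(ppv) || sen + ppv == 0) NA_real_
            else 2 * sen * ppv / (sen + ppv),
       mcc = mcc, n = n)
}

#' Reconstruct the integer confusion matrix behind printed SEN/SPE
#'
#' Given sensitivity and specificity reported to a fixed precision and the
#' two group sizes, finds the unique integer counts consistent with them;
#' errors when no or several matrices match.
#'
#' @param sen,spe printed sensitivity and specificity.
#' @param n_pos,n_neg positive/negative group sizes.
#' @param digits precision of the printed values (default 2).
#' @return List with `tp`, `fp`, `tn`, `fn`.
#' @export
reconstruct_confusion <- function(sen, spe, n_pos, n_neg, digits = 2) {
  tol <- 0.5 * 10^(-digits)
  tp <- which(abs((0:n_pos) / n_pos - sen) < tol) - 1L
  tn <- which(abs((0:n_neg) / n_neg - spe) < tol) - 1L
  if (length(tp) != 1 || length(tn) != 1)
    stop("printed SEN/SPE do not identify a unique integer confusion matrix")
  list(tp = tp, fp = n_neg - tn, tn = tn, fn = n_pos - tp)
}

#' ROC curve and Mann-Whitney AUC
#'
#' AUC is the probability that a random positive outscores a random
#' negative, with ties counted 1/2 (computed from midranks). The curve
#' uses the rule "score >= threshold is positive", with thresholds at
#' +Inf, the midpoints between consecutive distinct scores, and -Inf,
#' ordered descending.
#'
#' @param scores numeric classifier scores, higher = more MCE-like.
#' @param labels logical, `TRUE` = positive; both classes required.
#' @return List: `curve` (data.frame threshold/fpr/tpr, thresholds
#'   descending) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)   # midranks
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  u <- sort(unique(scores), decreasing = TRUE)
  thr <- c(Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, -Inf)
  tpr <- vapply(thr, function(t) sum(scores[labels] >= t) / n1, 0)
  fpr <- vapply(thr, function(t) sum(scores[!labels] >= t) / n0, 0)
  list(curve = data.frame(threshold = thr, fpr = fpr, tpr = tpr), auc = auc)
}

#' Youden-optimal cutoff of an ROC curve
#'
#' Returns the threshold maximizing `TPR - FPR` (Youden's J); on ties the
#' lowest threshold is returned.
#'
#' @param roc the result of [roc_auc()] or its `curve` data.frame.
#' @return Scalar threshold.
#' @export
youden_cutoff <- function(roc) {
  curve <- if (is.data.frame(roc)) roc else roc$curve
  if (nrow(curve) == 0) stop("empty ROC curve")
  j <- curve$tpr - curve$fpr
  cand <- curve$threshold[j >= max(j) - 1e-12]
  min(cand)
}

# ---- DeLong paired AUC test ----------------------------------------------

# structural components: for each positive, the fraction of negatives it
# beats (ties 1/2); for each negative, the fraction of positives beating it
delong_components <- function(scores, labels) {
  xs <- scores[labels]; ys <- scores[!labels]
  v10 <- vapply(xs, function(x) mean((x > ys) + 0.5 * (x == ys)), 0)
  v01 <- vapply(ys, function(y) mean((xs > y) + 0.5 * (xs == y)), 0)
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong test for two paired AUCs
#'
#' Compares the AUCs of two score vectors measured on the same subjects
#' using the DeLong structural-component variance of the paired AUC
#' difference; two-sided normal p-value.
#'
#' @param scores_a,scores_b paired score vectors.
#' @param labels logical labels shared by both.
#' @return List: `auc_a`, `auc_b`, `delta`, `z`, `p`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores_a) == length(labels),
            length(scores_b) == length(labels))
  if (length(unique(labels)) < 2) stop("both classes must be present")
  ca <- delong_components(scores_a, labels)
  cb <- delong_components(scores_b, labels)
  delta <- ca$auc - cb$auc
  if (identical(as.numeric(scores_a), as.numeric(scores_b)))
    return(list(auc_a = ca$auc, auc_b = cb$auc, delta = 0, z = 0, p = 1))
  n1 <- length(ca$v10); n0 <- length(ca$v01)
  s10 <- stats::var(cbind(ca$v10, cb$v10))
  s01 <- stats::var(cbind(ca$v01, cb$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n1 +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n0
  if (v <= 0) {
    if (abs(delta) < 1e-12)
      return(list(auc_a = ca$auc, auc_b = cb$auc, delta = delta, z = 0, p = 1))
    stop("zero variance of the AUC difference with unequal AUCs")
  }
  z <- delta / sqrt(v)
  list(auc_a = ca$auc, auc_b = cb$auc, delta = delta, z = z,
       p = 2 * stats::pnorm(-abs(z)))
}

#' Exhaustive random-forest hyperparameter grid search
#'
#' Scores every `(random_state, n_estimators)` combination by LOOCV AUC
#' (the seed set before each fit plays the role of the random_state);
#' ties are broken toward the smallest `n_estimators`, then the smallest
#' `random_state`.
#'
#' @param x,y as in [loocv_evaluate()].
#' @param config a [model_config()] whose grids define the search space.
#' @return List: `random_state`, `n_estimators`, `auc`, and `table`
#'   (data.frame of every combination with its LOOCV AUC).
#' @export
rf_grid_search <- function(x, y, config = model_config("rf")) {
  grid <- expand.grid(random_state = config$rf_random_state_grid,
                      n_estimators = config$rf_n_estimators_grid)
  grid$auc <- NA_real_
  for (k in seq_len(nrow(grid))) {
    cf <- config
    cf$classifier <- "rf"
    cf$seed <- as.integer(grid$random_state[k])
    cf$n_estimators <- grid$n_estimators[k]
    grid$auc[k] <- loocv_evaluate(x, y, cf)$auc
  }
  best <- grid[order(-grid$auc, grid$n_estimators, grid$random_state), ][1, ]
  list(random_state = best$random_state, n_estimators = best$n_estimators,
       auc = best$auc, table = grid)
}

#' Time-normalized NWU variants
#'
#' Edema grows with time from onset, so NWU can be normalized by the
#' onset-to-scan interval: `NWU / t` and `NWU / log(t + 1)` (natural log).
#'
#' @param nwu scalar or vector NWU.
#' @param t_hours positive onset-to-scan time(s) in hours.
#' @return List: `nwu_per_hour`, `nwu_per_log_time`.
#' @export
time_normalized_nwu <- function(nwu, t_hours) {
  if (any(t_hours <= 0)) stop("onset-to-scan time must be positive")
  list(nwu_per_hour = nwu / t_hours,
       nwu_per_log_time = nwu / log(t_hours + 1))
}

round_half_up <- function(x, digits = 2) floor(x * 10^digits + 0.5) / 10^digits
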