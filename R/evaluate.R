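#' Binary classification metrics from confusion counts
#'
#' Sensitivity Sn = TP/(TP+FN), specificity Sp = TN/(TN+FP), accuracy
#' Acc = (TP+TN)/n and Matthews Correlation Coefficient
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FN)(TP+FP)(TN+FP)(TN+FN)), with
#' MCC defined as 0 when any factor of the denominator is 0.
#'
#' @param tp,fp,tn,fn Non-negative confusion counts (positives =
#'   cancerlectins).
#' @return A one-row tibble with columns `sn`, `sp`, `acc`, `mcc`.
#' @export
classification_metrics <- function(tp, fp, tn, fn) {
  tp <- unname(tp); fp <- unname(fp); tn <- unname(tn); fn <- unname(fn)
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0)) abort("confusion counts must be non-negative")
  n <- sum(counts)
  if (n == 0) abort("no evaluated samples (all counts zero)")
  sn <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  sp <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  acc <- (tp + tn) / n
  den <- prod(sqrt(c(tp + fn, tp + fp, tn + fp, tn + fn)))
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / den
  tibble::tibble(sn = sn, sp = sp, acc = acc, mcc = mcc)
}

#' ROC points from scores and labels
#'
#' Sweeps a decision threshold over all distinct scores (plus the two
#' degenerate extremes) and records (1 - Sp, Sn) at each; a sample is
#' called positive when `score >= threshold`.
#'
#' @param scores Numeric classifier scores, higher = more positive.
#' @param labels Binary labels (1 = positive).
#' @return Tibble with columns `threshold`, `fpr` (1 - Sp), `tpr` (Sn),
#'   ordered so both coordinates are non-decreasing.
#' @export
roc_points <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  npos <- sum(labels == 1)
  nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) abort("ROC needs both classes present")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  pts <- lapply(thr, function(t) {
    pred <- scores >= t
    c(fpr = sum(pred & labels == 0) / nneg, tpr = sum(pred & labels == 1) / npos)
  })
  m <- do.call(rbind, pts)
  tibble::tibble(threshold = thr, fpr = m[, "fpr"], tpr = m[, "tpr"])
}

#' Area under the ROC curve, trapezoidal rule
#'
#' @param roc Tibble from [roc_points()].
#' @return AUC in \[0, 1\].
#' @export
auc_trapezoid <- function(roc) {
  o <- order(roc$fpr, roc$tpr)
  x <- roc$fpr[o]
  y <- roc$tpr[o]
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

#' Area under the ROC curve, Mann-Whitney rank form
#'
#' The probability that a random positive scores above a random negative
#' (ties counted half), computed from the rank-sum statistic. Equals the
#' trapezoidal AUC exactly.
#'
#' @inheritParams roc_points
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(scores, labels) {
  npos <- sum(labels == 1)
  nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) abort("AUC needs both classes present")
  r <- rank(scores)
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

# stratified fold assignment, deterministic per seed
make_folds <- function(labels, folds, seed) {
  if (min(table(labels)) < folds) {
    abort(sprintf("need at least %d samples per class for %d-fold CV", folds, folds))
  }
  set.seed(seed)
  fold_id <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    fold_id[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
  }
  fold_id
}

supported_classifiers <- function() {
  c("rf", "knn", "nb", "logreg", "tree", "dummy")
}

# fit on train, return P(positive) on test; each classifier is an
# off-the-shelf implementation behind this one surface
fit_predict_scores <- function(classifier, Xtr, ytr, Xte, trees, seed) {
  set.seed(seed)
  switch(classifier,
    rf = {
      fit <- randomForest::randomForest(x = Xtr, y = ytr, ntree = trees)
      predict(fit, Xte, type = "prob")[, "1"]
    },
    knn = {
      if (!requireNamespace("class", quietly = TRUE)) abort("knn needs the class package")
      pred <- class::knn(Xtr, Xte, cl = ytr, k = 1, prob = TRUE)
      p <- attr(pred, "prob")
      ifelse(pred == "1", p, 1 - p)
    },
    nb = {
      if (!requireNamespace("e1071", quietly = TRUE)) abort("nb needs the e1071 package")
      fit <- e1071::naiveBayes(x = Xtr, y = ytr)
      predict(fit, Xte, type = "raw")[, "1"]
    },
    logreg = {
      d <- data.frame(Xtr, .y = ytr)
      fit <- suppressWarnings(stats::glm(.y ~ ., data = d, family = stats::binomial()))
      suppressWarnings(predict(fit, data.frame(Xte), type = "response"))
    },
    tree = {
      if (!requireNamespace("rpart", quietly = TRUE)) abort("tree needs the rpart package")
      d <- data.frame(Xtr, .y = ytr)
      fit <- rpart::rpart(.y ~ ., data = d, method = "class")
      predict(fit, data.frame(Xte), type = "prob")[, "1"]
    },
    dummy = rep(mean(ytr == "1"), nrow(Xte)),
    abort(sprintf(
      "unknown classifier '%s'; supported: %s",
      classifier, paste(supported_classifiers(), collapse = ", ")
    ))
  )
}

#' Cross-validated evaluation of a classifier on a feature matrix
#'
#' Stratified k-fold cross-validation: the data are split into `folds`
#' nonoverlapping parts preserving class proportions; each part is used
#' in turn as the test set. Confusion counts are pooled over the folds,
#' and the ROC is built from the pooled out-of-fold scores (for a Random
#' Forest, the fraction of trees voting positive).
#'
#' SMOTE placement is controlled by `smote`:
#' `"pre_split"` balances the whole matrix before splitting (the published
#' procedure; synthetic points can land in test folds), `"per_fold"`
#' balances only each fold's training part (leakage-safe), `"off"` does
#' nothing.
#'
#' @param features Feature tibble.
#' @param folds Number of folds (default 5).
#' @param classifier One of `"rf"`, `"knn"`, `"nb"`, `"logreg"`, `"tree"`,
#'   `"dummy"`.
#' @param trees Random-Forest size (default 100).
#' @param smote One of `"off"` (default), `"pre_split"`, `"per_fold"`.
#' @param smote_k SMOTE neighbour count (default 5).
#' @param seed Seed controlling the fold split, SMOTE and classifier fits.
#' @return An `eval_report`: list with `pooled` (one-row metric tibble
#'   incl. `auc`), `per_fold` (metric tibble per fold), `roc`
#'   (from [roc_points()]), `counts` (pooled TP/FP/TN/FN), `scores`
#'   (out-of-fold score tibble) and `config`.
#' @export
cross_validate <- function(features, folds = 5, classifier = "rf",
                           trees = 100, smote = c("off", "pre_split", "per_fold"),
                           smote_k = 5, seed = 1) {
  smote <- match.arg(smote)
  if (!classifier %in% supported_classifiers()) {
    abort(sprintf(
      "unknown classifier '%s'; supported: %s",
      classifier, paste(supported_classifiers(), collapse = ", ")
    ))
  }
  if (smote == "pre_split") {
    features <- smote_balance(features, k = smote_k, seed = seed)
  }
  y <- features$label
  fold_id <- make_folds(y, folds = folds, seed = seed)
  fcols <- feature_cols(features)

  score <- numeric(nrow(features))
  per_fold <- vector("list", folds)
  counts <- c(tp = 0, fp = 0, tn = 0, fn = 0)
  for (f in seq_len(folds)) {
    tr_idx <- which(fold_id != f)
    te_idx <- which(fold_id == f)
    train <- features[tr_idx, ]
    if (smote == "per_fold") {
      train <- smote_balance(train, k = smote_k, seed = seed + f)
    }
    Xtr <- as.data.frame(train[, fcols])
    ytr <- factor(train$label, levels = c(0, 1))
    Xte <- as.data.frame(features[te_idx, fcols])
    s <- fit_predict_scores(classifier, Xtr, ytr, Xte, trees = trees, seed = seed + f)
    score[te_idx] <- s
    pred <- as.integer(s >= 0.5)
    truth <- y[te_idx]
    fc <- c(
      tp = sum(pred == 1 & truth == 1), fp = sum(pred == 1 & truth == 0),
      tn = sum(pred == 0 & truth == 0), fn = sum(pred == 0 & truth == 1)
    )
    counts <- counts + fc
    per_fold[[f]] <- dplyr::bind_cols(
      tibble::tibble(fold = f),
      classification_metrics(fc["tp"], fc["fp"], fc["tn"], fc["fn"])
    )
  }

  roc <- roc_points(score, y)
  pooled <- classification_metrics(counts["tp"], counts["fp"], counts["tn"], counts["fn"])
  pooled$auc <- auc_trapezoid(roc)
  structure(
    list(
      pooled = pooled,
      per_fold = dplyr::bind_rows(per_fold),
      roc = roc,
      counts = counts,
      scores = tibble::tibble(
        id = features$id, label = y, fold = fold_id, score = score
      ),
      config = list(
        folds = folds, classifier = classifier, trees = trees,
        smote = smote, smote_k = smote_k, seed = seed
      )
    ),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<eval_report> %s, %d-fold CV (smote = %s, seed = %d)\n",
    cfg$classifier, cfg$folds, cfg$smote, cfg$seed
  ))
  p <- x$pooled
  cat(sprintf(
    "  Sn %.3f  Sp %.3f  Acc %.3f  MCC %.3f  AUC %.3f\n",
    p$sn, p$sp, p$acc, p$mcc, p$auc
  ))
  invisible(x)
}

#' Compare classifiers under identical cross-validation folds
#'
#' Evaluates each named classifier with [cross_validate()] at the same
#' seed (hence identical fold splits and SMOTE placement) and tabulates
#' Sn/Sp/Acc/MCC/AUC per classifier.
#'
#' @inheritParams cross_validate
#' @param classifiers Character vector of classifier names.
#' @return Tibble with one row per classifier and columns `classifier`,
#'   `sn`, `sp`, `acc`, `mcc`, `auc`. The full `eval_report`s are attached
#'   as attribute `reports`.
#' @export
compare_classifiers <- function(features, classifiers = c("rf", "nb", "knn"),
                                folds = 5, trees = 100,
                                smote = c("off", "pre_split", "per_fold"),
                                smote_k = 5, seed = 1) {
  smote <- match.arg(smote)
  unknown <- setdiff(classifiers, supported_classifiers())
  if (length(unknown) > 0) {
    abort(sprintf(
      "unknown classifier(s) %s; supported: %s",
      paste(unknown, collapse = ", "),
      paste(supported_classifiers(), collapse = ", ")
    ))
  }
  reports <- lapply(classifiers, function(cl) {
    cross_validate(
      features, folds = folds, classifier = cl, trees = trees,
      smote = smote, smote_k = smote_k, seed = seed
    )
  })
  out <- dplyr::bind_cols(
    tibble::tibble(classifier = classifiers),
    dplyr::bind_rows(lapply(reports, function(r) r$pooled))
  )
  attr(out, "reports") <- setNames(reports, classifiers)
  out
}
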