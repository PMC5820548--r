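test_that("metric formulas follow the confusion-count definitions", {
  perfect <- classification_metrics(10, 0, 10, 0)
  expect_equal(unlist(perfect), c(sn = 1, sp = 1, acc = 1, mcc = 1))

  chance <- classification_metrics(5, 5, 5, 5)
  expect_equal(unlist(chance), c(sn = 0.5, sp = 0.5, acc = 0.5, mcc = 0))

  # plug-in oracle: direct evaluation of each formula
  tp <- 8; fn <- 2; tn <- 7; fp <- 3
  m <- classification_metrics(tp, fp, tn, fn)
  expect_equal(m$sn, tp / (tp + fn))
  expect_equal(m$sp, tn / (tn + fp))
  expect_equal(m$acc, (tp + tn) / (tp + fp + tn + fn))
  expect_equal(
    m$mcc,
    (tp * tn - fp * fn) /
      sqrt((tp + fn) * (tp + fp) * (tn + fp) * (tn + fn))
  )
  # zero denominator factor -> MCC defined as 0
  expect_equal(classification_metrics(0, 0, 5, 5)$mcc, 0)
  expect_error(classification_metrics(0, 0, 0, 0), "zero")
})

test_that("trapezoid and Mann-Whitney AUC agree to 1e-9, including ties", {
  set.seed(19)
  for (i in 1:10) {
    labels <- rep(c(1, 0), c(12, 15))
    scores <- round(c(rnorm(12, 1), rnorm(15)), sample(c(1, 2, 8), 1))
    a1 <- auc_trapezoid(roc_points(scores, labels))
    a2 <- auc_rank(scores, labels)
    expect_equal(a1, a2, tolerance = 1e-9)
    if (requireNamespace("pROC", quietly = TRUE)) {
      a3 <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE)))
      expect_equal(a1, a3, tolerance = 1e-9)
    }
  }
})

test_that("ROC points are monotone and span the unit square corners", {
  set.seed(23)
  roc <- roc_points(runif(30), rep(c(1, 0), 15))
  expect_true(!is.unsorted(roc$fpr))
  expect_true(!is.unsorted(roc$tpr))
  expect_equal(roc$fpr[1], 0)
  expect_equal(roc$tpr[1], 0)
  expect_equal(roc$fpr[nrow(roc)], 1)
  expect_equal(roc$tpr[nrow(roc)], 1)
})

test_that("stratified folds partition the data with near-equal class shares", {
  feat <- make_blobs(23, 37, d = 3, seed = 8)
  rep5 <- cross_validate(feat, folds = 5, trees = 10, seed = 3)
  fold_id <- rep5$scores$fold
  expect_setequal(unique(fold_id), 1:5)
  sizes <- table(fold_id)
  expect_lte(diff(range(sizes)), 2) # each class split may differ by 1
  for (f in 1:5) {
    pos_share <- table(fold_id[feat$label == 1])
    expect_lte(diff(range(pos_share)), 1)
  }
})

test_that("pooled accuracy equals (TP+TN)/n from the summed fold counts", {
  feat <- make_blobs(20, 25, d = 5, shift = 1, seed = 12)
  rep5 <- cross_validate(feat, trees = 30, seed = 5)
  cts <- rep5$counts
  expect_equal(sum(cts), nrow(feat))
  expect_equal(rep5$pooled$acc, (cts[["tp"]] + cts[["tn"]]) / sum(cts))
  expect_equal(nrow(tidy(rep5)), 5)
  expect_equal(glance(rep5)$acc, rep5$pooled$acc)
})

test_that("separable blobs are classified nearly perfectly; permuted labels are at chance", {
  feat <- make_blobs(100, 100, d = 10, shift = 2, seed = 1)
  rep5 <- cross_validate(feat, trees = 100, seed = 1)
  expect_gte(rep5$pooled$acc, 0.95)

  accs <- sapply(1:10, function(s) {
    perm <- feat
    set.seed(1000 + s)
    perm$label <- sample(perm$label)
    cross_validate(perm, trees = 40, seed = s)$pooled$acc
  })
  expect_lt(abs(mean(accs) - 0.5), 0.1)
})

test_that("MCC is near zero when predictions are independent of labels", {
  set.seed(40)
  mccs <- replicate(50, {
    truth <- rep(c(1, 0), c(20, 20))
    pred <- sample(truth) # label-independent predictions
    classification_metrics(
      sum(pred == 1 & truth == 1), sum(pred == 1 & truth == 0),
      sum(pred == 0 & truth == 0), sum(pred == 0 & truth == 1)
    )$mcc
  })
  expect_lt(abs(mean(mccs)), 0.05)
})

test_that("cross_validate is deterministic and validates its inputs", {
  feat <- make_blobs(15, 15, d = 4, seed = 2)
  a <- cross_validate(feat, trees = 25, seed = 6)
  b <- cross_validate(feat, trees = 25, seed = 6)
  expect_identical(a$pooled, b$pooled)
  expect_identical(a$scores, b$scores)
  expect_error(cross_validate(feat, classifier = "mystery"), "supported")
  expect_error(cross_validate(make_blobs(3, 30, d = 2), folds = 5), "per class")
})

test_that("classifier comparison shares folds and ranks RF above a majority dummy", {
  feat <- make_blobs(30, 30, d = 8, shift = 2, seed = 4)
  tab <- compare_classifiers(feat, c("rf", "dummy"), trees = 50, seed = 3)
  expect_equal(nrow(tab), 2)
  expect_true(all(c("sn", "sp", "acc", "mcc", "auc") %in% names(tab)))
  expect_gt(tab$acc[tab$classifier == "rf"], tab$acc[tab$classifier == "dummy"])

  twice <- compare_classifiers(feat, c("rf", "rf"), trees = 50, seed = 3)
  expect_equal(twice[1, -1], twice[2, -1])
  expect_error(compare_classifiers(feat, "nope"), "supported")
})

test_that("per-fold SMOTE never places synthetic rows in a test fold", {
  feat <- make_blobs(12, 40, d = 4, shift = 1, seed = 21)
  rep5 <- cross_validate(feat, smote = "per_fold", trees = 20, seed = 2)
  # every out-of-fold score belongs to an original record
  expect_setequal(rep5$scores$id, feat$id)
  expect_equal(nrow(rep5$scores), nrow(feat))
})
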