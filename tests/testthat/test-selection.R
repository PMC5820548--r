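# independent ReliefF oracle: explicit loops, k nearest hits/misses,
# range-normalized diffs on min-max scaled features
relief_oracle <- function(X, y, k) {
  n <- nrow(X)
  rngs <- apply(X, 2, function(x) diff(range(x)))
  rngs[rngs == 0] <- 1
  Xs <- sapply(seq_len(ncol(X)), function(j) (X[, j] - min(X[, j])) / rngs[j])
  score <- numeric(ncol(X))
  for (i in seq_len(n)) {
    d <- sqrt(colSums((t(Xs) - Xs[i, ])^2))
    same <- setdiff(which(y == y[i]), i)
    opp <- which(y != y[i])
    hits <- same[order(d[same])][seq_len(min(k, length(same)))]
    misses <- opp[order(d[opp])][seq_len(min(k, length(opp)))]
    for (f in seq_len(ncol(X))) {
      score[f] <- score[f] +
        mean(abs(Xs[misses, f] - Xs[i, f])) - mean(abs(Xs[hits, f] - Xs[i, f]))
    }
  }
  score / n
}

test_that("ReliefF scores match a hand-executed k = 1 pass on a 6-sample toy", {
  toy <- tibble::tibble(
    id = paste0("s", 1:6),
    label = c(1L, 1L, 1L, 0L, 0L, 0L),
    f1 = c(0, 0.1, 0.2, 0.8, 0.9, 1.0),
    f2 = c(0.5, 0, 1, 0.5, 0, 1)
  )
  got <- relief_scores(toy, k = 1)
  expected <- relief_oracle(as.matrix(toy[, c("f1", "f2")]), toy$label, k = 1)
  expect_equal(
    got$score[match(c("f1", "f2"), got$feature)],
    expected,
    tolerance = 1e-12
  )
  expect_gt(expected[1], 0) # f1 separates the classes
})

test_that("a constant feature scores exactly 0 and a separating feature ranks first", {
  set.seed(14)
  feat <- make_blobs(20, 20, d = 5, n_informative = 1, shift = 6, seed = 14)
  feat$const <- 1.5
  rk <- relief_scores(feat, k = 3)
  expect_identical(rk$score[rk$feature == "const"], 0)
  expect_equal(rk$feature[1], "f01")
  expect_gt(rk$score[1], 0)
  expect_true(all(rk$retained == (rk$score > 0)))
  expect_setequal(rk$rank, seq_len(nrow(rk)))
})

test_that("ReliefF matches the loop oracle on random data for several k", {
  set.seed(25)
  feat <- make_blobs(12, 15, d = 4, shift = 1, seed = 25)
  X <- as.matrix(feat[, feature_cols(feat)])
  for (k in c(1, 3, 10)) {
    got <- relief_scores(feat, k = k)
    expected <- relief_oracle(X, feat$label, k)
    expect_equal(
      got$score[match(feature_cols(feat), got$feature)],
      expected,
      tolerance = 1e-12
    )
  }
})

test_that("label-independent features have scores within noise of zero", {
  # fresh noise features and permuted labels each rerun, so the 50 scores
  # are independent draws of the null ReliefF score
  scores <- sapply(1:50, function(s) {
    d <- make_blobs(50, 50, d = 3, shift = 0, seed = 7000 + s)
    d$label <- sample(d$label)
    rk <- relief_scores(d, k = 10)
    rk$score[rk$feature == "f01"]
  })
  se <- sd(scores) / sqrt(length(scores))
  expect_lt(abs(mean(scores)), 3 * se + 1e-8)
})

test_that("SFS adds the informative feature first and returns the argmax prefix", {
  feat <- make_blobs(25, 25, d = 6, n_informative = 1, shift = 5, seed = 18)
  tr <- sfs_select(feat, feature_cols(feat), trees = 30, seed = 2, cap = 4)
  expect_equal(tr$feature[1], "f01")
  expect_equal(nrow(tr), 4)
  sel_acc <- tr$cv_accuracy[attr(tr, "selected_size")]
  expect_true(all(sel_acc >= tr$cv_accuracy))
  # shortest prefix attaining the max
  expect_equal(attr(tr, "selected_size"), which.max(tr$cv_accuracy))
  expect_equal(attr(tr, "selected"), tr$feature[seq_len(attr(tr, "selected_size"))])
})

test_that("a single candidate yields a one-step trace; selection is seed-reproducible", {
  feat <- make_blobs(15, 15, d = 3, seed = 5)
  tr1 <- sfs_select(feat, "f01", trees = 20, seed = 7)
  expect_equal(nrow(tr1), 1)
  expect_equal(attr(tr1, "selected_size"), 1L)

  tr_a <- sfs_select(feat, feature_cols(feat), trees = 20, seed = 7, cap = 2)
  tr_b <- sfs_select(feat, feature_cols(feat), trees = 20, seed = 7, cap = 2)
  expect_identical(tr_a, tr_b)
  expect_error(sfs_select(feat, feature_cols(feat), cap = 0), "cap")
  expect_error(sfs_select(feat, "nope"), "unknown")
})

test_that("the two-step selector filters by score > 0 then wraps SFS over the retained set", {
  feat <- make_blobs(20, 20, d = 5, n_informative = 2, shift = 3, seed = 9)
  out <- select_features(feat, relief_k = 3, trees = 30, cap = 3, seed = 4)
  expect_true(all(out$ranking$score[match(out$selected, out$ranking$feature)] > 0))
  expect_lte(length(out$selected), 3)
  expect_equal(out$selected, attr(out$trace, "selected"))
})
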