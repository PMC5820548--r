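#' ReliefF feature relevance scores
#'
#' Scores each feature by how well it separates nearest neighbours of the
#' opposite class (misses) from nearest neighbours of the same class
#' (hits): a feature's score accumulates `diff(f, x, miss) - diff(f, x, hit)`
#' averaged over the sampled instances and their `k` nearest hits and
#' misses, with `diff` the absolute difference normalized by the feature's
#' range. Features are min-max scaled internally for the neighbour search.
#' Constant features score exactly 0; the retained subset is every feature
#' with score strictly greater than 0.
#'
#' @param features Feature tibble (`id`, `label`, optional `synthetic`,
#'   feature columns). Two classes required, at least 2 samples per class.
#' @param k Nearest hits/misses per instance (default 10, truncated when a
#'   class is small).
#' @param m Number of instances to sample (default `NULL` = all instances,
#'   in order).
#' @param seed Seed used only when `m` is smaller than the number of rows.
#' @return A `relief_ranking` tibble with columns `feature`, `score`,
#'   `rank` (1 = most relevant; ties broken by column order) and `retained`
#'   (`score > 0`), ordered by rank.
#' @export
relief_scores <- function(features, k = 10, m = NULL, seed = 1) {
  fcols <- feature_cols(features)
  y <- features$label
  if (length(unique(y)) != 2) abort("ReliefF needs exactly two classes")
  if (min(table(y)) < 2) abort("ReliefF needs at least 2 samples per class")
  X <- as.matrix(features[, fcols])
  n <- nrow(X)

  rng <- apply(X, 2, function(x) diff(range(x)))
  denom <- ifelse(rng == 0, 1, rng) # constant features contribute diff 0
  Xs <- sweep(sweep(X, 2, apply(X, 2, min)), 2, denom, "/")

  if (is.null(m) || m >= n) {
    picks <- seq_len(n)
  } else {
    set.seed(seed)
    picks <- sample(n, m)
  }
  D <- as.matrix(stats::dist(Xs))

  score <- numeric(length(fcols))
  for (i in picks) {
    same <- which(y == y[i])
    same <- same[same != i]
    opp <- which(y != y[i])
    kh <- min(k, length(same))
    km <- min(k, length(opp))
    hits <- same[order(D[i, same])][seq_len(kh)]
    misses <- opp[order(D[i, opp])][seq_len(km)]
    dh <- abs(sweep(Xs[hits, , drop = FALSE], 2, Xs[i, ]))
    dm <- abs(sweep(Xs[misses, , drop = FALSE], 2, Xs[i, ]))
    score <- score + colMeans(dm) - colMeans(dh)
  }
  score <- score / length(picks)

  out <- tibble::tibble(
    feature = fcols,
    score = unname(score),
    rank = rank(-score, ties.method = "first"),
    retained = score > 0
  )
  out <- dplyr::arrange(out, .data$rank)
  class(out) <- c("relief_ranking", class(out))
  out
}

#' Sequential forward selection over a candidate feature list
#'
#' Greedy wrapper: starting from the empty set, at each step add the
#' candidate feature whose addition maximizes cross-validated classifier
#' accuracy on the current set. Fold splits are fixed once and reused
#' across every step and candidate so accuracies are comparable. Ties are
#' broken in candidate order (i.e. by ReliefF rank when candidates come
#' from [relief_scores()]), then by lower index.
#'
#' @param features Feature tibble.
#' @param candidates Character vector of candidate feature names, in
#'   priority order (typically the retained, rank-ordered ReliefF subset).
#' @param folds Cross-validation folds for the wrapped evaluator (default 5).
#' @param trees Random-Forest trees in the evaluator (default 100).
#' @param cap Maximum number of features to add (default all candidates).
#' @param seed Seed fixing the fold split and each forest.
#' @return An `sfs_trace` tibble with columns `step`, `feature`,
#'   `cv_accuracy`, plus attributes `selected` (character vector: the
#'   shortest prefix attaining the maximum accuracy) and `selected_size`.
#' @export
sfs_select <- function(features, candidates, folds = 5, trees = 100,
                       cap = Inf, seed = 1) {
  if (length(candidates) == 0) abort("candidates must be non-empty")
  if (cap < 1) abort("cap must be >= 1")
  missing <- setdiff(candidates, feature_cols(features))
  if (length(missing) > 0) {
    abort(sprintf("unknown candidate features: %s", paste(missing, collapse = ", ")))
  }
  y <- factor(features$label, levels = c(0, 1))
  fold_id <- make_folds(features$label, folds = folds, seed = seed)

  chosen <- character(0)
  remaining <- candidates
  trace <- list()
  step <- 0L
  while (length(remaining) > 0 && step < cap) {
    step <- step + 1L
    accs <- vapply(remaining, function(f) {
      X <- as.data.frame(features[, c(chosen, f)])
      cv_accuracy_rf(X, y, fold_id, trees = trees, seed = seed)
    }, numeric(1))
    best <- which.max(accs) # first max -> candidate-order tie-break
    chosen <- c(chosen, remaining[best])
    trace[[step]] <- tibble::tibble(
      step = step,
      feature = remaining[best],
      cv_accuracy = accs[[best]]
    )
    remaining <- remaining[-best]
  }
  out <- dplyr::bind_rows(trace)
  sel_size <- which.max(out$cv_accuracy) # shortest prefix at the max
  attr(out, "selected") <- out$feature[seq_len(sel_size)]
  attr(out, "selected_size") <- sel_size
  class(out) <- c("sfs_trace", class(out))
  out
}

# 5-fold accuracy of a Random Forest on fixed folds; deterministic per seed
cv_accuracy_rf <- function(X, y, fold_id, trees, seed) {
  correct <- 0L
  for (f in sort(unique(fold_id))) {
    tr <- fold_id != f
    set.seed(seed + f)
    fit <- randomForest::randomForest(
      x = X[tr, , drop = FALSE], y = y[tr], ntree = trees
    )
    pred <- predict(fit, X[!tr, , drop = FALSE])
    correct <- correct + sum(pred == y[!tr])
  }
  correct / length(y)
}

#' Two-step feature selection: ReliefF filter then SFS wrapper
#'
#' Step 1 ranks features by ReliefF and retains those with score > 0;
#' step 2 runs sequential forward selection over the retained features in
#' rank order and returns the accuracy-maximizing prefix.
#'
#' @inheritParams relief_scores
#' @inheritParams sfs_select
#' @param relief_k,relief_m ReliefF neighbour count and sample size.
#' @return List with `ranking` (the `relief_ranking`), `trace` (the
#'   `sfs_trace`) and `selected` (character vector of selected features).
#' @export
select_features <- function(features, relief_k = 10, relief_m = NULL,
                            folds = 5, trees = 100, cap = Inf, seed = 1) {
  ranking <- relief_scores(features, k = relief_k, m = relief_m, seed = seed)
  retained <- ranking$feature[ranking$retained]
  if (length(retained) == 0) {
    abort("no features passed the ReliefF score > 0 filter")
  }
  trace <- sfs_select(
    features, retained,
    folds = folds, trees = trees, cap = cap, seed = seed
  )
  list(ranking = ranking, trace = trace, selected = attr(trace, "selected"))
}
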