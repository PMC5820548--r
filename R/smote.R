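#' Balance classes by SMOTE oversampling of the minority class
#'
#' Appends synthetic minority-class rows until both classes have equal
#' counts. Each synthetic point is `x + u * (x_nn - x)` with `u` uniform
#' on \[0, 1\], `x` a minority sample and `x_nn` one of its `k` nearest
#' minority neighbours under Euclidean distance, so every synthetic point
#' lies on a segment between two real minority points. Base samples are
#' cycled in a seeded random order; for each, one of its `k` neighbours is
#' drawn uniformly.
#'
#' @param features Feature tibble (`id`, `label`, feature columns).
#' @param k Number of nearest minority neighbours (default 5); must be
#'   smaller than the minority class size.
#' @param seed Integer seed; the result is deterministic given the seed.
#' @param standardize If `TRUE`, z-score features for the neighbour search
#'   only (synthetic values are still interpolated on the raw scale).
#'   Default `FALSE`: raw-feature distances.
#' @return Feature tibble with a logical `synthetic` column; original rows
#'   first and unchanged, synthetic rows appended with ids
#'   `smote_<base id>_<serial>` and the minority label.
#' @export
smote_balance <- function(features, k = 5, seed = 1, standardize = FALSE) {
  labels <- features$label
  tab <- table(factor(labels, levels = sort(unique(labels))))
  if (length(tab) != 2) abort("SMOTE needs exactly two classes")

  out <- features
  out$synthetic <- rep(FALSE, nrow(features))
  n_needed <- abs(tab[[1]] - tab[[2]])
  if (n_needed == 0) {
    return(out[, c("id", "label", "synthetic", feature_cols(features))])
  }

  minority <- as.integer(names(tab)[which.min(tab)])
  min_idx <- which(labels == minority)
  if (length(min_idx) <= k) {
    abort(sprintf(
      "minority class has %d samples; needs > k = %d (use a smaller k)",
      length(min_idx), k
    ))
  }

  fcols <- feature_cols(features)
  X <- as.matrix(features[min_idx, fcols])
  if (any(!is.finite(X))) abort("features must be finite for SMOTE")
  Xd <- if (standardize) {
    scale(X, center = TRUE, scale = apply(X, 2, function(x) {
      s <- sd(x)
      if (s == 0) 1 else s
    }))
  } else {
    X
  }
  nn <- knn_index(Xd, k)

  rng <- local({
    set.seed(seed)
    list(
      order = sample(nrow(X)),
      nn_pick = sample.int(k, n_needed, replace = TRUE),
      u = runif(n_needed)
    )
  })
  base <- rng$order[((seq_len(n_needed) - 1) %% nrow(X)) + 1]

  neigh <- nn[cbind(base, rng$nn_pick)]
  synth <- X[base, , drop = FALSE] + rng$u * (X[neigh, , drop = FALSE] - X[base, , drop = FALSE])

  synth_tbl <- tibble::as_tibble(synth, .name_repair = "minimal")
  names(synth_tbl) <- fcols
  synth_tbl <- dplyr::bind_cols(
    tibble::tibble(
      id = sprintf("smote_%s_%d", features$id[min_idx][base], seq_len(n_needed)),
      label = minority,
      synthetic = TRUE
    ),
    synth_tbl
  )
  dplyr::bind_rows(out[, c("id", "label", "synthetic", fcols)], synth_tbl)
}

# k nearest neighbours (excluding self) per row, Euclidean; minority
# classes here are a few hundred rows, so the full distance matrix is fine
knn_index <- function(X, k) {
  D <- as.matrix(stats::dist(X))
  diag(D) <- Inf
  idx <- apply(D, 1, function(d) order(d)[seq_len(k)])
  if (k == 1) matrix(idx, ncol = 1) else t(idx)
}
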