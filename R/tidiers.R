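#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Per-fold metrics of an evaluation
#'
#' @param x An `eval_report`.
#' @param ... Ignored.
#' @return Tibble with one row per fold: `fold`, `sn`, `sp`, `acc`, `mcc`.
#' @export
tidy.eval_report <- function(x, ...) {
  x$per_fold
}

#' One-row summary of an evaluation
#'
#' @param x An `eval_report`.
#' @param ... Ignored.
#' @return One-row tibble: pooled `sn`, `sp`, `acc`, `mcc`, `auc` plus the
#'   classifier, fold count, SMOTE mode and seed.
#' @export
glance.eval_report <- function(x, ...) {
  dplyr::bind_cols(
    x$pooled,
    tibble::tibble(
      classifier = x$config$classifier,
      folds = x$config$folds,
      smote = x$config$smote,
      seed = x$config$seed
    )
  )
}

#' @export
tidy.sfs_trace <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @export
glance.sfs_trace <- function(x, ...) {
  tibble::tibble(
    selected_size = attr(x, "selected_size"),
    best_accuracy = max(x$cv_accuracy),
    candidates_tried = nrow(x)
  )
}
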