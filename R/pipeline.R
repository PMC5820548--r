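#' Run the full prediction pipeline
#'
#' Orchestrates encode -> balance -> select -> train/evaluate over a pair
#' of labelled FASTA files, writing every stage's output plus a manifest
#' into `outdir`. All stage outputs are pure functions of the inputs, the
#' configuration and the seed, so re-running with the same manifest
#' reproduces them.
#'
#' Files written: `features.csv` (the encoded matrix), `balanced.csv`
#' (after SMOTE, when enabled), `relief.tsv`, `sfs_trace.tsv`,
#' `selection_curve.pdf`, `report.json`, `roc.tsv`, `roc.pdf`,
#' `manifest.json`.
#'
#' @inheritParams read_dataset
#' @inheritParams encode_dataset
#' @param outdir Output directory, created if needed.
#' @param smote SMOTE placement: `"pre_split"` (default; balance the full
#'   matrix before selection and cross-validation, the published
#'   procedure), `"per_fold"` (balance training folds only) or `"off"`.
#' @param smote_k SMOTE neighbour count.
#' @param relief_k ReliefF neighbour count.
#' @param sfs_cap Maximum features added during forward selection
#'   (default all retained candidates).
#' @param folds,trees Cross-validation folds and forest size.
#' @param select Run the two-step feature selection (default `TRUE`);
#'   when `FALSE` the evaluation uses all encoded features.
#' @param seed Global seed.
#' @return Invisibly, a list with `features`, `balanced`, `selection`,
#'   `report` and `outdir`.
#' @export
run_pipeline <- function(positives, negatives,
                         pssm_dir = NULL, disorder_dir = NULL,
                         outdir,
                         views = c("ctd", "pseaac", "pssm", "disorder"),
                         nonstandard = "drop",
                         lambda = 50, w = 0.15, gamma = 5,
                         disorder_threshold = 0.5,
                         transition_denominator = "L",
                         smote = c("pre_split", "per_fold", "off"),
                         smote_k = 5, relief_k = 10, sfs_cap = Inf,
                         folds = 5, trees = 100, select = TRUE, seed = 1) {
  smote <- match.arg(smote)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  records <- stage("read", read_dataset(positives, negatives, nonstandard = nonstandard))
  features <- stage("encode", encode_dataset(
    records,
    views = views, pssm_dir = pssm_dir, disorder_dir = disorder_dir,
    lambda = lambda, w = w, gamma = gamma,
    disorder_threshold = disorder_threshold,
    transition_denominator = transition_denominator
  ))
  write_feature_matrix(features, file.path(outdir, "features.csv"))

  working <- features
  if (smote == "pre_split") {
    working <- stage("balance", smote_balance(features, k = smote_k, seed = seed))
    write_feature_matrix(working, file.path(outdir, "balanced.csv"))
  }

  selection <- NULL
  eval_features <- working
  if (select) {
    selection <- stage("select", select_features(
      working,
      relief_k = relief_k, folds = folds, trees = trees,
      cap = sfs_cap, seed = seed
    ))
    readr::write_tsv(selection$ranking, file.path(outdir, "relief.tsv"))
    readr::write_tsv(
      tidy(selection$trace), file.path(outdir, "sfs_trace.tsv")
    )
    ggplot2::ggsave(
      file.path(outdir, "selection_curve.pdf"),
      autoplot(selection$trace), width = 6, height = 4
    )
    keep <- c("id", "label", intersect("synthetic", names(working)), selection$selected)
    eval_features <- working[, keep]
  }

  report <- stage("evaluate", cross_validate(
    eval_features,
    folds = folds, classifier = "rf", trees = trees,
    smote = if (smote == "per_fold") "per_fold" else "off",
    smote_k = smote_k, seed = seed
  ))
  readr::write_tsv(report$roc, file.path(outdir, "roc.tsv"))
  ggplot2::ggsave(file.path(outdir, "roc.pdf"), autoplot(report), width = 5, height = 5)

  jsonlite::write_json(
    list(
      pooled = as.list(report$pooled),
      per_fold = report$per_fold,
      counts = as.list(report$counts),
      config = report$config,
      selected_features = selection$selected %||% feature_cols(eval_features)
    ),
    file.path(outdir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  jsonlite::write_json(
    list(
      package = "lectinpred",
      version = as.character(utils::packageVersion("lectinpred")),
      r_version = R.version.string,
      seed = seed,
      inputs = list(
        positives = positives, negatives = negatives,
        pssm_dir = pssm_dir, disorder_dir = disorder_dir
      ),
      config = list(
        views = views, nonstandard = nonstandard, lambda = lambda, w = w,
        gamma = gamma, disorder_threshold = disorder_threshold,
        transition_denominator = transition_denominator, smote = smote,
        smote_k = smote_k, relief_k = relief_k, sfs_cap = sfs_cap,
        folds = folds, trees = trees, select = select
      )
    ),
    file.path(outdir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )

  invisible(list(
    features = features, balanced = working,
    selection = selection, report = report, outdir = outdir
  ))
}
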