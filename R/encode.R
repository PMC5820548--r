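#' Encode a labelled dataset into the multiview feature matrix
#'
#' Runs the requested feature views over every record and assembles the
#' feature tibble. With all four views at default parameters each record
#' yields 147 (CTD) + 70 (PseAAC) + 120 (PSSM) + 28 (disorder) = 365
#' features, in that fixed column order.
#'
#' @param records Tibble with columns `id`, `sequence`, `label`
#'   (from [read_dataset()] or [simulate_dataset()]).
#' @param views Character subset of `c("ctd", "pseaac", "pssm", "disorder")`;
#'   views are encoded and laid out in this canonical order regardless of
#'   the order given.
#' @param pssm_dir Directory holding one PSI-BLAST ASCII PSSM per record,
#'   named `<id>.pssm`. Required when the `"pssm"` view is requested.
#' @param disorder_dir Directory holding one disorder TSV per record,
#'   named `<id>.diso`. Required when the `"disorder"` view is requested.
#' @param lambda,w Classical PseAAC parameters (defaults 50 and 0.15).
#' @param gamma PsePSSM maximum lag (default 5).
#' @param disorder_threshold Segmentation threshold (default 0.5).
#' @param transition_denominator `"L"` (as printed) or `"L-1"` for the CTD
#'   transition block.
#' @param missing_profile What to do when a record has no PSSM file:
#'   `"skip"` (default) drops the record with a warning; `"pseudo"`
#'   substitutes a sequence-derived pseudo-profile built from BLOSUM62
#'   rows (an approximation, logged per record).
#' @param missing_disorder What to do when a record has no disorder file:
#'   `"skip"` (default) or `"neutral"` (all scores 0.5, logged).
#' @return Feature tibble: `id`, `label`, then one numeric column per
#'   feature; row order follows `records` (minus skipped records).
#' @export
encode_dataset <- function(records,
                           views = c("ctd", "pseaac", "pssm", "disorder"),
                           pssm_dir = NULL, disorder_dir = NULL,
                           lambda = 50, w = 0.15, gamma = 5,
                           disorder_threshold = 0.5,
                           transition_denominator = c("L", "L-1"),
                           missing_profile = c("skip", "pseudo"),
                           missing_disorder = c("skip", "neutral")) {
  views <- intersect(c("ctd", "pseaac", "pssm", "disorder"), match.arg(
    views, c("ctd", "pseaac", "pssm", "disorder"), several.ok = TRUE
  ))
  if (length(views) == 0) abort("at least one feature view is required")
  transition_denominator <- match.arg(transition_denominator)
  missing_profile <- match.arg(missing_profile)
  missing_disorder <- match.arg(missing_disorder)
  if ("pssm" %in% views && is.null(pssm_dir) && missing_profile == "skip") {
    abort("pssm view requested but no pssm_dir given")
  }
  if ("disorder" %in% views && is.null(disorder_dir) && missing_disorder == "skip") {
    abort("disorder view requested but no disorder_dir given")
  }

  skipped <- character(0)
  rows <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    id <- records$id[i]
    seq <- records$sequence[i]
    parts <- list()
    if ("ctd" %in% views) {
      parts$ctd <- encode_ctd(seq, denominator = transition_denominator)
    }
    if ("pseaac" %in% views) {
      parts$pseaac <- encode_pseaac(seq, lambda = lambda, w = w)
    }
    if ("pssm" %in% views) {
      pfile <- if (is.null(pssm_dir)) "" else file.path(pssm_dir, paste0(id, ".pssm"))
      if (nzchar(pfile) && file.exists(pfile)) {
        prof <- parse_pssm(pfile)
        if (prof$residues != seq) {
          abort(sprintf("PSSM residues for '%s' do not match the FASTA sequence", id))
        }
      } else if (missing_profile == "pseudo") {
        inform(sprintf("no PSSM for '%s'; using BLOSUM62 pseudo-profile", id))
        prof <- pseudo_profile(seq)
      } else {
        skipped <- c(skipped, id)
        next
      }
      parts$pssm <- encode_profile(prof, gamma = gamma)
    }
    if ("disorder" %in% views) {
      dfile <- if (is.null(disorder_dir)) "" else file.path(disorder_dir, paste0(id, ".diso"))
      if (nzchar(dfile) && file.exists(dfile)) {
        scores <- read_disorder(dfile, expected_length = nchar(seq))
      } else if (missing_disorder == "neutral") {
        inform(sprintf("no disorder track for '%s'; using neutral 0.5 scores", id))
        scores <- rep(0.5, nchar(seq))
      } else {
        skipped <- c(skipped, id)
        next
      }
      parts$disorder <- encode_disorder(scores, seq, threshold = disorder_threshold)
    }
    rows[[i]] <- do.call(c, unname(parts))
  }

  keep <- !vapply(rows, is.null, logical(1))
  if (!any(keep)) abort("no records could be encoded")
  if (length(skipped) > 0) {
    warn(sprintf(
      "skipped %d record(s) without profile/disorder input: %s",
      length(skipped), paste(unique(skipped), collapse = ", ")
    ))
  }
  m <- do.call(rbind, rows[keep])
  dplyr::bind_cols(
    tibble::tibble(id = records$id[keep], label = records$label[keep]),
    tibble::as_tibble(m, .name_repair = "minimal")
  )
}

# Sequence-derived stand-in for a missing PSSM: the BLOSUM62 row of each
# observed residue, restricted to the 20 natural amino acids. Coarser than
# a real PSI-BLAST profile (no position-specific conservation), and said so
# wherever it is offered.
pseudo_profile <- function(sequence) {
  blosum <- blosum62_matrix()
  res <- strsplit(sequence, "")[[1]]
  scores <- blosum[res, , drop = FALSE]
  rownames(scores) <- NULL
  structure(
    list(residues = sequence, scores = scores),
    class = "profile_matrix"
  )
}

blosum62_matrix <- function() {
  if (is.null(the$blosum62)) {
    if (!requireNamespace("Biostrings", quietly = TRUE)) {
      abort("the BLOSUM62 pseudo-profile fallback needs the Biostrings package")
    }
    env <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = env)
    m <- env$BLOSUM62[AA_ALPHABET, AA_ALPHABET]
    the$blosum62 <- m
  }
  the$blosum62
}
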