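#' Read labelled protein sequences from FASTA
#'
#' Reads a multi-record FASTA file and attaches a single binary class label
#' to every record (1 = positive class, e.g. cancerlectin; 0 = negative).
#' Sequences are upper-cased and sanitized to the 20-letter amino-acid
#' alphabet before any encoder sees them.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped lines).
#' @param label Binary class label (0 or 1) applied to every record in the
#'   file. Labels are per-file because the benchmark datasets ship as one
#'   FASTA of positives and one of negatives.
#' @param nonstandard Policy for residues outside the 20-letter alphabet
#'   (B, Z, X, U, O, J): `"drop"` (default) deletes them with a warning
#'   counting removals per record; `"strict"` rejects any record containing
#'   one.
#' @return A tibble with columns `id`, `sequence`, `label`, one row per
#'   FASTA record, in file order.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1", "ACDEFGHIKLMNPQRSTVWY"), fa)
#' read_fasta(fa, label = 1)
#' @export
read_fasta <- function(path, label, nonstandard = c("drop", "strict")) {
  nonstandard <- match.arg(nonstandard)
  stopifnot(length(label) == 1, label %in% c(0L, 1L))
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))

  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0) abort(sprintf("empty FASTA file: %s", path))
  first <- nonblank[1]
  if (!startsWith(trimws(lines[first]), ">")) {
    abort(sprintf(
      "malformed FASTA: line %d of %s does not start a '>' header", first, path
    ))
  }

  headers <- grepl("^>", lines)
  idx <- cumsum(headers)
  ids <- sub("^>\\s*", "", lines[headers])
  ids <- sub("\\s.*$", "", ids) # id = first whitespace-delimited token
  seqs <- vapply(
    split(lines[!headers], idx[!headers]),
    function(x) paste(gsub("\\s", "", x), collapse = ""),
    character(1)
  )
  # headers with no sequence lines at all
  seqs <- unname(seqs[match(seq_along(ids), as.integer(names(seqs)))])
  seqs[is.na(seqs)] <- ""
  seqs <- toupper(seqs)

  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    abort(sprintf(
      "duplicate FASTA ids in %s: %s", path, paste(dup, collapse = ", ")
    ))
  }

  records <- tibble::tibble(id = ids, sequence = seqs, label = as.integer(label))
  sanitize_records(records, nonstandard = nonstandard, source = path)
}

sanitize_records <- function(records, nonstandard = "drop", source = "input") {
  seqs <- records$sequence
  bad_char <- gsub(paste0("[", paste(AA_ALPHABET, collapse = ""), "]"), "", seqs)
  has_bad <- nzchar(bad_char)

  if (any(has_bad)) {
    unknown <- setdiff(
      unique(strsplit(paste(bad_char, collapse = ""), "")[[1]]),
      NONSTANDARD_AA
    )
    if (length(unknown) > 0) {
      abort(sprintf(
        "%s: characters %s are not amino-acid codes (records: %s)",
        source, paste(unknown, collapse = ""),
        paste(records$id[has_bad], collapse = ", ")
      ))
    }
    if (nonstandard == "strict") {
      abort(sprintf(
        "%s: non-standard residues in records %s (strict policy)",
        source, paste(records$id[has_bad], collapse = ", ")
      ))
    }
    counts <- nchar(bad_char[has_bad])
    warn(sprintf(
      "%s: dropped non-standard residues: %s",
      source,
      paste(sprintf("%s (%d)", records$id[has_bad], counts), collapse = ", ")
    ))
    seqs[has_bad] <- gsub(
      paste0("[^", paste(AA_ALPHABET, collapse = ""), "]"), "", seqs[has_bad]
    )
  }

  empty <- !nzchar(seqs)
  if (any(empty)) {
    abort(sprintf(
      "%s: records empty after sanitization: %s",
      source, paste(records$id[empty], collapse = ", ")
    ))
  }
  records$sequence <- seqs
  records
}

#' Read a labelled two-class dataset from a pair of FASTA files
#'
#' @param positives,negatives FASTA paths for the positive (label 1) and
#'   negative (label 0) class.
#' @inheritParams read_fasta
#' @return A tibble with columns `id`, `sequence`, `label`; positives first,
#'   then negatives, each in file order.
#' @export
read_dataset <- function(positives, negatives, nonstandard = c("drop", "strict")) {
  nonstandard <- match.arg(nonstandard)
  pos <- read_fasta(positives, label = 1L, nonstandard = nonstandard)
  neg <- read_fasta(negatives, label = 0L, nonstandard = nonstandard)
  records <- dplyr::bind_rows(pos, neg)
  dup <- unique(records$id[duplicated(records$id)])
  if (length(dup) > 0) {
    abort(sprintf(
      "ids occur in both classes: %s", paste(dup, collapse = ", ")
    ))
  }
  records
}

#' Columns of a feature tibble that hold feature values
#'
#' Feature tibbles carry the bookkeeping columns `id`, `label` and
#' (after SMOTE) `synthetic`; everything else is a numeric feature.
#'
#' @param features A feature tibble.
#' @return Character vector of feature column names, in column order.
#' @export
feature_cols <- function(features) {
  setdiff(names(features), c("id", "label", "synthetic"))
}

#' Write a feature matrix to CSV
#'
#' Layout: first column `id`, then one column per feature, then `label`
#' (and `synthetic` last when present). Doubles are written in full
#' precision so the file round-trips losslessly.
#'
#' @param features Feature tibble (`id`, `label`, optional `synthetic`,
#'   feature columns).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(features, path) {
  fcols <- feature_cols(features)
  if (anyDuplicated(fcols)) abort("feature column names must be unique")
  ord <- c("id", fcols, "label", intersect("synthetic", names(features)))
  readr::write_csv(features[, ord], path)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param path CSV path.
#' @return Feature tibble with `id`, `label` (and `synthetic` if present)
#'   first, then feature columns.
#' @export
read_feature_matrix <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("id", "label") %in% names(tbl))) {
    abort(sprintf("%s is not a feature-matrix CSV (needs id and label columns)", path))
  }
  tbl$label <- as.integer(tbl$label)
  meta <- c("id", "label", intersect("synthetic", names(tbl)))
  tbl[, c(meta, setdiff(names(tbl), meta))]
}
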