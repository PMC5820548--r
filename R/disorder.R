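#' Read a per-residue disorder track
#'
#' Reads a tab-separated file with columns (position, residue, score),
#' one row per residue, scores in \[0, 1\] as produced by per-residue
#' disorder predictors such as VSL2.
#'
#' @param path Path to the TSV file.
#' @param expected_length Sequence length the track must match.
#' @return Numeric vector of `expected_length` disorder scores.
#' @export
read_disorder <- function(path, expected_length) {
  if (!file.exists(path)) abort(sprintf("disorder file not found: %s", path))
  tbl <- utils::read.table(
    path, sep = "\t", header = FALSE,
    col.names = c("position", "residue", "score"),
    colClasses = c("integer", "character", "numeric")
  )
  if (nrow(tbl) != expected_length) {
    abort(sprintf(
      "%s: %d rows but sequence length is %d", path, nrow(tbl), expected_length
    ))
  }
  if (!identical(tbl$position, seq_len(nrow(tbl)))) {
    abort(sprintf("%s: positions are not contiguous 1..L", path))
  }
  bad <- which(tbl$score < 0 | tbl$score > 1 | is.na(tbl$score))
  if (length(bad) > 0) {
    abort(sprintf("%s: row %d: score outside [0, 1]", path, bad[1]))
  }
  tbl$score
}

#' Write a disorder track (fixture/round-trip helper)
#'
#' @param scores Numeric vector in \[0, 1\].
#' @param sequence Amino-acid string of matching length.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_disorder <- function(scores, sequence, path) {
  stopifnot(length(scores) == nchar(sequence))
  utils::write.table(
    data.frame(
      position = seq_along(scores),
      residue = strsplit(sequence, "")[[1]],
      score = formatC(scores, format = "f", digits = 6)
    ),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

# maximal runs of (score >= threshold); returns lengths of disordered and
# ordered segments
disorder_segments <- function(scores, threshold) {
  state <- scores >= threshold
  r <- rle(state)
  list(
    disordered = r$lengths[r$values],
    ordered = r$lengths[!r$values]
  )
}

#' Encode a disorder track as 28 summary features
#'
#' Features, in fixed order: mean and (population) standard deviation of
#' all scores (2); number of disordered and ordered segments (2), where a
#' segment is a maximal run of residues at or above / below the threshold;
#' min and max disordered-segment length and min and max ordered-segment
#' length (4), 0 when no segment of that kind exists; mean disorder score
#' of each of the 20 amino acids (20), 0 for residues absent from the
#' sequence.
#'
#' @param scores Numeric disorder scores in \[0, 1\].
#' @param sequence Amino-acid string of the same length.
#' @param threshold Disorder decision boundary (default 0.5, the VSL2
#'   convention); a residue is disordered when `score >= threshold`.
#' @return Named numeric 28-vector (`diso.mean`, `diso.sd`, `diso.nseg.d`,
#'   `diso.nseg.o`, `diso.minlen.d`, `diso.maxlen.d`, `diso.minlen.o`,
#'   `diso.maxlen.o`, `diso.aamean.<res>`).
#' @export
encode_disorder <- function(scores, sequence, threshold = 0.5) {
  L <- nchar(sequence)
  if (length(scores) != L) {
    abort(sprintf("disorder track length %d != sequence length %d", length(scores), L))
  }
  if (threshold <= 0 || threshold >= 1) abort("threshold must be in (0, 1)")
  seg <- disorder_segments(scores, threshold)
  seg_stat <- function(x, f) if (length(x) == 0) 0 else f(x)
  res <- strsplit(sequence, "")[[1]]
  aamean <- vapply(AA_ALPHABET, function(a) {
    s <- scores[res == a]
    if (length(s) == 0) 0 else mean(s)
  }, numeric(1))
  v <- c(
    mean(scores),
    sqrt(mean((scores - mean(scores))^2)),
    length(seg$disordered),
    length(seg$ordered),
    seg_stat(seg$disordered, min),
    seg_stat(seg$disordered, max),
    seg_stat(seg$ordered, min),
    seg_stat(seg$ordered, max),
    aamean
  )
  names(v) <- c(
    "diso.mean", "diso.sd", "diso.nseg.d", "diso.nseg.o",
    "diso.minlen.d", "diso.maxlen.d", "diso.minlen.o", "diso.maxlen.o",
    paste0("diso.aamean.", AA_ALPHABET)
  )
  v
}
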