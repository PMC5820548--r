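#' Parse a PSI-BLAST ASCII PSSM file
#'
#' Reads the `-out_ascii_pssm` dialect: header lines, one row per residue
#' holding the position, the residue letter and 20 log-odds integers (the
#' first numeric block), then trailing statistics. The second 20-column
#' weighted-percentage block and the K/lambda lines are ignored. Columns
#' are remapped from the file's header order to the canonical alphabetical
#' amino-acid order so feature names are stable across files.
#'
#' @param path Path to the PSSM file.
#' @return A `profile_matrix`: list with `residues` (length-L string) and
#'   `scores` (L x 20 integer matrix of raw log-odds, columns named by
#'   residue in alphabetical order).
#' @export
parse_pssm <- function(path) {
  if (!file.exists(path)) abort(sprintf("PSSM file not found: %s", path))
  lines <- readLines(path, warn = FALSE)

  # column-order header: the line whose fields are >= 20 single letters
  header_at <- NA_integer_
  for (i in seq_along(lines)) {
    fields <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(fields) >= 20 && all(nchar(fields) == 1) &&
        all(fields %in% AA_ALPHABET)) {
      header_at <- i
      break
    }
  }
  if (is.na(header_at)) {
    abort(sprintf("%s: no PSSM column header found", path))
  }
  col_order <- strsplit(trimws(lines[header_at]), "\\s+")[[1]][1:20]
  if (anyDuplicated(col_order)) {
    abort(sprintf("%s: line %d: duplicated residues in column header", path, header_at))
  }

  residues <- character(0)
  rows <- list()
  expected_pos <- 1L
  for (i in (header_at + 1):length(lines)) {
    fields <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(fields) == 0 || is.na(suppressWarnings(as.integer(fields[1])))) {
      break # first trailing-statistics line ends the data block
    }
    pos <- as.integer(fields[1])
    if (pos != expected_pos) {
      abort(sprintf("%s: line %d: position %d, expected %d", path, i, pos, expected_pos))
    }
    if (length(fields) < 22) {
      abort(sprintf("%s: line %d: fewer than 20 score columns", path, i))
    }
    scores <- suppressWarnings(as.numeric(fields[3:22]))
    if (anyNA(scores) || any(scores != round(scores))) {
      abort(sprintf("%s: line %d: non-integer log-odds score", path, i))
    }
    residues[expected_pos] <- fields[2]
    rows[[expected_pos]] <- as.integer(scores)
    expected_pos <- expected_pos + 1L
  }
  if (length(rows) == 0) abort(sprintf("%s: no PSSM rows found", path))

  scores <- do.call(rbind, rows)
  colnames(scores) <- col_order
  scores <- scores[, AA_ALPHABET, drop = FALSE]
  structure(
    list(residues = paste(residues, collapse = ""), scores = scores),
    class = "profile_matrix"
  )
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf(
    "<profile_matrix> %d positions x 20 residues (raw log-odds %d..%d)\n",
    nrow(x$scores), min(x$scores), max(x$scores)
  ))
  invisible(x)
}

#' Sigmoid scaling of PSSM scores
#'
#' Maps raw log-odds scores elementwise into (0, 1) with the logistic
#' function 1 / (1 + exp(-x)).
#'
#' @param x Numeric matrix or vector of raw scores.
#' @return Object of the same shape with values in (0, 1).
#' @export
scale_sigmoid <- function(x) {
  1 / (1 + exp(-x))
}

#' PSSM amino-acid composition (20 features)
#'
#' Column means of the sigmoid-scaled profile: the average scaled
#' substitution score toward each residue type along the sequence.
#'
#' @param profile A `profile_matrix` from [parse_pssm()].
#' @return Named numeric 20-vector (`pssm.aac.<res>`), each value in (0, 1).
#' @export
pssm_aac <- function(profile) {
  v <- colMeans(scale_sigmoid(profile$scores))
  names(v) <- paste0("pssm.aac.", AA_ALPHABET)
  v
}

#' PsePSSM lagged autocovariance (20 x gamma features)
#'
#' For each residue column k of the sigmoid-scaled profile and each lag
#' j = 1..gamma, the autocovariance
#' (1/(L-j)) * sum_i (E_ik - mean_k)(E_(i+j)k - mean_k),
#' where mean_k is the column mean over the whole sequence. Captures
#' sequence-order information in the evolutionary profile.
#'
#' @inheritParams pssm_aac
#' @param gamma Maximum lag (default 5); must be < L.
#' @return Named numeric (20 * gamma)-vector in residue-major, lag-minor
#'   order (`psepssm.<res>.lag<j>`).
#' @export
pse_pssm <- function(profile, gamma = 5) {
  E <- scale_sigmoid(profile$scores)
  L <- nrow(E)
  if (gamma >= L) {
    abort(sprintf("PsePSSM with gamma = %d needs profile length >= %d (got %d)",
                  gamma, gamma + 1, L))
  }
  centered <- sweep(E, 2, colMeans(E))
  out <- numeric(20 * gamma)
  nms <- character(20 * gamma)
  pos <- 1L
  for (k in 1:20) {
    ck <- centered[, k]
    for (j in seq_len(gamma)) {
      out[pos] <- sum(ck[1:(L - j)] * ck[(1 + j):L]) / (L - j)
      nms[pos] <- paste0("psepssm.", AA_ALPHABET[k], ".lag", j)
      pos <- pos + 1L
    }
  }
  setNames(out, nms)
}

#' Encode a profile as the 120-dimensional evolutionary feature vector
#'
#' Concatenates PSSM-AAC (20) and PsePSSM (20 x gamma, 100 at the default
#' gamma = 5).
#'
#' @inheritParams pse_pssm
#' @return Named numeric vector of length 20 + 20 * gamma.
#' @export
encode_profile <- function(profile, gamma = 5) {
  c(pssm_aac(profile), pse_pssm(profile, gamma))
}
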