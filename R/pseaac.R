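#' Standardized residue indices for classical PseAAC
#'
#' Hydrophobicity, hydrophilicity and side-chain mass for the 20 amino
#' acids, each standardized to zero mean and unit (population) standard
#' deviation over the 20 residues. Raw values ship as a plain-text
#' resource with provenance notes.
#'
#' @return A 20 x 3 numeric matrix, rows named by residue, columns
#'   `hydrophobicity`, `hydrophilicity`, `mass`.
#' @export
pseaac_indices <- function() {
  if (is.null(the$pseaac_idx)) {
    tbl <- readr::read_tsv(
      lectinpred_extdata("pseaac_indices.tsv"),
      comment = "#", show_col_types = FALSE, progress = FALSE
    )
    stopifnot(identical(sort(tbl$residue), AA_ALPHABET))
    m <- as.matrix(tbl[, c("hydrophobicity", "hydrophilicity", "mass")])
    rownames(m) <- tbl$residue
    m <- m[AA_ALPHABET, ]
    # population standardization (divide by sqrt(mean squared deviation)),
    # the classical PseAAC convention
    m <- apply(m, 2, function(x) (x - mean(x)) / sqrt(mean((x - mean(x))^2)))
    the$pseaac_idx <- m
  }
  the$pseaac_idx
}

#' Sequence-order correlation factor of tier j
#'
#' theta_j = mean over residue pairs (i, i+j) of the average squared
#' difference of the three standardized indices:
#' (1/3)\[(H1_i - H1_(i+j))^2 + (H2_i - H2_(i+j))^2 + (M_i - M_(i+j))^2\].
#'
#' @param sequence Amino-acid string.
#' @param j Tier (lag), 1 <= j <= L-1.
#' @param indices Index matrix from [pseaac_indices()].
#' @return Non-negative scalar.
#' @export
tier_correlation <- function(sequence, j, indices = pseaac_indices()) {
  L <- nchar(sequence)
  if (j >= L) {
    abort(sprintf("tier %d needs sequence length >= %d (got %d)", j, j + 1, L))
  }
  res <- strsplit(sequence, "")[[1]]
  x <- indices[res, , drop = FALSE]
  d <- x[1:(L - j), , drop = FALSE] - x[(1 + j):L, , drop = FALSE]
  mean(rowMeans(d^2))
}

#' Encode a sequence as classical Pseudo Amino Acid Composition
#'
#' The (20 + lambda)-dimensional classical PseAAC: 20 amino-acid occurrence
#' frequencies plus lambda sequence-order correlation factors theta_j,
#' jointly normalized so all components sum to 1 with the order terms
#' weighted by `w`.
#'
#' @param sequence Amino-acid string of length >= `lambda + 1`.
#' @param lambda Number of correlation tiers (default 50).
#' @param w Weight of the sequence-order terms (default 0.15; valid range
#'   0.05-0.70, with `w = 0` allowed to recover plain composition).
#' @param indices Index matrix from [pseaac_indices()].
#' @return Named numeric (20 + lambda)-vector, names `pseaac.<res>` then
#'   `pseaac.theta<j>`; components are non-negative and sum to 1.
#' @export
encode_pseaac <- function(sequence, lambda = 50, w = 0.15,
                          indices = pseaac_indices()) {
  if (!(w == 0 || (w >= 0.05 && w <= 0.70))) {
    abort("w must be 0 or in [0.05, 0.70]")
  }
  if (lambda < 1) abort("lambda must be >= 1")
  L <- nchar(sequence)
  if (L <= lambda) {
    abort(sprintf(
      "PseAAC with lambda = %d needs sequence length >= %d (got %d)",
      lambda, lambda + 1, L
    ))
  }
  res <- strsplit(sequence, "")[[1]]
  f <- tabulate(match(res, AA_ALPHABET), nbins = 20) / L
  theta <- vapply(seq_len(lambda), function(j) {
    tier_correlation(sequence, j, indices)
  }, numeric(1))
  denom <- sum(f) + w * sum(theta)
  v <- c(f / denom, w * theta / denom)
  names(v) <- c(paste0("pseaac.", AA_ALPHABET), paste0("pseaac.theta", seq_len(lambda)))
  v
}
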