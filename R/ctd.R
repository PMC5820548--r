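#' Physicochemical groupings for CTD features
#'
#' Seven physicochemical properties, each partitioning the 20 amino acids
#' into three groups: hydrophobicity, normalized van der Waals volume,
#' polarity, polarizability, charge, secondary structure and solvent
#' accessibility. Shipped as a plain-text resource and validated on load.
#'
#' @return A tibble with columns `property`, `group1`, `group2`, `group3`
#'   (each group a string of residue letters).
#' @export
ctd_groupings <- function() {
  if (is.null(the$ctd_groups)) {
    tbl <- readr::read_tsv(
      lectinpred_extdata("ctd_groups.tsv"),
      show_col_types = FALSE, progress = FALSE
    )
    for (i in seq_len(nrow(tbl))) {
      all_res <- sort(strsplit(paste0(tbl$group1[i], tbl$group2[i], tbl$group3[i]), "")[[1]])
      if (!identical(all_res, AA_ALPHABET)) {
        abort(sprintf("CTD grouping '%s' does not partition the 20 amino acids", tbl$property[i]))
      }
    }
    the$ctd_groups <- tbl
  }
  the$ctd_groups
}

the <- new.env(parent = emptyenv())

# residue -> group index (1/2/3) under one property
group_index <- function(sequence, grouping) {
  res <- strsplit(sequence, "")[[1]]
  g <- integer(length(res))
  for (k in 1:3) {
    g[res %in% strsplit(grouping[[paste0("group", k)]], "")[[1]]] <- k
  }
  if (any(g == 0L)) abort("sequence contains residues outside the 20-letter alphabet")
  g
}

#' CTD composition block for one property
#'
#' Fraction of residues falling in each of the property's three groups:
#' (N1/L, N2/L, N3/L). Components sum to 1.
#'
#' @param sequence Amino-acid string (sanitized, length >= 1).
#' @param grouping One row of [ctd_groupings()] (data frame or list with
#'   `group1`..`group3`).
#' @return Numeric 3-vector of fractions.
#' @export
ctd_composition <- function(sequence, grouping) {
  if (nchar(sequence) < 1) abort("composition needs a non-empty sequence")
  g <- group_index(sequence, grouping)
  tabulate(g, nbins = 3) / length(g)
}

#' CTD transition block for one property
#'
#' Frequency of dipeptides whose two residues fall in different groups:
#' ((N12+N21)/L, (N13+N31)/L, (N23+N32)/L). The printed formula divides by
#' the sequence length L; `denominator = "L-1"` gives the conventional
#' dipeptide count instead.
#'
#' @inheritParams ctd_composition
#' @param denominator `"L"` (default, as printed) or `"L-1"`.
#' @return Numeric 3-vector (order: groups 1-2, 1-3, 2-3).
#' @export
ctd_transition <- function(sequence, grouping, denominator = c("L", "L-1")) {
  denominator <- match.arg(denominator)
  L <- nchar(sequence)
  if (L < 2) abort("transition needs a sequence of length >= 2")
  g <- group_index(sequence, grouping)
  a <- g[-L]
  b <- g[-1]
  cross <- function(i, j) sum((a == i & b == j) | (a == j & b == i))
  den <- if (denominator == "L") L else L - 1L
  c(cross(1, 2), cross(1, 3), cross(2, 3)) / den
}

#' CTD distribution block for one property
#'
#' For each group, the 1-based positions of its first residue and of the
#' residues at the 25%, 50%, 75% and 100% quantiles of its occurrences
#' (ceiling indexing), each divided by L. A group absent from the sequence
#' contributes five zeros.
#'
#' @inheritParams ctd_composition
#' @return Numeric 15-vector (5 values per group, groups in order).
#' @export
ctd_distribution <- function(sequence, grouping) {
  L <- nchar(sequence)
  if (L < 1) abort("distribution needs a non-empty sequence")
  g <- group_index(sequence, grouping)
  out <- numeric(15)
  for (k in 1:3) {
    pos <- which(g == k)
    n <- length(pos)
    if (n == 0) next
    idx <- c(1L, ceiling(c(0.25, 0.5, 0.75) * n), n)
    out[(k - 1) * 5 + 1:5] <- pos[idx] / L
  }
  out
}

#' Encode a sequence as the 147-dimensional CTD vector
#'
#' Concatenates composition (3), transition (3) and distribution (15)
#' blocks over the seven physicochemical properties: 7 x 21 = 147 features.
#'
#' @inheritParams ctd_transition
#' @return Named numeric 147-vector. Names follow
#'   `<property>.C.g<k>`, `<property>.T.g<i>g<j>`, `<property>.D.g<k>.<q>`
#'   with `q` in `first`, `q25`, `q50`, `q75`, `q100`.
#' @export
encode_ctd <- function(sequence, denominator = c("L", "L-1")) {
  denominator <- match.arg(denominator)
  groups <- ctd_groupings()
  blocks <- lapply(seq_len(nrow(groups)), function(i) {
    grp <- groups[i, ]
    v <- c(
      ctd_composition(sequence, grp),
      ctd_transition(sequence, grp, denominator),
      ctd_distribution(sequence, grp)
    )
    names(v) <- paste0(grp$property, ".", ctd_block_names())
    v
  })
  unlist(blocks)
}

ctd_block_names <- function() {
  c(
    paste0("C.g", 1:3),
    c("T.g1g2", "T.g1g3", "T.g2g3"),
    paste0(
      "D.g", rep(1:3, each = 5), ".",
      rep(c("first", "q25", "q50", "q75", "q100"), 3)
    )
  )
}
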