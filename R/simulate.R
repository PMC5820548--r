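#' Simulate a labelled protein dataset with companion PSSM and disorder files
#'
#' Generates two classes of protein sequences drawn i.i.d. from
#' class-specific residue-frequency profiles, a PSI-BLAST-style ASCII PSSM
#' per record, and a per-residue disorder track per record, then writes
#' them in the exact file dialects the readers expect. The positive class
#' is biased toward hydrophobic residues by `separation` (the extra
#' frequency mass moved onto C, F, I, L, M, V, W); `separation = 0` makes
#' the classes indistinguishable. Each PSSM elevates the raw log-odds at
#' the observed residue by `pssm_delta` over integer noise, and disorder
#' tracks are clipped moving averages (window 5) of uniform noise centred
#' on the class disorder mean. Everything is deterministic given the seed.
#'
#' @param n_pos,n_neg Records per class.
#' @param length_range Sequence length bounds; the minimum must be >= 56
#'   so every encoder's length precondition (lambda + 1 = 51 for PseAAC,
#'   gamma + 1 = 6 for PsePSSM) holds.
#' @param separation Frequency mass (0 to 0.5) shifted onto hydrophobic
#'   residues in the positive class.
#' @param pssm_delta Raw log-odds bonus at the observed residue.
#' @param pssm_noise SD of the integer noise added to every PSSM cell.
#' @param disorder_mean Length-2 numeric: mean disorder score of the
#'   positive and negative class.
#' @param seed Integer seed.
#' @param dir Output directory (created if needed; default a fresh temp
#'   directory). Files written: `positives.fasta`, `negatives.fasta`,
#'   `pssm/<id>.pssm`, `diso/<id>.diso`, `labels.tsv`.
#' @return A list with `records` (tibble `id`, `sequence`, `label`),
#'   `dir`, `positives`, `negatives`, `pssm_dir`, `disorder_dir`.
#' @export
simulate_dataset <- function(n_pos = 50, n_neg = 50,
                             length_range = c(56, 120),
                             separation = 0.2,
                             pssm_delta = 4, pssm_noise = 2,
                             disorder_mean = c(0.6, 0.4),
                             seed = 1,
                             dir = tempfile("lectinpred_sim_")) {
  if (length_range[1] < 56) abort("minimum simulated length is 56")
  if (separation < 0 || separation > 0.5) abort("separation must be in [0, 0.5]")
  if (n_pos < 1 || n_neg < 1) abort("need at least one record per class")

  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pssm_dir <- file.path(dir, "pssm")
  diso_dir <- file.path(dir, "diso")
  dir.create(pssm_dir, showWarnings = FALSE)
  dir.create(diso_dir, showWarnings = FALSE)

  profiles <- class_profiles(separation)
  set.seed(seed)
  recs <- list()
  i <- 0L
  for (cls in c(1L, 0L)) {
    n <- if (cls == 1L) n_pos else n_neg
    prof <- if (cls == 1L) profiles$pos else profiles$neg
    dmean <- if (cls == 1L) disorder_mean[1] else disorder_mean[2]
    prefix <- if (cls == 1L) "pos" else "neg"
    for (j in seq_len(n)) {
      i <- i + 1L
      id <- sprintf("%s%03d", prefix, j)
      L <- sample(length_range[1]:length_range[2], 1)
      seq <- paste(sample(AA_ALPHABET, L, replace = TRUE, prob = prof), collapse = "")
      write_synthetic_pssm(
        seq, file.path(pssm_dir, paste0(id, ".pssm")),
        delta = pssm_delta, noise = pssm_noise
      )
      write_disorder(
        simulate_disorder_track(L, dmean), seq,
        file.path(diso_dir, paste0(id, ".diso"))
      )
      recs[[i]] <- tibble::tibble(id = id, sequence = seq, label = cls)
    }
  }
  records <- dplyr::bind_rows(recs)

  pos_path <- file.path(dir, "positives.fasta")
  neg_path <- file.path(dir, "negatives.fasta")
  write_fasta(records[records$label == 1L, ], pos_path)
  write_fasta(records[records$label == 0L, ], neg_path)
  utils::write.table(
    records[, c("id", "label")], file.path(dir, "labels.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )

  list(
    records = records, dir = dir,
    positives = pos_path, negatives = neg_path,
    pssm_dir = pssm_dir, disorder_dir = diso_dir
  )
}

#' Simulate an imbalanced dataset
#'
#' Convenience wrapper around [simulate_dataset()] mirroring an imbalanced
#' benchmark: of `n` total records, `round(ratio * n)` are positives (the
#' minority) and the rest negatives.
#'
#' @param n Total number of records.
#' @param ratio Minority (positive-class) fraction, in (0, 0.5).
#' @param smote_k The SMOTE neighbour count the dataset must support; an
#'   error is raised when the minority would have fewer than `smote_k + 1`
#'   members.
#' @param ... Passed to [simulate_dataset()].
#' @return As [simulate_dataset()].
#' @export
make_imbalanced <- function(n, ratio, smote_k = 5, ...) {
  if (ratio <= 0 || ratio >= 0.5) abort("ratio must be in (0, 0.5)")
  n_min <- round(ratio * n)
  if (n_min < smote_k + 1) {
    abort(sprintf(
      "ratio %.3f leaves %d minority samples; need at least %d for k = %d",
      ratio, n_min, smote_k + 1, smote_k
    ))
  }
  simulate_dataset(n_pos = n_min, n_neg = n - n_min, ...)
}

# positive class gets `separation` extra frequency mass on hydrophobic
# residues, taken proportionally from the rest; negative class is uniform
class_profiles <- function(separation) {
  base <- rep(1 / 20, 20)
  names(base) <- AA_ALPHABET
  hydro <- c("C", "F", "I", "L", "M", "V", "W")
  pos <- base
  pos[hydro] <- pos[hydro] + separation / length(hydro)
  pos[!names(pos) %in% hydro] <- pos[!names(pos) %in% hydro] -
    separation / (20 - length(hydro))
  pos <- pos / sum(pos)
  list(pos = pos, neg = base)
}

write_fasta <- function(records, path) {
  wrapped <- vapply(records$sequence, function(s) {
    paste(substring(s, seq(1, nchar(s), 60), pmin(seq(60, nchar(s) + 59, 60), nchar(s))),
          collapse = "\n")
  }, character(1))
  writeLines(paste0(">", records$id, "\n", wrapped), path)
  invisible(path)
}

# PSI-BLAST order, distinct from the package's alphabetical order on
# purpose: parsing must prove the remapping
PSIBLAST_ORDER <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
)

write_synthetic_pssm <- function(sequence, path, delta = 4, noise = 2) {
  res <- strsplit(sequence, "")[[1]]
  L <- length(res)
  raw <- matrix(
    as.integer(round(rnorm(L * 20, mean = -1, sd = noise))),
    nrow = L, ncol = 20, dimnames = list(NULL, PSIBLAST_ORDER)
  )
  raw[cbind(seq_len(L), match(res, PSIBLAST_ORDER))] <-
    raw[cbind(seq_len(L), match(res, PSIBLAST_ORDER))] + as.integer(delta)
  pct <- matrix(0L, nrow = L, ncol = 20)

  lines <- c(
    "",
    paste(
      "Last position-specific scoring matrix computed, weighted observed",
      "percentages rounded down, information per position, and relative",
      "weight of gapless real matches to pseudocounts"
    ),
    paste0(
      "         ",
      paste(sprintf("%4s", PSIBLAST_ORDER), collapse = ""), " ",
      paste(sprintf("%4s", PSIBLAST_ORDER), collapse = "")
    ),
    vapply(seq_len(L), function(i) {
      paste0(
        sprintf("%5d %s ", i, res[i]),
        paste(sprintf("%4d", raw[i, ]), collapse = ""), " ",
        paste(sprintf("%4d", pct[i, ]), collapse = ""),
        sprintf("  %4.2f %8.2f", 0.50, 1.00)
      )
    }, character(1)),
    "",
    "                      K         Lambda",
    "Standard Ungapped    0.1370     0.3200",
    "Standard Gapped      0.0410     0.2670",
    "PSI Ungapped         0.1680     0.3120",
    "PSI Gapped           0.0410     0.2670"
  )
  writeLines(lines, path)
  invisible(path)
}

# moving-average (window 5) uniform noise around the class mean, clipped
simulate_disorder_track <- function(L, mean_score, amplitude = 0.6) {
  x <- runif(L + 4, -0.5, 0.5)
  sm <- stats::filter(x, rep(1 / 5, 5), sides = 2)
  sm <- sm[!is.na(sm)][seq_len(L)]
  pmin(pmax(mean_score + amplitude * as.numeric(sm), 0), 1)
}
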