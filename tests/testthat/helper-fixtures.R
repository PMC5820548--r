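# shared fixture builders; everything is generated in code at test time

AA <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

rand_seq <- function(L) paste(sample(AA, L, replace = TRUE), collapse = "")

# feature tibble with gaussian features; class means shifted by `shift` on
# the first `n_informative` features
make_blobs <- function(n_pos, n_neg, d = 10, n_informative = d, shift = 2,
                       seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm((n_pos + n_neg) * d), ncol = d)
  X[seq_len(n_pos), seq_len(n_informative)] <-
    X[seq_len(n_pos), seq_len(n_informative)] + shift
  colnames(X) <- sprintf("f%02d", seq_len(d))
  dplyr::bind_cols(
    tibble::tibble(
      id = sprintf("s%03d", seq_len(n_pos + n_neg)),
      label = rep(c(1L, 0L), c(n_pos, n_neg))
    ),
    tibble::as_tibble(X)
  )
}

# tiny labelled FASTA pair on disk
write_fasta_pair <- function(pos_seqs, neg_seqs, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  pos <- file.path(dir, "pos.fasta")
  neg <- file.path(dir, "neg.fasta")
  writeLines(paste0(">p", seq_along(pos_seqs), "\n", pos_seqs), pos)
  writeLines(paste0(">n", seq_along(neg_seqs), "\n", neg_seqs), neg)
  list(positives = pos, negatives = neg)
}

# independent brute-force CTD oracle: recomputes C/T/D from first
# principles with explicit loops, never via the package's encoder
ctd_oracle <- function(sequence, grouping, denominator = "L") {
  res <- strsplit(sequence, "")[[1]]
  L <- length(res)
  g <- vapply(res, function(r) {
    for (k in 1:3) {
      if (grepl(r, grouping[[paste0("group", k)]], fixed = TRUE)) return(k)
    }
    stop("unknown residue")
  }, integer(1))
  comp <- sapply(1:3, function(k) sum(g == k)) / L
  trans <- c(0, 0, 0)
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  for (i in seq_len(L - 1)) {
    for (p in 1:3) {
      a <- pairs[[p]][1]; b <- pairs[[p]][2]
      if ((g[i] == a && g[i + 1] == b) || (g[i] == b && g[i + 1] == a)) {
        trans[p] <- trans[p] + 1
      }
    }
  }
  trans <- trans / if (denominator == "L") L else L - 1
  distr <- numeric(15)
  for (k in 1:3) {
    pos <- which(g == k)
    if (length(pos) == 0) next
    n <- length(pos)
    qidx <- c(1, ceiling(0.25 * n), ceiling(0.5 * n), ceiling(0.75 * n), n)
    distr[(k - 1) * 5 + 1:5] <- pos[qidx] / L
  }
  c(comp, trans, distr)
}

# brute-force PseAAC tier correlation: plain double-sum expansion
theta_oracle <- function(sequence, j, indices) {
  res <- strsplit(sequence, "")[[1]]
  L <- length(res)
  total <- 0
  for (i in 1:(L - j)) {
    a <- indices[res[i], ]
    b <- indices[res[i + j], ]
    total <- total + (1 / 3) * ((a[[1]] - b[[1]])^2 + (a[[2]] - b[[2]])^2 + (a[[3]] - b[[3]])^2)
  }
  as.numeric(total / (L - j))
}

# brute-force PsePSSM autocovariance for one column and lag
psepssm_oracle <- function(scaled_col, j) {
  L <- length(scaled_col)
  m <- sum(scaled_col) / L
  acc <- 0
  for (i in 1:(L - j)) {
    acc <- acc + (scaled_col[i] - m) * (scaled_col[i + j] - m)
  }
  acc / (L - j)
}
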