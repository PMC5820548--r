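PSIBLAST <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
)

test_that("parse_pssm reads the golden fixture and remaps header column order", {
  prof <- parse_pssm(test_path("fixtures", "toy.pssm"))
  expect_equal(prof$residues, "MHTAC")
  expect_equal(dim(prof$scores), c(5L, 20L))
  expect_equal(colnames(prof$scores), AA)
  # row r in the fixture runs (r-10)..(r+9) across the PSI-BLAST column
  # order; spot-check hand-read cells after the alphabetical remap
  expect_equal(prof$scores[[1, "A"]], -9) # first file column
  expect_equal(prof$scores[[1, "V"]], 10) # last file column
  expect_equal(prof$scores[[3, "R"]], -6)
  expect_equal(prof$scores[[5, "M"]], 7)
  expected <- t(sapply(1:5, function(r) (r - 10):(r + 9)))[, match(AA, PSIBLAST)]
  colnames(expected) <- AA
  expect_equal(prof$scores, expected)
})

test_that("malformed PSSM files fail with the offending line", {
  lines <- readLines(test_path("fixtures", "toy.pssm"))
  short <- withr::local_tempfile(fileext = ".pssm")
  row4 <- strsplit(trimws(lines[6]), "\\s+")[[1]]
  lines[6] <- paste(row4[1:21], collapse = " ") # only 19 score columns
  writeLines(lines, short)
  expect_error(parse_pssm(short), "fewer than 20")

  skipped <- withr::local_tempfile(fileext = ".pssm")
  lines2 <- readLines(test_path("fixtures", "toy.pssm"))
  writeLines(lines2[-5], skipped) # drop position 2: non-contiguous
  expect_error(parse_pssm(skipped), "expected 2")
})

test_that("sigmoid scaling is the logistic map into (0, 1)", {
  expect_equal(scale_sigmoid(0), 0.5)
  expect_gt(scale_sigmoid(20), 0.9999999)
  expect_equal(scale_sigmoid(-1), 1 / (1 + exp(1)), tolerance = 1e-12)
  x <- -10:10
  expect_true(all(diff(scale_sigmoid(x)) > 0))
})

test_that("PSSM-AAC is the column mean of the scaled matrix", {
  prof <- structure(
    list(residues = "AAA", scores = matrix(0, 3, 20, dimnames = list(NULL, AA))),
    class = "profile_matrix"
  )
  expect_equal(unname(pssm_aac(prof)), rep(0.5, 20))

  one <- structure(
    list(residues = "M", scores = matrix(-2:17, 1, 20, dimnames = list(NULL, AA))),
    class = "profile_matrix"
  )
  expect_equal(unname(pssm_aac(one)), unname(scale_sigmoid(-2:17)))

  set.seed(4)
  m <- matrix(sample(-8:8, 60, replace = TRUE), 3, 20, dimnames = list(NULL, AA))
  prof3 <- structure(list(residues = "ACD", scores = m), class = "profile_matrix")
  manual <- sapply(1:20, function(k) {
    (scale_sigmoid(m[[1, k]]) + scale_sigmoid(m[[2, k]]) + scale_sigmoid(m[[3, k]])) / 3
  })
  expect_equal(unname(pssm_aac(prof3)), unname(manual), tolerance = 1e-12)
  expect_true(all(pssm_aac(prof3) > 0 & pssm_aac(prof3) < 1))
})

test_that("PsePSSM matches the brute-force autocovariance and handles lags", {
  set.seed(10)
  m <- matrix(sample(-7:7, 140, replace = TRUE), 7, 20, dimnames = list(NULL, AA))
  prof <- structure(list(residues = "ACDEFGH", scores = m), class = "profile_matrix")
  v <- pse_pssm(prof, gamma = 5)
  expect_length(v, 100)
  scaled <- 1 / (1 + exp(-m))
  for (k in c(1, 7, 20)) {
    for (j in 1:5) {
      expect_equal(
        unname(v[paste0("psepssm.", AA[k], ".lag", j)]),
        psepssm_oracle(scaled[, k], j),
        tolerance = 1e-12
      )
    }
  }
  # a constant column has zero autocovariance at every lag
  m2 <- m
  m2[, 3] <- 2
  prof2 <- structure(list(residues = "ACDEFGH", scores = m2), class = "profile_matrix")
  v2 <- pse_pssm(prof2, gamma = 5)
  expect_equal(unname(v2[paste0("psepssm.D.lag", 1:5)]), rep(0, 5))

  expect_error(pse_pssm(prof, gamma = 7), "length")
})

test_that("profile features are invariant under residue-order reversal", {
  set.seed(12)
  m <- matrix(sample(-6:6, 200, replace = TRUE), 10, 20, dimnames = list(NULL, AA))
  prof <- structure(list(residues = strrep("A", 10), scores = m), class = "profile_matrix")
  rev_prof <- structure(
    list(residues = strrep("A", 10), scores = m[10:1, ]),
    class = "profile_matrix"
  )
  expect_equal(pssm_aac(prof), pssm_aac(rev_prof), tolerance = 1e-12)
  expect_equal(pse_pssm(prof), pse_pssm(rev_prof), tolerance = 1e-12)
})

test_that("the lag-0 analogue of the autocovariance is the column variance", {
  set.seed(2)
  m <- matrix(sample(-5:5, 160, replace = TRUE), 8, 20, dimnames = list(NULL, AA))
  scaled <- 1 / (1 + exp(-m))
  for (k in c(2, 11)) {
    # the autocovariance recursion evaluated at lag 0 must recover the
    # population variance of the scaled column
    pop_var <- mean((scaled[, k] - mean(scaled[, k]))^2)
    expect_equal(psepssm_oracle(scaled[, k], 0), pop_var, tolerance = 1e-12)
  }
})

test_that("encode_profile concatenates to 120 dimensions, deterministically", {
  prof <- parse_pssm(test_path("fixtures", "toy.pssm"))
  v <- encode_profile(prof, gamma = 4) # L = 5 needs gamma < 5
  expect_length(v, 20 + 20 * 4)
  expect_equal(v, encode_profile(prof, gamma = 4))
  set.seed(20)
  m <- matrix(sample(-7:7, 400, replace = TRUE), 20, 20, dimnames = list(NULL, AA))
  prof20 <- structure(list(residues = rand_seq(20), scores = m), class = "profile_matrix")
  expect_length(encode_profile(prof20), 120)
})
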