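blosum62 <- local({
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  env$BLOSUM62
})

test_that("linear-gap NW scores match hand-enumerated optima", {
  p <- score_params(gap_open = -8, mode = "linear")
  expect_equal(nw_align("AAA", "AAA", p)$score, 12)
  a <- nw_align("AW", "W", p)
  expect_equal(a$score, 3)
  expect_equal(nchar(a$gapped_a), nchar(a$gapped_b))
})

test_that("DP score equals exhaustive enumeration on short random pairs", {
  p <- score_params(gap_open = -4, mode = "linear")
  withr::with_seed(11, {
    for (k in 1:50) {
      a <- paste(sample(c("A", "C", "D", "E"), sample(1:6, 1), replace = TRUE),
                 collapse = "")
      b <- paste(sample(c("A", "C", "D", "E"), sample(1:6, 1), replace = TRUE),
                 collapse = "")
      expect_equal(nw_align(a, b, p)$score,
                   nw_enumerate(a, b, blosum62, -4),
                   info = paste(a, b))
    }
  })
})

test_that("affine NW agrees with Biostrings pairwiseAlignment scores", {
  # Biostrings charges gapOpening + k * gapExtension for a k-gap; our model
  # charges gap_open + (k - 1) * gap_extend, so open = -(10 + 1) matches
  # gapOpening = 10, gapExtension = 1.
  p <- score_params(gap_open = -11, gap_extend = -1, mode = "affine")
  withr::with_seed(12, {
    for (k in 1:20) {
      a <- paste(sample(AA_ALPHA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                        sample(8:30, 1), replace = TRUE), collapse = "")
      b <- paste(sample(AA_ALPHA, sample(8:30, 1), replace = TRUE),
                 collapse = "")
      ref <- Biostrings::pairwiseAlignment(
        a, b, substitutionMatrix = "BLOSUM62",
        gapOpening = 10, gapExtension = 1, type = "global",
        scoreOnly = TRUE)
      expect_equal(nw_align(a, b, p)$score, ref, info = paste(a, b))
    }
  })
})

test_that("alignment results satisfy their structural invariants", {
  p <- score_params()
  withr::with_seed(13, {
    for (k in 1:20) {
      ab <- replicate(2, paste(sample(AA_STD <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                                      sample(1:25, 1), replace = TRUE),
                               collapse = ""))
      aln <- nw_align(ab[1], ab[2], p)
      expect_equal(nchar(aln$gapped_a), nchar(aln$gapped_b))
      expect_gte(nchar(aln$gapped_a), 1)
      # no column with a gap in both rows
      ca <- strsplit(aln$gapped_a, "")[[1]]
      cb <- strsplit(aln$gapped_b, "")[[1]]
      expect_false(any(ca == "-" & cb == "-"))
      # degapping recovers the inputs
      expect_equal(gsub("-", "", aln$gapped_a), ab[1])
      expect_equal(gsub("-", "", aln$gapped_b), ab[2])
      # score symmetry
      expect_equal(aln$score, nw_align(ab[2], ab[1], p)$score)
    }
  })
})

test_that("self-alignment gives identity 1 and distance 0", {
  withr::with_seed(14, {
    x <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 30,
                      replace = TRUE), collapse = "")
  })
  aln <- nw_align(x, x)
  expect_equal(pairwise_identity(aln$gapped_a, aln$gapped_b)$id_value, 1)
  expect_equal(identity_to_distance(
    pairwise_identity(aln$gapped_a, aln$gapped_b)$id_value), 0)
})

test_that("ambiguity codes score neutrally, unknown residues error", {
  # U is not in the BLOSUM series: scored 0 against everything, no failure
  aln <- nw_align("ACU", "ACU", score_params(gap_open = -8, mode = "linear"))
  expect_equal(aln$gapped_a, "ACU")
  expect_equal(aln$score, 4 + 9 + 0)
  # O has no tolerated fallback
  expect_error(nw_align("ACO", "ACD"), class = "alnvalid_scoring_error",
               regexp = "O")
})

test_that("all-pairs distances satisfy the distance-matrix contract", {
  seqs <- tibble::tibble(id = c("x", "x2", "w"),
                         residues = c("AAA", "AAA", "WWW"))
  d <- all_pairs_distances(seqs, score_params(gap_open = -8, mode = "linear"))
  expect_s3_class(d, "aln_dist")
  expect_equal(d["x", "x2"], 0)
  expect_equal(d["x", "w"], d["x2", "w"])
  expect_true(all(diag(unclass(d)) == 0))
  expect_true(all(unclass(d) >= 0 & unclass(d) <= 1))

  expect_error(all_pairs_distances(seqs[1, ]), class = "alnvalid_contract_error")
})

test_that("scoring errors from all-pairs name the offending pair", {
  seqs <- tibble::tibble(id = c("ok", "bad"), residues = c("ACD", "AJO"))
  expect_error(all_pairs_distances(seqs), class = "alnvalid_scoring_error")
})

test_that("score_params validates the gap model", {
  expect_error(score_params(gap_open = 2), class = "alnvalid_contract_error")
  expect_error(score_params(gap_open = -1, gap_extend = -5),
               class = "alnvalid_contract_error")
  expect_error(score_params(matrix = "NOSUCH"),
               class = "alnvalid_contract_error")
  expect_silent(score_params(gap_open = -5, gap_extend = 3, mode = "linear"))
})
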