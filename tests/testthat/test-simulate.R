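test_that("generator produces the requested counts and labels", {
  sim <- generate_families(n_families = 3, seqs_per_family = 5, length = 40,
                           between_divergence = 0.4, within_divergence = 0.1,
                           seed = 51)
  expect_equal(nrow(sim$sequences), 15)
  expect_equal(as.vector(table(sim$sequences$family)), rep(5L, 3))
  expect_length(unique(sim$sequences$family), 3)
  expect_false(any(grepl("-", sim$sequences$residues)))
  expect_equal(nchar(sim$truth$root), 40)
})

test_that("generation is deterministic under the seed", {
  s1 <- generate_families(2, 3, 30, 0.5, 0.1, indel_prob = 0.05, seed = 52)
  s2 <- generate_families(2, 3, 30, 0.5, 0.1, indel_prob = 0.05, seed = 52)
  expect_identical(s1$sequences, s2$sequences)
  s3 <- generate_families(2, 3, 30, 0.5, 0.1, indel_prob = 0.05, seed = 53)
  expect_false(identical(s1$sequences, s3$sequences))
})

test_that("zero within-divergence collapses families to identical members", {
  sim <- generate_families(3, 4, 50, between_divergence = 0.5,
                           within_divergence = 0, indel_prob = 0, seed = 54)
  per_family <- split(sim$sequences$residues, sim$sequences$family)
  for (fam in per_family) expect_length(unique(fam), 1)
  d <- all_pairs_distances(sim$sequences)
  expect_equal(sw_score(d, sim$sequences[, c("id", "family")]), 1)
})

test_that("spec validation rejects out-of-range parameters", {
  expect_error(generate_families(between_divergence = 1.5),
               class = "alnvalid_contract_error")
  expect_error(generate_families(indel_prob = 0.8),
               class = "alnvalid_contract_error")
  expect_error(generate_families(n_families = 1))
})

test_that("expected_identity closed form matches its endpoints and model", {
  expect_equal(expected_identity(0), 1)
  expect_equal(expected_identity(1), 0)
  expect_equal(expected_identity(0.3), 0.7)
  expect_equal(expected_identity(0.3, branches = 2), 0.7^2 + 0.3^2 / 19)
  expect_error(expected_identity(-0.1), class = "alnvalid_contract_error")
})

test_that("realized site identity concentrates around the closed form", {
  # Monte-Carlo: mutate a copy of a fixed sequence many times and compare
  # the mean site identity against 1 - d (no indels, no alignment needed)
  d <- 0.3
  n_pairs <- 1000
  L <- 100
  ids <- withr::with_seed(55, {
    root <- sample(alnvalid:::AA_STANDARD, L, replace = TRUE)
    vapply(seq_len(n_pairs), function(k) {
      mut <- alnvalid:::mutate_sites(root, d)
      mean(mut == root)
    }, numeric(1))
  })
  expect_lt(abs(mean(ids) - expected_identity(d)), 0.01)
})

test_that("aligned identity between family members matches the two-branch form", {
  sim <- generate_families(2, 12, 150, between_divergence = 0.9,
                           within_divergence = 0.1, indel_prob = 0, seed = 56)
  ds <- sim$sequences
  d <- all_pairs_distances(ds)
  lab <- stats::setNames(ds$family, ds$id)
  same <- outer(lab[rownames(d)], lab[rownames(d)], "==")
  within_ids <- unclass(d)[upper.tri(d) & same]
  # equal-length ungapped members: NW aligns them site-by-site
  expect_lt(abs(mean(1 - within_ids) - expected_identity(0.1, branches = 2)),
            0.02)
})

test_that("separation scores respond to the divergence dials", {
  lab_of <- function(s) s$sequences[, c("id", "family")]
  sw_at <- function(between, within) {
    sim <- generate_families(3, 5, 80, between, within, seed = 57)
    sw_score(all_pairs_distances(sim$sequences), lab_of(sim))
  }
  expect_gt(sw_at(0.7, 0.05), sw_at(0.2, 0.05)) # more between-divergence helps
  expect_gt(sw_at(0.5, 0.02), sw_at(0.5, 0.3))  # more within-divergence hurts
})

test_that("presets table is well-formed", {
  p <- synthetic_presets()
  expect_true(all(p$between_divergence > p$within_divergence))
  expect_true(all(p$indel_prob >= 0 & p$indel_prob <= 0.5))
})
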