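test_that("silhouettes on the worked two-family example match hand values", {
  v <- validity_scores(worked_example_dist(), worked_example_labels())
  expect_equal(round(v$silhouettes$silhouette, 6),
               c(0.882353, 0.866667, 0.733333, 0.764706))
  expect_equal(round(v$sw, 6), 0.811765)
  # one within-pair per family: SS_w = 0 exactly, so RS = 1
  expect_equal(v$ss_w, 0)
  expect_equal(v$rs, 1)
})

test_that("silhouette matches the naive double-loop and cluster::silhouette", {
  withr::with_seed(31, {
    for (k in 1:20) {
      n <- sample(4:50, 1)
      d <- random_dist_matrix(n)
      lab <- random_labels(n, sample(2:4, 1))
      s <- silhouette_values(d, lab)$silhouette
      expect_lt(max(abs(s - naive_silhouette(d, unname(lab)))), 1e-12)

      # independent library implementation (only defined when no family is
      # a singleton; conventions differ there)
      if (all(table(lab) >= 2)) {
        ref <- cluster::silhouette(as.integer(factor(unname(lab))),
                                   dmatrix = unclass(d))
        expect_lt(max(abs(s - ref[, "sil_width"])), 1e-10)
      }
    }
  })
})

test_that("silhouette edge conventions hold", {
  # perfectly separated: all intra 0, all inter 0.8
  ids <- paste0("s", 1:4)
  m <- matrix(0.8, 4, 4, dimnames = list(ids, ids))
  m[1, 2] <- m[2, 1] <- 0; m[3, 4] <- m[4, 3] <- 0; diag(m) <- 0
  lab <- c(s1 = "A", s2 = "A", s3 = "B", s4 = "B")
  expect_equal(silhouette_values(aln_dist(m), lab)$silhouette, rep(1, 4))
  expect_equal(sw_score(aln_dist(m), lab), 1)

  # singleton family member gets the neutral value 0
  lab2 <- c(s1 = "A", s2 = "A", s3 = "B", s4 = "C")
  s <- silhouette_values(aln_dist(m), lab2)
  expect_equal(s$silhouette[s$id == "s3"], 0)
  expect_equal(s$silhouette[s$id == "s4"], 0)
})

test_that("validity contract errors fire", {
  d <- worked_example_dist()
  expect_error(silhouette_values(d, c(s1 = "A", s2 = "A", s3 = "A", s4 = "A")),
               class = "alnvalid_contract_error")
  expect_error(silhouette_values(d, c(s1 = "A", s2 = "A", s3 = "B")),
               class = "alnvalid_label_error")
  # no within-family pair anywhere
  expect_error(rs_score(d, c(s1 = "A", s2 = "B", s3 = "C", s4 = "D")),
               class = "alnvalid_contract_error")
})

test_that("RS follows its sum-of-squares definition", {
  withr::with_seed(32, {
    for (k in 1:20) {
      n <- sample(5:25, 1)
      d <- random_dist_matrix(n)
      lab <- random_labels(n, sample(2:4, 1))
      if (!any(outer(lab, lab, "==")[upper.tri(diag(n))])) next
      for (wc in c("cluster", "global")) {
        rs <- rs_score(d, lab, within_center = wc)
        expect_equal(rs, naive_rs(d, unname(lab), wc))
        expect_gte(rs, 0)
        expect_lte(rs, 1)
      }
    }
  })
})

test_that("RS degenerate conventions hold", {
  # all pairwise distances equal: no structure, RS = 0
  ids <- paste0("s", 1:4)
  m <- matrix(0.5, 4, 4, dimnames = list(ids, ids)); diag(m) <- 0
  lab <- c(s1 = "A", s2 = "A", s3 = "B", s4 = "B")
  expect_equal(rs_score(aln_dist(m), lab), 0)

  # per-cluster centring explains at least as much as global centring
  withr::with_seed(33, {
    d <- random_dist_matrix(12)
    lab2 <- random_labels(12, 3)
  })
  expect_gte(rs_score(d, lab2, "cluster"), rs_score(d, lab2, "global"))
})

test_that("SW and RS are invariant under permutation, relabeling and scaling", {
  withr::with_seed(34, {
    d <- random_dist_matrix(15)
    lab <- random_labels(15, 3)
  })
  sw0 <- sw_score(d, lab)
  rs0 <- rs_score(d, lab)

  # simultaneous permutation of rows/columns and labels
  perm <- withr::with_seed(35, sample.int(15))
  dp <- aln_dist(unclass(d)[perm, perm])
  expect_equal(sw_score(dp, lab[rownames(dp)]), sw0)
  expect_equal(rs_score(dp, lab[rownames(dp)]), rs0)

  # bijective renaming of families
  ren <- c(fam1 = "x", fam2 = "y", fam3 = "z")
  lab2 <- stats::setNames(ren[lab], names(lab))
  expect_equal(sw_score(d, lab2), sw0)
  expect_equal(rs_score(d, lab2), rs0)

  # uniform shrinking of all distances changes neither score
  for (c_ in c(0.1, 0.5, 1.0)) {
    dc <- aln_dist(unclass(d) * c_)
    expect_lt(abs(sw_score(dc, lab) - sw0), 1e-12)
    expect_lt(abs(rs_score(dc, lab) - rs0), 1e-12)
  }
})

test_that("permuting labels on separated data lowers SW", {
  sim <- generate_families(n_families = 3, seqs_per_family = 5, length = 80,
                           between_divergence = 0.6, within_divergence = 0.05,
                           seed = 36)
  d <- all_pairs_distances(sim$sequences)
  lab <- sim$sequences[, c("id", "family")]
  sw_true <- sw_score(d, lab)
  withr::with_seed(37, {
    for (k in 1:5) {
      shuffled <- lab
      shuffled$family <- sample(shuffled$family)
      expect_lt(sw_score(d, shuffled), sw_true)
    }
  })
})

test_that("validity result object is tidy-friendly", {
  v <- validity_scores(worked_example_dist(), worked_example_labels())
  td <- tidy(v)
  expect_equal(names(td), c("id", "family", "silhouette"))
  g <- glance(v)
  expect_equal(g$n, 4L)
  expect_equal(g$n_families, 2L)
  expect_equal(g$sw, v$sw)
  p <- autoplot(v)
  expect_s3_class(p, "ggplot")
})
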