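# Independent reference implementations and fixture builders used across the
# suite. These deliberately share no code with the package internals.

# Exhaustive enumeration of all global alignments under a linear gap penalty:
# the brute-force optimum the DP must match.
nw_enumerate <- function(a, b, sub, gap) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  na <- length(ca); nb <- length(cb)
  rec <- function(i, j) {
    if (i > na && j > nb) return(0)
    best <- -Inf
    if (i <= na && j <= nb) {
      best <- max(best, sub[ca[i], cb[j]] + rec(i + 1, j + 1))
    }
    if (i <= na) best <- max(best, gap + rec(i + 1, j))
    if (j <= nb) best <- max(best, gap + rec(i, j + 1))
    best
  }
  rec(1, 1)
}

# Naive O(n^2) silhouette: double loop straight from the definition.
naive_silhouette <- function(d, fam) {
  d <- unclass(d)
  n <- nrow(d)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(fam == fam[i] & seq_len(n) != i)
    if (length(own) == 0) { s[i] <- 0; next }
    a <- mean(d[i, own])
    b <- Inf
    for (f in setdiff(unique(fam), fam[i])) {
      b <- min(b, mean(d[i, fam == f]))
    }
    s[i] <- (b - a) / max(a, b)
    if (is.nan(s[i])) s[i] <- 0
  }
  s
}

# Naive RS from its definition over unordered pairs.
naive_rs <- function(d, fam, within_center = "cluster") {
  d <- unclass(d)
  n <- nrow(d)
  xs <- c(); within <- c(); wfam <- c()
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    xs <- c(xs, d[i, j])
    within <- c(within, fam[i] == fam[j])
    wfam <- c(wfam, if (fam[i] == fam[j]) fam[i] else NA)
  }
  xbar <- mean(xs)
  ss_t <- sum((xs - xbar)^2)
  xw <- xs[within]; fw <- wfam[within]
  if (within_center == "cluster") {
    ss_w <- 0
    for (f in unique(fw)) {
      xf <- xw[fw == f]
      ss_w <- ss_w + sum((xf - mean(xf))^2)
    }
  } else {
    ss_w <- sum((xw - xbar)^2)
  }
  if (ss_t == 0) 0 else (ss_t - ss_w) / ss_t
}

# Random valid distance matrix with ids s1..sn.
random_dist_matrix <- function(n) {
  m <- matrix(stats::runif(n * n), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  rownames(m) <- colnames(m) <- paste0("s", seq_len(n))
  aln_dist(m)
}

random_labels <- function(n, k = 3) {
  fam <- sample(paste0("fam", seq_len(k)), n, replace = TRUE)
  # guarantee at least 2 distinct families
  fam[1] <- "fam1"; fam[2] <- "fam2"
  stats::setNames(fam, paste0("s", seq_len(n)))
}

# The worked 4-sequence example: two tight families, cross distances large.
worked_example_dist <- function() {
  ids <- paste0("s", 1:4)
  m <- matrix(0, 4, 4, dimnames = list(ids, ids))
  m["s1", "s2"] <- m["s2", "s1"] <- 0.1
  m["s3", "s4"] <- m["s4", "s3"] <- 0.2
  m["s1", "s3"] <- m["s3", "s1"] <- 0.8
  m["s1", "s4"] <- m["s4", "s1"] <- 0.9
  m["s2", "s3"] <- m["s3", "s2"] <- 0.7
  m["s2", "s4"] <- m["s4", "s2"] <- 0.8
  aln_dist(m)
}

worked_example_labels <- function() {
  c(s1 = "famA", s2 = "famA", s3 = "famB", s4 = "famB")
}

write_tmp_fasta <- function(records, path = tempfile(fileext = ".fasta")) {
  writeLines(unlist(lapply(names(records), function(id) {
    c(paste0(">", id), records[[id]])
  })), path)
  path
}

# Stub "aligner" executables used to exercise the external-MSA adapter
# without real aligner binaries. Each is a self-contained Rscript that pads
# sequences with trailing gaps to equal length and prints gapped FASTA.
write_stub_aligner <- function(drop_first = FALSE) {
  path <- tempfile(fileext = ".R")
  writeLines(c(
    "args <- commandArgs(trailingOnly = TRUE)",
    "lines <- readLines(args[[1]])",
    "ids <- character(0); seqs <- character(0); cur <- ''",
    "for (ln in lines) {",
    "  if (startsWith(ln, '>')) { ids <- c(ids, sub('^>', '', ln)); seqs <- c(seqs, cur); cur <- '' }",
    "  else cur <- paste0(cur, ln)",
    "}",
    "seqs <- c(seqs, cur)[-1]",
    if (drop_first) "ids <- ids[-1]; seqs <- seqs[-1]" else "",
    "L <- max(nchar(seqs))",
    "pad <- function(s) paste0(s, strrep('-', L - nchar(s)))",
    "for (k in seq_along(ids)) cat('>', ids[k], '\\n', pad(seqs[k]), '\\n', sep = '')"
  ), path)
  path
}

stub_msa_method <- function(id = "stub-pad", drop_first = FALSE) {
  msa_method(id, command = file.path(R.home("bin"), "Rscript"),
             args = c(write_stub_aligner(drop_first), "{input}"))
}

# Deliberately corrupted multiple alignment: pad to equal length, then
# independently permute each row's columns, destroying homology.
corrupt_alignment <- function(ds, seed = 1) {
  L <- max(nchar(ds$residues))
  rows <- vapply(ds$residues, function(s) {
    paste0(s, strrep("-", L - nchar(s)))
  }, character(1))
  withr::with_seed(seed, {
    rows <- vapply(rows, function(r) {
      ch <- strsplit(r, "")[[1]]
      paste(ch[sample.int(length(ch))], collapse = "")
    }, character(1))
  })
  tibble::tibble(id = ds$id, aligned = unname(rows))
}
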