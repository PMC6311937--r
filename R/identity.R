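#' Percent identity of two gapped sequences
#'
#' Counts columns in which the two rows carry the same residue letter
#' (gap-gap columns never count as matches) and divides by the aligned
#' length: `ID = matched / length`. The denominator depends on the
#' gap-column policy:
#'
#' * `keep-all` (default): the full aligned length, including columns where
#'   both rows are gaps. This is the literal reading of "whole length of the
#'   aligned sequences" and means that for multiple-alignment projections the
#'   identity of two identical sequences can fall below 1 when the aligner
#'   spreads them over gap-gap columns.
#' * `drop-dual-gap`: columns that are gaps in both rows are removed before
#'   counting — the common convention for pairwise identity projected out of
#'   a multiple alignment.
#'
#' For pairwise alignments produced by [nw_align()] no gap-gap column exists,
#' so the two policies agree.
#'
#' @param gapped_a,gapped_b Equal-length strings over residues plus `-`.
#' @param policy `"keep-all"` or `"drop-dual-gap"`.
#' @return A one-row tibble with `matched`, `length` (the denominator used)
#'   and `id_value = matched / length`.
#' @examples
#' pairwise_identity("ACD-EF", "AC-DEF")      # 4 matches over 6 columns
#' pairwise_identity("AC--", "AC--", policy = "drop-dual-gap")
#' @export
pairwise_identity <- function(gapped_a, gapped_b,
                              policy = c("keep-all", "drop-dual-gap")) {
  policy <- match.arg(policy)
  stopifnot(is.character(gapped_a), length(gapped_a) == 1,
            is.character(gapped_b), length(gapped_b) == 1)
  gapped_a <- toupper(gapped_a)
  gapped_b <- toupper(gapped_b)
  if (nchar(gapped_a) != nchar(gapped_b) || nchar(gapped_a) < 1) {
    abort("gapped sequences must have equal length >= 1",
          class = "alnvalid_contract_error")
  }
  counts <- gapped_identity_counts_cpp(charToRaw(gapped_a), charToRaw(gapped_b))
  matched <- counts[1]
  len <- if (policy == "keep-all") nchar(gapped_a) else counts[2]
  if (len == 0) {
    abort("all columns are gap-gap; identity undefined under drop-dual-gap",
          class = "alnvalid_degenerate_error")
  }
  tibble(matched = matched, length = len, id_value = matched / len)
}

#' Convert percent identity to sequence distance
#'
#' `dis = 1 - ID`: identical sequences (ID = 1) are at distance 0.
#'
#' @param id_value Numeric vector of identities in \[0, 1\].
#' @return `1 - id_value`.
#' @export
identity_to_distance <- function(id_value) {
  if (!is.numeric(id_value) || any(!is.finite(id_value)) ||
      any(id_value < 0) || any(id_value > 1)) {
    abort("id_value must be numeric in [0, 1]",
          class = "alnvalid_contract_error")
  }
  1 - id_value
}

#' Pairwise-projected distance matrix from a multiple alignment
#'
#' Projects every unordered pair of rows out of a multiple-alignment matrix,
#' computes its percent identity under the chosen gap-column policy and
#' returns the distance matrix `dis = 1 - ID` (diagonal 0, symmetric).
#'
#' @param aln An alignment tibble with columns `id` and `aligned`
#'   (equal-length gapped rows), as returned by
#'   `read_fasta(path, aligned = TRUE)`; at least 2 rows.
#' @param policy Gap-column policy, see [pairwise_identity()].
#' @return An [aln_dist] distance matrix in the row order of `aln`.
#' @export
msa_distance_matrix <- function(aln, policy = c("keep-all", "drop-dual-gap")) {
  policy <- match.arg(policy)
  stopifnot(is.data.frame(aln), all(c("id", "aligned") %in% names(aln)))
  n <- nrow(aln)
  if (n < 2) {
    abort("need at least 2 aligned rows", class = "alnvalid_contract_error")
  }
  if (anyDuplicated(aln$id)) {
    abort("alignment row ids must be unique", class = "alnvalid_contract_error")
  }
  rows <- toupper(aln$aligned)
  L <- unique(nchar(rows))
  if (length(L) != 1 || L < 1) {
    abort("alignment rows must all have the same length >= 1",
          class = "alnvalid_contract_error")
  }
  raws <- lapply(rows, charToRaw)
  keep_all <- policy == "keep-all"
  values <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      counts <- gapped_identity_counts_cpp(raws[[i]], raws[[j]])
      len <- if (keep_all) L else counts[2]
      if (len == 0) {
        abort(paste0("rows ", aln$id[i], " and ", aln$id[j],
                     " share only gap-gap columns; identity undefined ",
                     "under drop-dual-gap"),
              class = "alnvalid_degenerate_error")
      }
      values[i, j] <- values[j, i] <- 1 - counts[1] / len
    }
  }
  aln_dist(values, aln$id)
}
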