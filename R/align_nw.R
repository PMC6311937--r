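#' Scoring parameters for global pairwise alignment
#'
#' Bundles the substitution matrix and gap model used by [nw_align()] and
#' [all_pairs_distances()]. Defaults are the community-standard protein
#' settings: BLOSUM62 with affine gaps, opening -10 and extension -1 (a gap
#' run of length k costs `gap_open + (k - 1) * gap_extend`). In `linear`
#' mode every gap column costs `gap_open` and `gap_extend` is ignored;
#' linear mode exists mainly because its optimum is easy to verify by
#' exhaustive enumeration.
#'
#' @param matrix Name of a substitution matrix shipped with Biostrings
#'   (e.g. `"BLOSUM62"`, `"BLOSUM45"`, `"PAM250"`) or a symmetric numeric
#'   matrix with residue letters as dimnames.
#' @param gap_open Gap opening penalty (non-positive).
#' @param gap_extend Gap extension penalty (non-positive; must satisfy
#'   `gap_open <= gap_extend <= 0` in affine mode).
#' @param mode `"affine"` or `"linear"`.
#' @return An object of class `aln_score_params`.
#' @export
score_params <- function(matrix = "BLOSUM62", gap_open = -10, gap_extend = -1,
                         mode = c("affine", "linear")) {
  mode <- match.arg(mode)
  sub <- resolve_substitution_matrix(matrix)
  if (!is.numeric(gap_open) || length(gap_open) != 1 || gap_open > 0) {
    abort("gap_open must be a single non-positive number",
          class = "alnvalid_contract_error")
  }
  if (mode == "affine") {
    if (!is.numeric(gap_extend) || length(gap_extend) != 1 ||
        gap_extend > 0 || gap_open > gap_extend) {
      abort("affine mode requires gap_open <= gap_extend <= 0",
            class = "alnvalid_contract_error")
    }
  }
  structure(
    list(matrix_name = if (is.character(matrix)) matrix else "custom",
         matrix = sub, gap_open = as.numeric(gap_open),
         gap_extend = as.numeric(gap_extend), mode = mode),
    class = "aln_score_params"
  )
}

#' @export
print.aln_score_params <- function(x, ...) {
  cat("<aln_score_params> ", x$matrix_name, ", ", x$mode,
      " gaps: open ", x$gap_open,
      if (x$mode == "affine") paste0(", extend ", x$gap_extend) else "",
      "\n", sep = "")
  invisible(x)
}

resolve_substitution_matrix <- function(matrix) {
  if (is.character(matrix)) {
    stopifnot(length(matrix) == 1)
    env <- new.env()
    ok <- tryCatch({
      utils::data(list = matrix, package = "Biostrings", envir = env)
      TRUE
    }, warning = function(w) FALSE, error = function(e) FALSE)
    if (!ok || !exists(matrix, envir = env)) {
      abort(paste0("unknown substitution matrix: ", matrix),
            class = "alnvalid_contract_error")
    }
    matrix <- get(matrix, envir = env)
  }
  matrix <- as.matrix(matrix)
  if (is.null(rownames(matrix)) || !identical(rownames(matrix), colnames(matrix))) {
    abort("substitution matrix needs identical residue dimnames",
          class = "alnvalid_contract_error")
  }
  if (max(abs(matrix - t(matrix))) > 0) {
    abort("substitution matrix must be symmetric",
          class = "alnvalid_contract_error")
  }
  storage.mode(matrix) <- "double"
  matrix
}

# Extend the matrix with zero-scoring rows for tolerated ambiguity/rare codes
# that it lacks (e.g. U in the BLOSUM series); any other missing residue is a
# scoring error naming the residue.
augment_matrix <- function(sub, letters_needed) {
  missing <- setdiff(letters_needed, rownames(sub))
  if (length(missing) == 0) return(sub)
  tolerated <- intersect(missing, AA_EXTENDED)
  hard <- setdiff(missing, AA_EXTENDED)
  if (length(hard) > 0) {
    abort(paste0("residue '", hard[1], "' has no substitution-matrix entry"),
          class = "alnvalid_scoring_error")
  }
  for (ch in tolerated) {
    sub <- rbind(cbind(sub, 0), 0)
    rownames(sub)[nrow(sub)] <- ch
    colnames(sub)[ncol(sub)] <- ch
  }
  sub
}

encode_seq <- function(residues, alphabet) {
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  idx <- match(chars, alphabet)
  if (anyNA(idx)) {
    abort(paste0("residue '", chars[which(is.na(idx))[1]],
                 "' has no substitution-matrix entry"),
          class = "alnvalid_scoring_error")
  }
  idx - 1L
}

#' Needleman-Wunsch global pairwise alignment
#'
#' Aligns two protein sequences end-to-end by dynamic programming, maximising
#' the summed substitution score minus gap penalties under `params`.
#' Traceback ties are broken deterministically (diagonal, then gap in `b`,
#' then gap in `a`), so identical inputs always yield the identical alignment
#' and hence identical downstream percent-identity values.
#'
#' @param a,b Residue strings (or single-row tibbles with a `residues`
#'   column). Must be non-empty and gap-free.
#' @param params An [score_params()] object.
#' @return An object of class `aln_pairwise`: a list with `gapped_a`,
#'   `gapped_b` (equal-length gapped strings; no column is gap-gap) and
#'   `score` (the optimal DP score).
#' @examples
#' aln <- nw_align("HEAGAWGHEE", "PAWHEAE")
#' aln$score
#' @export
nw_align <- function(a, b, params = score_params()) {
  a <- as_residue_string(a, "a")
  b <- as_residue_string(b, "b")
  stopifnot(inherits(params, "aln_score_params"))
  sub <- augment_matrix(params$matrix,
                        unique(c(strsplit(a, "")[[1]], strsplit(b, "")[[1]])))
  alphabet <- rownames(sub)
  res <- nw_align_cpp(encode_seq(a, alphabet), encode_seq(b, alphabet), sub,
                      params$gap_open, params$gap_extend,
                      params$mode == "affine")
  ga <- gb <- character(length(res$moves))
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  ia <- ib <- 0L
  for (k in seq_along(res$moves)) {
    mv <- res$moves[k]
    if (mv == 0L) {
      ia <- ia + 1L; ib <- ib + 1L
      ga[k] <- ca[ia]; gb[k] <- cb[ib]
    } else if (mv == 1L) {
      ia <- ia + 1L
      ga[k] <- ca[ia]; gb[k] <- GAP
    } else {
      ib <- ib + 1L
      ga[k] <- GAP; gb[k] <- cb[ib]
    }
  }
  structure(
    list(gapped_a = paste(ga, collapse = ""),
         gapped_b = paste(gb, collapse = ""),
         score = res$score, params = params),
    class = "aln_pairwise"
  )
}

as_residue_string <- function(x, arg) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1, "residues" %in% names(x))
    x <- x$residues
  }
  if (!is.character(x) || length(x) != 1 || !nzchar(x)) {
    abort(paste0("sequence '", arg, "' must be a single non-empty residue string"),
          class = "alnvalid_contract_error")
  }
  if (grepl("-", x, fixed = TRUE)) {
    abort(paste0("sequence '", arg, "' contains gaps; alignment input must be ungapped"),
          class = "alnvalid_contract_error")
  }
  toupper(x)
}

#' @export
print.aln_pairwise <- function(x, ...) {
  cat("<aln_pairwise> score ", x$score, "\n", sep = "")
  cat(" ", x$gapped_a, "\n ", x$gapped_b, "\n", sep = "")
  invisible(x)
}

#' Tidy a pairwise alignment
#'
#' @param x An `aln_pairwise` object.
#' @param ... Unused.
#' @return One-row tibble with the gapped strings, score, alignment length,
#'   matched-residue count and percent identity (keep-all policy).
#' @export
tidy.aln_pairwise <- function(x, ...) {
  idc <- pairwise_identity(x$gapped_a, x$gapped_b)
  tibble(gapped_a = x$gapped_a, gapped_b = x$gapped_b, score = x$score,
         length = idc$length, matched = idc$matched, id_value = idc$id_value)
}

#' All-pairs percent-identity distances by pairwise alignment
#'
#' Globally aligns every unordered pair of sequences with [nw_align()],
#' computes the percent identity of each alignment (matched residues over the
#' full alignment length) and returns the distance matrix `dis = 1 - ID`.
#' Each pair is aligned once, so the matrix is symmetric by construction;
#' the diagonal is 0 and identical sequences get distance 0 exactly.
#'
#' @param seqs A tibble of sequences with columns `id` and `residues`
#'   (at least 2 rows).
#' @param params An [score_params()] object.
#' @return An [aln_dist] distance matrix in the row order of `seqs`.
#' @export
all_pairs_distances <- function(seqs, params = score_params()) {
  stopifnot(is.data.frame(seqs), all(c("id", "residues") %in% names(seqs)))
  n <- nrow(seqs)
  if (n < 2) {
    abort("need at least 2 sequences for a distance matrix",
          class = "alnvalid_contract_error")
  }
  if (anyDuplicated(seqs$id)) {
    abort("sequence ids must be unique", class = "alnvalid_contract_error")
  }
  residues <- toupper(seqs$residues)
  letters_needed <- unique(unlist(strsplit(residues, "", fixed = TRUE)))
  sub <- withCallingHandlers(
    augment_matrix(params$matrix, letters_needed),
    alnvalid_scoring_error = function(e) {
      ch <- sub("^residue '(.)'.*$", "\\1", conditionMessage(e))
      bad <- seqs$id[grepl(ch, residues, fixed = TRUE)]
      abort(paste0(conditionMessage(e), " (in sequence(s): ",
                   paste(head(bad, 5), collapse = ", "), ")"),
            class = "alnvalid_scoring_error")
    }
  )
  alphabet <- rownames(sub)
  enc <- lapply(residues, encode_seq, alphabet = alphabet)
  affine <- params$mode == "affine"

  values <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      res <- tryCatch(
        nw_align_cpp(enc[[i]], enc[[j]], sub, params$gap_open,
                     params$gap_extend, affine),
        error = function(e) {
          abort(paste0("alignment failed for pair (", seqs$id[i], ", ",
                       seqs$id[j], "): ", conditionMessage(e)),
                class = "alnvalid_scoring_error")
        }
      )
      mv <- res$moves
      # identity straight from the move path: diagonal columns where the two
      # residues are the same letter, over the full alignment length
      di <- mv == 0L
      ai <- cumsum(mv != 2L)[di]
      bi <- cumsum(mv != 1L)[di]
      matched <- sum(enc[[i]][ai] == enc[[j]][bi])
      values[i, j] <- values[j, i] <- 1 - matched / length(mv)
    }
  }
  aln_dist(values, seqs$id)
}
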