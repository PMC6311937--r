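#' Read protein sequences from a FASTA file
#'
#' Reads plain (unaligned) or gapped (aligned) FASTA. Sequences are upper-cased
#' on read and `.` gap characters are normalised to `-`, so downstream code
#' deals with a single canonical form. The sequence id is the first
#' whitespace-delimited token of each header line.
#'
#' @param path Path to a FASTA file.
#' @param aligned If `FALSE` (default), gaps in the input are an error and a
#'   sequence tibble is returned. If `TRUE`, all rows must have identical
#'   gapped length and an alignment tibble is returned.
#'
#' @return A tibble with columns `id` and, for `aligned = FALSE`, `residues`
#'   (gap-free residue strings); for `aligned = TRUE`, `aligned` (gapped rows
#'   of equal length).
#'
#' @details Residues are validated against the 20-letter amino-acid alphabet
#'   plus the ambiguity/rare codes X, B, Z and U; anything else is an error
#'   naming the offending sequence. Duplicate ids and empty files are format
#'   errors.
#'
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1", "ACDE", ">s2", "ACDF"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path, aligned = FALSE) {
  stopifnot(is.character(path), length(path) == 1)
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path), class = "alnvalid_io_error")
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      abort(paste0("failed to parse FASTA file '", path, "': ",
                   conditionMessage(e)), class = "alnvalid_format_error")
    }
  )
  if (length(set) == 0) {
    abort(paste0("FASTA file '", path, "' contains no records"),
          class = "alnvalid_format_error")
  }
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate sequence ids in '", path, "': ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
          class = "alnvalid_format_error")
  }
  seqs <- toupper(as.character(set))
  seqs <- gsub(".", "-", seqs, fixed = TRUE)

  if (aligned) {
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1) {
      abort(paste0("ragged aligned FASTA '", path, "': row lengths ",
                   paste(sort(unique(lens)), collapse = ", ")),
            class = "alnvalid_format_error")
    }
    validate_residues(gsub("-", "", seqs, fixed = TRUE), ids, allow_empty = TRUE)
    tibble(id = ids, aligned = unname(seqs))
  } else {
    if (any(grepl("-", seqs, fixed = TRUE))) {
      bad <- ids[grepl("-", seqs, fixed = TRUE)]
      abort(paste0("gap characters in unaligned FASTA '", path,
                   "' (sequence ", bad[1], "); use aligned = TRUE"),
            class = "alnvalid_format_error")
    }
    validate_residues(seqs, ids)
    tibble(id = ids, residues = unname(seqs))
  }
}

validate_residues <- function(seqs, ids, allow_empty = FALSE) {
  if (!allow_empty && any(nchar(seqs) == 0)) {
    abort(paste0("empty sequence: ", ids[nchar(seqs) == 0][1]),
          class = "alnvalid_format_error")
  }
  pattern <- paste0("[^", paste(AA_EXTENDED, collapse = ""), "]")
  bad <- grepl(pattern, seqs)
  if (any(bad)) {
    i <- which(bad)[1]
    ch <- regmatches(seqs[i], regexpr(pattern, seqs[i]))
    abort(paste0("invalid residue '", ch, "' in sequence ", ids[i]),
          class = "alnvalid_format_error")
  }
  invisible(TRUE)
}

#' Write sequences to a FASTA file
#'
#' @param seqs A tibble with an `id` column and either `residues` (plain) or
#'   `aligned` (gapped) sequence strings.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  col <- if ("residues" %in% names(seqs)) "residues" else "aligned"
  stopifnot(all(c("id", col) %in% names(seqs)))
  set <- Biostrings::BStringSet(setNames(seqs[[col]], seqs$id))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read a sequence-id to family-label table
#'
#' Reads a two-column TSV mapping sequence ids to protein-family labels. A
#' header row (`id<TAB>family`, case-insensitive) is detected and skipped
#' automatically. Every id must map to exactly one family: an id listed under
#' two different families is ambiguous and rejected here (pooled datasets
#' resolve multi-family sequences by exclusion at assembly time instead; see
#' [build_benchmark_group()]).
#'
#' @param path Path to a two-column TSV file.
#' @return A tibble with columns `id` and `family`.
#' @export
read_labels <- function(path) {
  stopifnot(is.character(path), length(path) == 1)
  if (!file.exists(path)) {
    abort(paste0("label file not found: ", path), class = "alnvalid_io_error")
  }
  tab <- tryCatch(
    readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(.default = "c"),
                    progress = FALSE),
    error = function(e) {
      abort(paste0("failed to parse label TSV '", path, "': ",
                   conditionMessage(e)), class = "alnvalid_format_error")
    }
  )
  if (nrow(tab) == 0) {
    abort(paste0("label file '", path, "' is empty"),
          class = "alnvalid_format_error")
  }
  if (ncol(tab) != 2) {
    abort(paste0("label file '", path, "' must have exactly two columns, found ",
                 ncol(tab)), class = "alnvalid_format_error")
  }
  names(tab) <- c("id", "family")
  if (tolower(tab$id[1]) == "id" && tolower(tab$family[1]) %in% c("family", "label")) {
    tab <- tab[-1, , drop = FALSE]
  }
  if (nrow(tab) == 0) {
    abort(paste0("label file '", path, "' has a header but no rows"),
          class = "alnvalid_format_error")
  }
  tab <- dplyr::distinct(tab)
  dup <- tab$id[duplicated(tab$id)]
  if (length(dup) > 0) {
    abort(paste0("ambiguous labels: id(s) listed under more than one family: ",
                 paste(unique(dup), collapse = ", ")),
          class = "alnvalid_label_error")
  }
  as_tibble(tab)
}

#' Write a label table
#'
#' @param labels A tibble with columns `id` and `family`.
#' @param path Output path.
#' @param header Write an `id<TAB>family` header row?
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path, header = FALSE) {
  stopifnot(all(c("id", "family") %in% names(labels)))
  readr::write_tsv(labels[, c("id", "family")], path, col_names = header,
                   progress = FALSE)
  invisible(path)
}
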