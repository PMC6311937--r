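#' Construct a labeled sequence-distance matrix
#'
#' An `aln_dist` is a symmetric numeric matrix of pairwise sequence distances
#' `dis = 1 - ID`, with values in \[0, 1\], a zero diagonal, and sequence ids
#' as dimnames. Row/column order always equals the order of the sequence set
#' the matrix was computed from, so labels and distances can never silently
#' drift apart.
#'
#' @param values A square numeric matrix.
#' @param ids Character vector of sequence ids, one per row.
#' @param tol Tolerance for the symmetry check.
#' @return An object of class `aln_dist` (a classed matrix).
#' @export
aln_dist <- function(values, ids = rownames(values), tol = 1e-9) {
  values <- as.matrix(values)
  n <- nrow(values)
  if (n != ncol(values)) {
    abort("distance matrix must be square", class = "alnvalid_contract_error")
  }
  if (is.null(ids) || length(ids) != n || anyDuplicated(ids)) {
    abort("distance matrix needs one unique id per row",
          class = "alnvalid_contract_error")
  }
  if (any(!is.finite(values))) {
    abort("distance matrix contains non-finite values",
          class = "alnvalid_contract_error")
  }
  if (max(abs(values - t(values))) > tol) {
    abort("distance matrix is not symmetric", class = "alnvalid_contract_error")
  }
  if (any(values < -tol) || any(values > 1 + tol)) {
    abort("distances must lie in [0, 1]", class = "alnvalid_contract_error")
  }
  if (max(abs(diag(values))) > tol) {
    abort("distance matrix diagonal must be zero",
          class = "alnvalid_contract_error")
  }
  values <- (values + t(values)) / 2
  values[values < 0] <- 0
  values[values > 1] <- 1
  diag(values) <- 0
  dimnames(values) <- list(ids, ids)
  class(values) <- c("aln_dist", class(matrix()))
  values
}

#' @export
print.aln_dist <- function(x, ...) {
  cat("<aln_dist> ", nrow(x), " sequences\n", sep = "")
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x))), drop = FALSE], ...)
  if (nrow(x) > 6) cat("... (", nrow(x) - 6, " more rows)\n", sep = "")
  invisible(x)
}

#' Tidy a distance matrix into a long pair table
#'
#' @param x An [aln_dist] matrix.
#' @param ... Unused.
#' @return A tibble with one row per unordered sequence pair: `id_a`, `id_b`,
#'   `distance`.
#' @export
tidy.aln_dist <- function(x, ...) {
  ids <- rownames(x)
  idx <- which(upper.tri(x), arr.ind = TRUE)
  tibble(id_a = ids[idx[, 1]], id_b = ids[idx[, 2]],
         distance = x[idx])
}

#' @export
as.dist.aln_dist <- function(m, diag = FALSE, upper = FALSE) {
  stats::as.dist(unclass(m), diag = diag, upper = upper)
}

#' Write a distance matrix to disk
#'
#' Two plain-text dialects are supported: `tsv` (a header row of ids, then one
#' row per sequence with its id in the first column) and `phylip` (square
#' PHYLIP: a first line with the sequence count, then one row per sequence).
#' Values are written with 10 decimal places, so write/read round-trips agree
#' to well under 1e-9.
#'
#' @param m An [aln_dist] matrix (or a plain symmetric matrix with ids as
#'   dimnames).
#' @param path Output path.
#' @param dialect `"tsv"` or `"phylip"`.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(m, path, dialect = c("tsv", "phylip")) {
  dialect <- match.arg(dialect)
  m <- aln_dist(m) # validates symmetry/range/diagonal
  ids <- rownames(m)
  fmt <- function(row) sprintf("%.10f", row)
  lines <- character(0)
  if (dialect == "tsv") {
    lines <- c(paste(c("id", ids), collapse = "\t"),
               vapply(seq_along(ids), function(i) {
                 paste(c(ids[i], fmt(m[i, ])), collapse = "\t")
               }, character(1)))
  } else {
    lines <- c(sprintf("%d", length(ids)),
               vapply(seq_along(ids), function(i) {
                 paste(c(ids[i], fmt(m[i, ])), collapse = " ")
               }, character(1)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a distance matrix written by [write_distance_matrix()]
#'
#' @param path Input path.
#' @param dialect `"auto"` (default; PHYLIP is recognised by its leading
#'   count line), `"tsv"` or `"phylip"`.
#' @return An [aln_dist] matrix.
#' @export
read_distance_matrix <- function(path, dialect = c("auto", "tsv", "phylip")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort(paste0("distance file not found: ", path), class = "alnvalid_io_error")
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    abort(paste0("distance file '", path, "' is empty"),
          class = "alnvalid_format_error")
  }
  if (dialect == "auto") {
    dialect <- if (grepl("^\\s*[0-9]+\\s*$", lines[1])) "phylip" else "tsv"
  }
  if (dialect == "phylip") {
    n <- as.integer(trimws(lines[1]))
    body <- lines[-1]
    if (length(body) != n) {
      abort(paste0("PHYLIP distance file '", path, "' declares ", n,
                   " rows but has ", length(body)),
            class = "alnvalid_format_error")
    }
    parts <- strsplit(trimws(body), "\\s+")
    ids <- vapply(parts, `[[`, character(1), 1)
    vals <- lapply(parts, function(p) as.numeric(p[-1]))
  } else {
    parts <- strsplit(body <- lines, "\t", fixed = TRUE)
    header <- parts[[1]]
    if (identical(tolower(header[1]), "id")) {
      parts <- parts[-1]
    }
    ids <- vapply(parts, `[[`, character(1), 1)
    vals <- lapply(parts, function(p) as.numeric(p[-1]))
  }
  lens <- lengths(vals)
  if (length(unique(lens)) != 1 || lens[1] != length(ids)) {
    abort(paste0("ragged or non-square distance file '", path, "'"),
          class = "alnvalid_format_error")
  }
  values <- do.call(rbind, vals)
  if (anyNA(values)) {
    abort(paste0("non-numeric entries in distance file '", path, "'"),
          class = "alnvalid_format_error")
  }
  aln_dist(values, ids, tol = 1e-8)
}
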