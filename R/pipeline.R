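#' Assemble a labeled benchmark dataset from per-family FASTA files
#'
#' Pools the sequences of several protein families into one labeled dataset.
#' Each input file contributes one family; the family label is the file's
#' name in `family_files`. A sequence id that occurs under more than one
#' family would make its class label ambiguous, so such sequences are
#' excluded entirely (a message reports them).
#'
#' @param family_files A named character vector of FASTA paths (names are the
#'   family labels), or a tibble/data frame with columns `family` and `path`.
#'   At least two families are required.
#' @return A labeled sequence tibble with columns `id`, `residues`, `family`.
#' @export
build_benchmark_group <- function(family_files) {
  if (is.data.frame(family_files)) {
    stopifnot(all(c("family", "path") %in% names(family_files)))
    paths <- setNames(family_files$path, family_files$family)
  } else {
    paths <- family_files
  }
  if (length(paths) < 2 || is.null(names(paths)) || any(!nzchar(names(paths)))) {
    abort("need at least two named family FASTA files",
          class = "alnvalid_contract_error")
  }
  ds <- purrr::imap(paths, function(p, fam) {
    dplyr::mutate(read_fasta(p, aligned = FALSE), family = fam)
  })
  ds <- dplyr::bind_rows(ds)
  multi <- ds |>
    dplyr::distinct(.data$id, .data$family) |>
    dplyr::count(.data$id) |>
    dplyr::filter(.data$n > 1) |>
    dplyr::pull(.data$id)
  if (length(multi) > 0) {
    message("excluding ", length(multi),
            " sequence(s) present in more than one family: ",
            paste(head(multi, 10), collapse = ", "))
    ds <- dplyr::filter(ds, !.data$id %in% multi)
  }
  ds <- dplyr::distinct(ds)
  if (nrow(ds) == 0) {
    abort("all sequences were excluded as multi-family; dataset is empty",
          class = "alnvalid_empty_dataset_error")
  }
  if (anyDuplicated(ds$id)) {
    abort("duplicate sequence ids with conflicting residues within a family",
          class = "alnvalid_format_error")
  }
  as_tibble(ds)
}

#' Resample a labeled dataset without replacement
#'
#' Draws `floor(fraction * n)` sequences uniformly at random without
#' replacement (unstratified — family proportions are preserved only in
#' expectation), `reps` times. All randomness flows from `seed`; each
#' replicate uses its own draw from a single seeded stream, so the same
#' `(dataset, fraction, reps, seed)` always yields the same replicates.
#' Sequences keep their original relative order so downstream matrices stay
#' aligned with the dataset.
#'
#' @param ds A labeled sequence tibble (`id`, `residues`, `family`).
#' @param fraction Fraction of sequences to keep, in (0, 1]; `fraction = 1`
#'   returns full copies.
#' @param reps Number of replicates (>= 1).
#' @param seed Integer seed.
#' @return A list of `reps` labeled sequence tibbles.
#' @export
resample_dataset <- function(ds, fraction = 0.9, reps = 10, seed = 1) {
  stopifnot(is.data.frame(ds), nrow(ds) >= 2)
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    abort("fraction must be in (0, 1]", class = "alnvalid_contract_error")
  }
  stopifnot(reps >= 1)
  n <- nrow(ds)
  k <- floor(fraction * n)
  if (k < 2) {
    abort(paste0("floor(fraction * n) = ", k,
                 " leaves fewer than 2 sequences"),
          class = "alnvalid_contract_error")
  }
  withr::with_seed(as.integer(seed), {
    lapply(seq_len(reps), function(r) {
      idx <- sort(sample.int(n, k))
      ds[idx, , drop = FALSE]
    })
  })
}

#' Bundle a dataset with its resampling replicates
#'
#' A benchmark group is one named dataset plus its subsampled replicates
#' (default: 90% of the sequences, drawn 10 times), the unit on which
#' alignment methods are evaluated and compared.
#'
#' @param ds A labeled sequence tibble (`id`, `residues`, `family`).
#' @param name Group name (e.g. `"RV11"`).
#' @param reps Number of resampling replicates.
#' @param fraction Subsample fraction.
#' @param seed Integer seed for the resampling stream.
#' @return An object of class `aln_benchmark_group`.
#' @export
benchmark_group <- function(ds, name, reps = 10, fraction = 0.9, seed = 1) {
  stopifnot(is.character(name), length(name) == 1)
  resamples <- resample_dataset(ds, fraction = fraction, reps = reps, seed = seed)
  names(resamples) <- sprintf("resample_%02d", seq_len(reps))
  structure(
    list(name = name, original = ds, resamples = resamples,
         fraction = fraction, seed = as.integer(seed)),
    class = "aln_benchmark_group"
  )
}

#' @export
print.aln_benchmark_group <- function(x, ...) {
  cat("<aln_benchmark_group> ", x$name, ": ", nrow(x$original),
      " sequences, ", length(unique(x$original$family)), " families, ",
      length(x$resamples), " resamples (fraction ", x$fraction, ", seed ",
      x$seed, ")\n", sep = "")
  invisible(x)
}

#' Alignment method configurations
#'
#' `psa_method()` configures the built-in pairwise route: every sequence pair
#' is globally aligned with [nw_align()] and distances come from
#' [all_pairs_distances()]. `msa_method()` configures an external multiple
#' aligner invoked as a subprocess: the dataset is written as unaligned
#' FASTA, the command is run, its gapped FASTA output is read back and
#' distances come from [msa_distance_matrix()].
#'
#' @param id Method identifier used in score tables.
#' @param matrix,gap_open,gap_extend,mode Passed to [score_params()].
#' @param gap_policy Gap-column policy for identity, see
#'   [pairwise_identity()].
#' @param command External executable name or path (resolved on PATH at run
#'   time).
#' @param args Character vector of arguments; the placeholders `{input}` and
#'   `{output}` are substituted with the FASTA paths. If no `{output}`
#'   placeholder is present the aligner's stdout is captured as the aligned
#'   FASTA (the MAFFT convention).
#' @return An object of class `aln_method`.
#' @name method_config
NULL

#' @rdname method_config
#' @export
psa_method <- function(id = "psa-nw", matrix = "BLOSUM62", gap_open = -10,
                       gap_extend = -1, mode = "affine",
                       gap_policy = "keep-all") {
  structure(
    list(id = id, kind = "internal-psa",
         params = score_params(matrix, gap_open, gap_extend, mode),
         gap_policy = gap_policy),
    class = "aln_method"
  )
}

#' @rdname method_config
#' @export
msa_method <- function(id, command, args = c("{input}"),
                       gap_policy = "keep-all") {
  stopifnot(is.character(id), length(id) == 1,
            is.character(command), length(command) == 1,
            is.character(args))
  structure(
    list(id = id, kind = "external-msa", command = command, args = args,
         gap_policy = gap_policy),
    class = "aln_method"
  )
}

#' @export
print.aln_method <- function(x, ...) {
  cat("<aln_method> ", x$id, " (", x$kind, ")\n", sep = "")
  invisible(x)
}

#' Run one alignment method on one dataset
#'
#' @param ds A labeled sequence tibble (`id`, `residues`, ...).
#' @param method An [psa_method()] or [msa_method()] configuration.
#' @param workdir Scratch directory for external runs (created if needed).
#' @return An [aln_dist] distance matrix whose ids equal `ds$id`.
#' @export
run_method <- function(ds, method, workdir = tempfile("alnvalid_run_")) {
  stopifnot(inherits(method, "aln_method"), is.data.frame(ds))
  if (method$kind == "internal-psa") {
    return(all_pairs_distances(ds, method$params))
  }
  exe <- Sys.which(method$command)
  if (!nzchar(exe)) {
    abort(paste0("external aligner '", method$command, "' not found on PATH"),
          class = "alnvalid_tool_error")
  }
  dir.create(workdir, recursive = TRUE, showWarnings = FALSE)
  input <- file.path(workdir, "input.fasta")
  output <- file.path(workdir, "aligned.fasta")
  write_fasta(ds, input)
  args <- gsub("{input}", input, method$args, fixed = TRUE)
  to_stdout <- !any(grepl("{output}", method$args, fixed = TRUE))
  args <- gsub("{output}", output, args, fixed = TRUE)
  if (to_stdout) {
    status <- suppressWarnings(
      system2(exe, args, stdout = output, stderr = file.path(workdir, "stderr.txt"))
    )
  } else {
    status <- suppressWarnings(
      system2(exe, args, stdout = file.path(workdir, "stdout.txt"),
              stderr = file.path(workdir, "stderr.txt"))
    )
  }
  if (!identical(status, 0L)) {
    errtxt <- tryCatch(
      paste(readLines(file.path(workdir, "stderr.txt")), collapse = "\n"),
      error = function(e) "")
    abort(paste0("aligner '", method$id, "' exited with status ", status,
                 if (nzchar(errtxt)) paste0(":\n", errtxt) else ""),
          class = "alnvalid_tool_error")
  }
  aln <- read_fasta(output, aligned = TRUE)
  missing <- setdiff(ds$id, aln$id)
  if (length(missing) > 0) {
    abort(paste0("aligner '", method$id, "' dropped sequence(s): ",
                 paste(head(missing, 10), collapse = ", ")),
          class = "alnvalid_integrity_error")
  }
  aln <- aln[match(ds$id, aln$id), , drop = FALSE]
  degapped <- gsub("-", "", aln$aligned, fixed = TRUE)
  if (!identical(degapped, toupper(ds$residues))) {
    bad <- ds$id[degapped != toupper(ds$residues)]
    abort(paste0("aligner '", method$id, "' altered sequence(s): ",
                 paste(head(bad, 10), collapse = ", ")),
          class = "alnvalid_integrity_error")
  }
  msa_distance_matrix(aln, method$gap_policy)
}

#' Enumerate the alignment runs a benchmark design implies
#'
#' One run is one (dataset, method) pair; each group contributes its original
#' dataset plus every resample. Scheduling a full campaign of 8 groups of 11
#' datasets against 7 method configurations yields 616 runs.
#'
#' @param groups A list of [benchmark_group()] objects.
#' @param methods A list of method configurations.
#' @return A tibble with one row per run: `group`, `dataset`, `method`.
#' @export
schedule_runs <- function(groups, methods) {
  stopifnot(length(groups) >= 1)
  purrr::map_dfr(groups, function(g) {
    stopifnot(inherits(g, "aln_benchmark_group"))
    datasets <- c("original", names(g$resamples))
    tidyr::expand_grid(group = g$name, dataset = datasets,
                       method = purrr::map_chr(methods, "id"))
  })
}

#' Score every dataset of a group under every method
#'
#' Runs each configured alignment method on the group's original dataset and
#' on each resample, scores the resulting distance matrix against the family
#' labels, and returns one row per (dataset, method) with the SW and RS
#' scores — `(1 + reps) * length(methods)` rows in total.
#'
#' @param group An [benchmark_group()] object.
#' @param methods A list of [psa_method()] / [msa_method()] configurations.
#' @param within_center RS within-cluster centring, see [rs_score()].
#' @return A tibble with columns `group`, `dataset`, `method`, `n`, `sw`, `rs`.
#' @export
evaluate_group <- function(group, methods, within_center = "cluster") {
  stopifnot(inherits(group, "aln_benchmark_group"))
  if (length(methods) == 0) {
    warn("no methods configured; returning an empty score table")
    return(tibble(group = character(), dataset = character(),
                  method = character(), n = integer(),
                  sw = numeric(), rs = numeric()))
  }
  datasets <- c(list(original = group$original), group$resamples)
  purrr::map_dfr(names(datasets), function(dname) {
    ds <- datasets[[dname]]
    purrr::map_dfr(methods, function(m) {
      v <- tryCatch(
        validity_scores(run_method(ds, m), ds[, c("id", "family")],
                        within_center = within_center),
        error = function(e) {
          abort(paste0("evaluation failed for group ", group$name,
                       ", dataset ", dname, ", method ", m$id, ": ",
                       conditionMessage(e)),
                class = "alnvalid_pipeline_error")
        }
      )
      tibble(group = group$name, dataset = dname, method = m$id,
             n = v$n, sw = v$sw, rs = v$rs)
    })
  })
}

#' Compare two methods' scores over matched resamples with a t-test
#'
#' Runs a two-sided t-test (Welch by default; paired optionally, since
#' resamples are matched across methods) on two equal-length vectors of
#' validity scores, one per resample. A large p-value means the two methods
#' perform indistinguishably on this group; a small one means the difference
#' is systematic. Identical vectors give p = 1 by convention.
#'
#' @param scores_a,scores_b Equal-length numeric score vectors (length >= 2).
#' @param method_a,method_b Method names for reporting.
#' @param score Which score the vectors hold (e.g. `"SW"` or `"RS"`).
#' @param paired Use a paired t-test across matched resamples?
#' @return An object of class `aln_comparison`; `tidy()` turns it into a
#'   one-row tibble.
#' @export
compare_methods <- function(scores_a, scores_b, method_a = "A", method_b = "B",
                            score = "SW", paired = FALSE) {
  if (!is.numeric(scores_a) || !is.numeric(scores_b) ||
      length(scores_a) != length(scores_b) || length(scores_a) < 2) {
    abort("need two equal-length numeric vectors of length >= 2",
          class = "alnvalid_contract_error")
  }
  if (isTRUE(all.equal(scores_a, scores_b, tolerance = 0)) ||
      identical(scores_a, scores_b)) {
    statistic <- 0
    p_value <- 1
  } else if (stats::sd(scores_a) == 0 && stats::sd(scores_b) == 0 && !paired) {
    # two different constants: infinitely strong evidence of a difference
    statistic <- sign(mean(scores_a) - mean(scores_b)) * Inf
    p_value <- 0
  } else if (paired && stats::sd(scores_a - scores_b) == 0) {
    statistic <- sign(mean(scores_a) - mean(scores_b)) * Inf
    p_value <- if (mean(scores_a - scores_b) == 0) 1 else 0
  } else {
    tt <- t.test(scores_a, scores_b, alternative = "two.sided",
                 paired = paired, var.equal = FALSE)
    statistic <- unname(tt$statistic)
    p_value <- unname(tt$p.value)
  }
  structure(
    list(method_a = method_a, method_b = method_b, score = score,
         scores_a = scores_a, scores_b = scores_b,
         mean_diff = mean(scores_a) - mean(scores_b),
         statistic = statistic, p_value = p_value, paired = paired),
    class = "aln_comparison"
  )
}

#' @export
print.aln_comparison <- function(x, ...) {
  cat("<aln_comparison> ", x$method_a, " vs ", x$method_b, " (", x$score,
      if (x$paired) ", paired" else ", Welch", ")\n",
      "  mean diff ", sprintf("%.6f", x$mean_diff),
      ", p = ", format(x$p_value, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Tidy method for method comparisons
#'
#' @param x An `aln_comparison` object.
#' @param ... Unused.
#' @return One-row tibble: `method_a`, `method_b`, `score`, `n`,
#'   `mean_a`, `mean_b`, `mean_diff`, `statistic`, `p_value`.
#' @export
tidy.aln_comparison <- function(x, ...) {
  tibble(method_a = x$method_a, method_b = x$method_b, score = x$score,
         n = length(x$scores_a), mean_a = mean(x$scores_a),
         mean_b = mean(x$scores_b), mean_diff = x$mean_diff,
         statistic = x$statistic, p_value = x$p_value)
}

#' All pairwise method comparisons from a score table
#'
#' For each group and each unordered pair of methods, compares the resample
#' score vectors (the `original` row is excluded) with [compare_methods()],
#' once for SW and once for RS.
#'
#' @param scores A score table from [evaluate_group()] (rows from several
#'   groups may be bound together).
#' @param paired Use paired t-tests?
#' @return A tibble with one row per (group, method pair, score).
#' @export
compare_scores <- function(scores, paired = FALSE) {
  stopifnot(all(c("group", "dataset", "method", "sw", "rs") %in% names(scores)))
  res <- scores |>
    dplyr::filter(.data$dataset != "original") |>
    dplyr::arrange(.data$group, .data$method, .data$dataset)
  purrr::map_dfr(split(res, res$group), function(gtab) {
    methods <- unique(gtab$method)
    if (length(methods) < 2) return(tibble())
    pairs <- combn(methods, 2, simplify = FALSE)
    purrr::map_dfr(pairs, function(p) {
      a <- gtab[gtab$method == p[1], ]
      b <- gtab[gtab$method == p[2], ]
      stopifnot(identical(a$dataset, b$dataset))
      dplyr::bind_rows(
        dplyr::mutate(tidy(compare_methods(a$sw, b$sw, p[1], p[2], "SW",
                                           paired = paired)),
                      group = gtab$group[1], .before = 1),
        dplyr::mutate(tidy(compare_methods(a$rs, b$rs, p[1], p[2], "RS",
                                           paired = paired)),
                      group = gtab$group[1], .before = 1)
      )
    })
  })
}

#' Write benchmark report tables
#'
#' Writes the score table and the comparison table as TSV (scores to 6
#' decimal places) plus a summary naming the best method per group per score
#' (by mean over resamples). Re-running on identical inputs produces
#' byte-identical files.
#'
#' @param scores Score table from [evaluate_group()].
#' @param comparisons Comparison table from [compare_scores()] (may be empty).
#' @param dir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
report <- function(scores, comparisons, dir) {
  stopifnot(is.data.frame(scores), nrow(scores) > 0)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)

  fmt6 <- function(x) sprintf("%.6f", x)
  sc <- dplyr::mutate(scores, sw = fmt6(.data$sw), rs = fmt6(.data$rs))
  f <- file.path(dir, "scores.tsv")
  readr::write_tsv(sc, f, progress = FALSE)
  files <- c(files, f)

  summary_tab <- scores |>
    dplyr::filter(.data$dataset != "original") |>
    tidyr::pivot_longer(c("sw", "rs"), names_to = "score",
                        values_to = "value") |>
    dplyr::group_by(.data$group, .data$score, .data$method) |>
    dplyr::summarise(mean_score = mean(.data$value), .groups = "drop_last") |>
    dplyr::slice_max(.data$mean_score, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::rename(best_method = "method") |>
    dplyr::mutate(mean_score = fmt6(.data$mean_score),
                  score = toupper(.data$score)) |>
    dplyr::arrange(.data$group, .data$score)
  f <- file.path(dir, "summary.tsv")
  readr::write_tsv(summary_tab, f, progress = FALSE)
  files <- c(files, f)

  if (!is.null(comparisons) && nrow(comparisons) > 0) {
    cmp <- dplyr::mutate(
      comparisons,
      dplyr::across(dplyr::where(is.numeric), ~ sprintf("%.6g", .x))
    )
    f <- file.path(dir, "comparisons.tsv")
    readr::write_tsv(cmp, f, progress = FALSE)
    files <- c(files, f)
  }
  invisible(files)
}
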