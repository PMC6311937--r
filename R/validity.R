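# Normalise labels (tibble id/family or named vector) to a character vector
# aligned with the matrix row order; every id must have exactly one label.
as_label_vector <- function(labels, ids) {
  if (is.data.frame(labels)) {
    stopifnot(all(c("id", "family") %in% names(labels)))
    if (anyDuplicated(labels$id)) {
      abort("labels map an id to more than one family",
            class = "alnvalid_label_error")
    }
    labels <- setNames(as.character(labels$family), labels$id)
  }
  if (is.null(names(labels))) {
    if (length(labels) != length(ids)) {
      abort("unnamed label vector must match the number of sequences",
            class = "alnvalid_contract_error")
    }
    names(labels) <- ids
  }
  missing <- setdiff(ids, names(labels))
  if (length(missing) > 0) {
    abort(paste0("no family label for id(s): ",
                 paste(head(missing, 5), collapse = ", ")),
          class = "alnvalid_label_error")
  }
  as.character(labels[ids])
}

#' Per-sequence silhouette values from a distance matrix and family labels
#'
#' For sequence i with family label C, `a(i)` is the average distance to the
#' other members of C and `b(i)` the minimum, over the other families, of the
#' average distance from i to that family's members. The silhouette is
#' `S(i) = (b(i) - a(i)) / max(a(i), b(i))`, in \[-1, 1\]. A sequence that is
#' the only member of its family gets `S(i) = 0` (the standard neutral
#' convention), which keeps scores defined on subsamples that strand a family
#' with one member.
#'
#' No clustering is run: labels are the known protein families, and the
#' silhouette measures how well the distance structure separates them.
#'
#' @param d An [aln_dist] distance matrix (or symmetric matrix with id
#'   dimnames).
#' @param labels Family labels: a tibble with columns `id`, `family`, or a
#'   (named) character vector. At least two distinct families are required.
#' @return A tibble with one row per sequence: `id`, `family`, `silhouette`.
#' @export
silhouette_values <- function(d, labels) {
  d <- aln_dist(d)
  ids <- rownames(d)
  fam <- as_label_vector(labels, ids)
  ufam <- unique(fam)
  if (length(ufam) < 2) {
    abort("silhouette needs at least 2 distinct families",
          class = "alnvalid_contract_error")
  }
  n <- length(ids)
  # column sums of distances from each sequence to each family, n x k
  ind <- outer(fam, ufam, "==") * 1
  sums <- unclass(d) %*% ind
  counts <- colSums(ind)
  own <- match(fam, ufam)
  s <- numeric(n)
  for (i in seq_len(n)) {
    n_own <- counts[own[i]] - 1
    if (n_own == 0) { s[i] <- 0; next }
    a <- sums[i, own[i]] / n_own
    b <- min(sums[i, -own[i]] / counts[-own[i]])
    s[i] <- (b - a) / max(a, b)
    if (!is.finite(s[i])) s[i] <- 0 # a == b == 0
  }
  tibble(id = ids, family = fam, silhouette = s)
}

#' Silhouette-width score
#'
#' The arithmetic mean of the per-sequence silhouettes (see
#' [silhouette_values()]); near 1 when families are well separated by the
#' distances, near -1 when the labeling fits the distances poorly.
#'
#' @inheritParams silhouette_values
#' @return A single number in \[-1, 1\].
#' @export
sw_score <- function(d, labels) {
  mean(silhouette_values(d, labels)$silhouette)
}

#' RS (R-squared) cluster-validity score
#'
#' Treats every unordered pairwise distance as an observation and measures
#' how much of its squared variation is explained by the family partition:
#' `RS = (SS_t - SS_w) / SS_t`, where `SS_t` is the total sum of squared
#' deviations of all pairwise distances about their global mean and `SS_w`
#' sums, over families, the squared deviations of within-family distances.
#' RS lies in \[0, 1\]; higher means within-family distances are more
#' homogeneous relative to the whole, i.e. better separation.
#'
#' Two readings of the within-cluster centring are supported: the default
#' deviates each family's within-pair distances about that family's own mean
#' within-distance (the classical within/total decomposition); with
#' `within_center = "global"` they deviate about the global mean instead.
#'
#' Degenerate case: when all pairwise distances are equal, `SS_t = 0` and no
#' separable structure exists; RS is defined as 0.
#'
#' @inheritParams silhouette_values
#' @param within_center `"cluster"` (default) or `"global"`; see Details.
#' @return A single number in \[0, 1\].
#' @export
rs_score <- function(d, labels, within_center = c("cluster", "global")) {
  rs_components(d, labels, within_center)$rs
}

rs_components <- function(d, labels, within_center = c("cluster", "global")) {
  within_center <- match.arg(within_center)
  d <- aln_dist(d)
  ids <- rownames(d)
  fam <- as_label_vector(labels, ids)
  ut <- upper.tri(d)
  x_all <- unclass(d)[ut]
  same <- outer(fam, fam, "==")[ut]
  if (!any(same)) {
    abort("RS needs at least one within-family pair",
          class = "alnvalid_contract_error")
  }
  xbar <- mean(x_all)
  ss_t <- sum((x_all - xbar)^2)
  fam_pair <- outer(fam, fam, function(a, b) ifelse(a == b, a, NA))[ut]
  x_w <- x_all[same]
  f_w <- fam_pair[same]
  if (within_center == "cluster") {
    centers <- tapply(x_w, f_w, mean)
    ss_w <- sum((x_w - centers[f_w])^2)
  } else {
    ss_w <- sum((x_w - xbar)^2)
  }
  rs <- if (ss_t == 0) 0 else (ss_t - ss_w) / ss_t
  list(rs = rs, ss_t = ss_t, ss_w = ss_w)
}

#' Cluster-validity scores for one distance matrix and labeling
#'
#' Computes the per-sequence silhouettes, the silhouette-width (SW) score and
#' the RS score for a distance matrix against known family labels, bundled in
#' one result object with [tidy()], [glance()] and [autoplot()] methods.
#'
#' @inheritParams rs_score
#' @return An object of class `aln_validity` with fields `silhouettes`
#'   (tibble), `sw`, `rs`, `ss_t`, `ss_w`, `n`, `n_families`.
#' @examples
#' d <- aln_dist(matrix(c(0, .1, .8, .1, 0, .7, .8, .7, 0), 3),
#'               ids = c("s1", "s2", "s3"))
#' validity_scores(d, c(s1 = "A", s2 = "A", s3 = "B"))
#' @export
validity_scores <- function(d, labels, within_center = c("cluster", "global")) {
  within_center <- match.arg(within_center)
  sil <- silhouette_values(d, labels)
  rs <- rs_components(d, labels, within_center)
  structure(
    list(silhouettes = sil, sw = mean(sil$silhouette), rs = rs$rs,
         ss_t = rs$ss_t, ss_w = rs$ss_w, n = nrow(sil),
         n_families = length(unique(sil$family)),
         within_center = within_center),
    class = "aln_validity"
  )
}

#' @export
print.aln_validity <- function(x, ...) {
  cat("<aln_validity> ", x$n, " sequences, ", x$n_families, " families\n",
      "  SW = ", sprintf("%.6f", x$sw), "   RS = ", sprintf("%.6f", x$rs),
      "\n", sep = "")
  invisible(x)
}

#' Tidy method for validity results: one row per sequence
#'
#' @param x An `aln_validity` object.
#' @param ... Unused.
#' @return The per-sequence silhouette tibble (`id`, `family`, `silhouette`).
#' @export
tidy.aln_validity <- function(x, ...) x$silhouettes

#' Glance method for validity results: one summary row
#'
#' @param x An `aln_validity` object.
#' @param ... Unused.
#' @return A one-row tibble with `n`, `n_families`, `sw`, `rs`, `ss_t`, `ss_w`.
#' @export
glance.aln_validity <- function(x, ...) {
  tibble(n = x$n, n_families = x$n_families, sw = x$sw, rs = x$rs,
         ss_t = x$ss_t, ss_w = x$ss_w)
}
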