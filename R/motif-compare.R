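#' Flatten a capped motif into a comparison vector
#'
#' Deterministic flattening used for motif-to-motif correlation: positions
#' ascending (-5..+4), residues in the fixed library alphabet order within
#' each position; the normalized acceptor pool values (S, T, Y) are
#' appended iff `include_acceptor` is `TRUE`. Clustering operates on the
#' linear capped values, not the log2 values.
#'
#' @param motif A [motif_matrix()] at stage `capped`.
#' @param include_acceptor Append the acceptor pool values?
#' @return Named numeric vector of length 198 (or 201 with acceptor).
#' @export
motif_vector <- function(motif, include_acceptor = FALSE) {
  require_stage(motif, "capped", "motif_vector")
  v <- as.vector(t(motif$values))  # position-major: all residues of -5 first
  names(v) <- as.vector(outer(colnames(motif$values),
                              rownames(motif$values),
                              function(r, p) paste0(p, ":", r)))
  if (include_acceptor) {
    acc <- motif$acceptor
    if (is.null(acc) || length(acc) < 3L) {
      stop_opls("input",
                "include_acceptor = TRUE requires all three acceptor pools")
    }
    acc <- acc[OPLS_ACCEPTORS]
    names(acc) <- paste0("0:", OPLS_ACCEPTORS)
    v <- c(v, acc)
  }
  v
}

#' Pairwise Pearson similarity between kinase motif vectors
#'
#' @param vectors Named list of equal-length numeric vectors, one per
#'   kinase (as from [motif_vector()]).
#' @param min_overlap Minimum number of jointly non-missing entries
#'   required per pair; pairs below it are an error. Missing cells use
#'   pairwise-complete correlation.
#' @param metric_tag Free-text tag recorded on the result.
#' @return Object of class `SimilarityMatrix`: list with `ids`, `values`
#'   (symmetric correlation matrix, unit diagonal), `metric_tag`.
#' @export
similarity_matrix <- function(vectors, min_overlap = 150L,
                              metric_tag = "pearson_capped") {
  if (!is.list(vectors) || length(vectors) < 2L) {
    stop_opls("input", "need at least 2 kinases to compare")
  }
  ids <- names(vectors)
  if (is.null(ids) || anyDuplicated(ids)) {
    stop_opls("input", "vectors must be uniquely named by kinase id")
  }
  len <- unique(lengths(vectors))
  if (length(len) != 1L) {
    stop_opls("input", "motif vectors differ in length: %s",
              paste(lengths(vectors), collapse = ","))
  }
  mat <- do.call(cbind, vectors)
  sds <- apply(mat, 2L, stats::sd, na.rm = TRUE)
  if (any(!is.finite(sds) | sds == 0)) {
    stop_opls("degenerate", "zero-variance motif vector(s): %s",
              paste(ids[!is.finite(sds) | sds == 0], collapse = ", "))
  }
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (j <= i) next
      n_ok <- sum(stats::complete.cases(mat[, c(i, j)]))
      if (n_ok < min_overlap) {
        stop_opls("input",
                  "kinases %s and %s share only %d complete cells (< %d)",
                  ids[i], ids[j], n_ok, min_overlap)
      }
    }
  }
  r <- stats::cor(mat, use = "pairwise.complete.obs")
  diag(r) <- 1
  dimnames(r) <- list(ids, ids)
  structure(list(ids = ids, values = r, metric_tag = metric_tag),
            class = "SimilarityMatrix")
}

#' @export
print.SimilarityMatrix <- function(x, ...) {
  cat(sprintf("SimilarityMatrix (%s): %d ids\n", x$metric_tag,
              length(x$ids)))
  print(round(x$values, 3))
  invisible(x)
}

#' Cluster kinases by motif similarity (one-minus-Pearson, average linkage)
#'
#' Converts a Pearson similarity matrix into distances `d = 1 - r` and
#' builds an average-linkage (UPGMA) tree. Kinase ids are ordered
#' lexicographically before clustering so tie-breaking is deterministic.
#'
#' @param sim A [similarity_matrix()] (Pearson metric).
#' @return Object of class `KinaseDendrogram`: list with the `hclust`
#'   object (`$hclust`, heights are one-minus-Pearson distances), the
#'   `ape::phylo` tree (`$phylo`, ultrametric, node depths = height / 2),
#'   and `$ids`.
#' @export
cluster_kinases <- function(sim) {
  if (!inherits(sim, "SimilarityMatrix")) {
    stop_opls("input", "cluster_kinases expects a SimilarityMatrix")
  }
  ord <- order(sim$ids)
  d <- 1 - sim$values[ord, ord]
  d[d < 0 & d > -1e-12] <- 0  # guard against r marginally above 1
  hc <- hclust(as.dist(d), method = "average")
  if (is.unsorted(hc$height)) {
    stop_opls("internal", "average-linkage heights are not monotone")
  }
  structure(list(hclust = hc, phylo = ape::as.phylo(hc),
                 ids = sim$ids[ord]),
            class = "KinaseDendrogram")
}

#' @export
print.KinaseDendrogram <- function(x, ...) {
  cat(sprintf("KinaseDendrogram over %d kinases; merge heights: %s\n",
              length(x$ids),
              paste(sprintf("%.3g", x$hclust$height), collapse = ", ")))
  cat(" ", ape::write.tree(x$phylo), "\n")
  invisible(x)
}

#' Two-group split at the root of a dendrogram
#'
#' @param dendro A [cluster_kinases()] result.
#' @return Named integer vector of group labels (1 or 2) from cutting the
#'   tree into two clusters at the root.
#' @export
root_bipartition <- function(dendro) {
  if (!inherits(dendro, "KinaseDendrogram")) {
    stop_opls("input", "root_bipartition expects a KinaseDendrogram")
  }
  stats::cutree(dendro$hclust, k = 2L)
}

#' Percent sequence identity over an alignment
#'
#' Identity between two aligned sequences is the number of identical
#' residues divided by the number of alignment columns where neither
#' sequence has a gap (`-`), times 100.
#'
#' @param aligned Named character vector of equal-length aligned sequences
#'   (or a named list of single strings).
#' @return A `SimilarityMatrix` with `metric_tag = "pct_identity"`,
#'   diagonal 100.
#' @export
sequence_identity_matrix <- function(aligned) {
  aligned <- vapply(aligned, as.character, "")
  ids <- names(aligned)
  if (is.null(ids) || length(aligned) < 2L) {
    stop_opls("input", "need >= 2 named aligned sequences")
  }
  n <- length(aligned)
  lens <- nchar(aligned)
  if (length(unique(lens)) != 1L) {
    stop_opls("alignment", "aligned sequences differ in length: %s",
              paste(lens, collapse = ","))
  }
  chars <- lapply(aligned, function(s) strsplit(toupper(s), "")[[1L]])
  values <- matrix(100, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      a <- chars[[i]]; b <- chars[[j]]
      ok <- a != "-" & b != "-"
      if (!any(ok)) {
        stop_opls("alignment", "%s and %s share no ungapped columns",
                  ids[i], ids[j])
      }
      pid <- 100 * sum(a[ok] == b[ok]) / sum(ok)
      values[i, j] <- pid
      values[j, i] <- pid
    }
  }
  structure(list(ids = ids, values = values, metric_tag = "pct_identity"),
            class = "SimilarityMatrix")
}

#' Sequence-logo letter heights from a log2 motif
#'
#' The letter height for (position, residue) is the log2 motif value
#' itself: 0 for a neutral residue (normalized intensity 1), positive for
#' favored, negative for disfavored. Logos drawn from these heights show
#' favored residues above the axis and disfavored ones below; the
#' `favored_only` variant zeroes the negative heights for a conventional
#' favored-residue logo.
#'
#' @param motif A [motif_matrix()] at stage `log2`.
#' @param favored_only Zero out negative heights?
#' @return Numeric 9 x 22 matrix of signed heights.
#' @export
logo_heights <- function(motif, favored_only = FALSE) {
  require_stage(motif, "log2", "logo_heights")
  h <- motif$values
  if (favored_only) h[h < 0] <- 0
  h
}
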