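#' Build a position-specific scoring matrix from a capped motif
#'
#' Takes the capped linear motif values over the 20 standard amino acids
#' at the nine flank positions as PSSM entries. The pT/pY columns are
#' split into a modified-residue table, consulted only when a window
#' annotates a residue as already phosphorylated (lowercase `t`/`y`).
#' Missing cells get the neutral value 1 (no information, no penalty);
#' entries below `floor` are clamped to keep all entries positive.
#'
#' @param motif A [motif_matrix()] at stage `capped`.
#' @param acceptor_set Which central acceptors the kinase phosphorylates;
#'   default from the library (`ST` -> S and T, `Y` -> Y). Sites with other
#'   acceptors are rejected by [filter_sites()] rather than penalized.
#' @param floor Positivity floor for entries, default `2^-6`.
#' @return Object of class `ScoringMatrix`: `entries` (9 x 20, strictly
#'   positive), `mod_entries` (9 x 2, pT/pY), `acceptor_set`, `kinase_id`,
#'   plus provenance (`n_replicates`, `floor`).
#' @export
build_scoring_matrix <- function(motif, acceptor_set = NULL, floor = 2^-6) {
  require_stage(motif, "capped", "build_scoring_matrix")
  assert_scalar_number(floor, "floor", positive = TRUE)
  if (is.null(acceptor_set)) {
    acceptor_set <- if (motif$library == "ST") c("S", "T") else "Y"
  }
  if (!all(acceptor_set %in% OPLS_ACCEPTORS)) {
    stop_opls("parameter", "acceptor_set must be a subset of S, T, Y")
  }
  entries <- motif$values[, OPLS_AA20, drop = FALSE]
  entries[is.na(entries)] <- 1
  entries <- pmax(entries, floor)
  mod <- motif$values[, c("pT", "pY"), drop = FALSE]
  mod[is.na(mod)] <- 1
  mod <- pmax(mod, floor)
  structure(
    list(kinase_id = motif$kinase_id, entries = entries, mod_entries = mod,
         acceptor_set = acceptor_set, floor = floor,
         n_replicates = motif$n_replicates),
    class = "ScoringMatrix"
  )
}

#' @export
print.ScoringMatrix <- function(x, ...) {
  cat(sprintf("ScoringMatrix: kinase %s, acceptors {%s}, floor %g\n",
              x$kinase_id, paste(x$acceptor_set, collapse = ","), x$floor))
  opt <- apply(x$entries, 1L, function(r) colnames(x$entries)[which.max(r)])
  cat("  optimal window:", paste(opt, collapse = ""), "\n")
  invisible(x)
}

#' The best-scoring (score 0) window of a scoring matrix
#'
#' @param matrix A [build_scoring_matrix()] result.
#' @return 9-character string taking the per-position argmax residue.
#' @export
optimal_window <- function(matrix) {
  if (!inherits(matrix, "ScoringMatrix")) {
    stop_opls("input", "optimal_window expects a ScoringMatrix")
  }
  paste(apply(matrix$entries, 1L, function(r) {
    colnames(matrix$entries)[which.max(r)]
  }), collapse = "")
}

# per-position log2 deviation from the column optimum; NA for padding
window_deviations <- function(matrix, window) {
  chars <- strsplit(window, "")[[1L]]
  if (length(chars) != 9L) {
    stop_opls("input", "window must be exactly 9 characters, got %d",
              length(chars))
  }
  vapply(seq_len(9L), function(i) {
    ch <- chars[i]
    if (ch == OPLS_PAD) return(NA_real_)
    if (ch %in% c("t", "y")) {
      ent <- matrix$mod_entries[i, if (ch == "t") "pT" else "pY"]
      colmax <- max(matrix$entries[i, ], matrix$mod_entries[i, ])
      return(log2(colmax) - log2(ent))
    }
    if (!(ch %in% OPLS_AA20)) {
      stop_opls("alphabet",
                "window position %d has unknown residue `%s`", i, ch)
    }
    log2(max(matrix$entries[i, ])) - log2(matrix$entries[i, ch])
  }, 0)
}

#' Score candidate phosphosites against a scoring matrix
#'
#' Scansite-style motif-match score: the mean, over scored window
#' positions, of the log2 deviation of the window residue's matrix entry
#' from the best entry in its column. The score is >= 0 and 0 exactly when
#' every residue is column-optimal; lower is better. Padding (`_`) at
#' protein termini is excluded and the mean taken over the remaining
#' positions, keeping truncated and full windows comparable. Lowercase
#' `t`/`y` mark phospho-threonine/-tyrosine and are scored against the
#' pT/pY columns.
#'
#' Because the score depends only on within-column ratios it is invariant
#' to any per-column positive rescaling of the matrix, hence to the
#' normalization stage of the underlying motif.
#'
#' @param matrix A [build_scoring_matrix()] result.
#' @param sites Data frame with columns `protein_id`, `position`,
#'   `acceptor`, `window` (as from [simulate_site_database()] or
#'   [read_sites_tsv()]).
#' @return Data frame of class `site_scores`: the input keys plus
#'   `kinase_id`, `score`, `n_scored_positions` and `percentile_rank`
#'   (fraction of sites scoring <= this site, in (0, 1]; low percentile =
#'   good match).
#' @export
score_sites <- function(matrix, sites) {
  if (!inherits(matrix, "ScoringMatrix")) {
    stop_opls("input", "score_sites expects a ScoringMatrix")
  }
  sites <- as.data.frame(sites)
  need <- c("protein_id", "position", "acceptor", "window")
  if (!all(need %in% names(sites))) {
    stop_opls("input", "sites must have columns %s",
              paste(need, collapse = ", "))
  }
  devs <- lapply(sites$window, window_deviations, matrix = matrix)
  score <- vapply(devs, function(d) {
    if (all(is.na(d))) {
      stop_opls("input", "window is all padding; nothing to score")
    }
    mean(d, na.rm = TRUE)
  }, 0)
  n_scored <- vapply(devs, function(d) sum(!is.na(d)), 0L)
  out <- data.frame(protein_id = sites$protein_id,
                    position = sites$position,
                    acceptor = sites$acceptor,
                    window = sites$window,
                    kinase_id = matrix$kinase_id,
                    score = score,
                    n_scored_positions = n_scored,
                    stringsAsFactors = FALSE)
  if ("group" %in% names(sites)) out$group <- sites$group
  out$percentile_rank <- rank(out$score, ties.method = "max") / nrow(out)
  class(out) <- c("site_scores", "data.frame")
  out
}

#' Score one site window
#'
#' Convenience scalar wrapper around [score_sites()].
#' @param matrix A `ScoringMatrix`.
#' @param window 9-character flank window.
#' @return The numeric score.
#' @export
score_window <- function(matrix, window) {
  d <- window_deviations(matrix, window)
  if (all(is.na(d))) stop_opls("input", "window is all padding")
  mean(d, na.rm = TRUE)
}

#' Filter a candidate-site list for a scoring matrix
#'
#' Removes sites whose acceptor residue the kinase cannot phosphorylate
#' (hard filter, not a score penalty), optionally removes duplicate
#' `(protein_id, position)` keys keeping the first occurrence, and, when a
#' `class` column is present, keeps only class I (confidently localized)
#' sites.
#'
#' @param sites Candidate-site data frame.
#' @param matrix A `ScoringMatrix` providing the acceptor set.
#' @param dedupe Remove duplicate site keys?
#' @param class_filter Keep only rows whose `class` column equals
#'   `"I"`/`"1"` (ignored when no such column exists)?
#' @return Filtered data frame.
#' @export
filter_sites <- function(sites, matrix, dedupe = TRUE,
                         class_filter = TRUE) {
  sites <- as.data.frame(sites)
  keep <- sites$acceptor %in% matrix$acceptor_set
  sites <- sites[keep, , drop = FALSE]
  if (class_filter && "class" %in% names(sites)) {
    sites <- sites[as.character(sites$class) %in% c("I", "1"), ,
                   drop = FALSE]
  }
  if (dedupe) {
    key <- paste(sites$protein_id, sites$position, sep = "@")
    sites <- sites[!duplicated(key), , drop = FALSE]
  }
  rownames(sites) <- NULL
  sites
}

#' Select the best-scoring fraction of sites
#'
#' Selects the `ceiling(fraction * n)` lowest-scoring sites. Ties at the
#' boundary are resolved inclusively: every site tied with the cutoff
#' score is selected, so the returned set can exceed the nominal count
#' (the attached attributes report both). Selection is a pure function of
#' the score multiset, so any strictly monotone transform of the score
#' yields the identical set.
#'
#' @param scores A [score_sites()] data frame.
#' @param fraction Fraction in (0, 1]; e.g. 0.10 for the top 10 percent.
#' @return The selected rows, ordered by score then key; attributes
#'   `nominal_n` (the ceiling count) and `cutoff_score`.
#' @export
percentile_select <- function(scores, fraction = 0.10) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1) {
    stop_opls("parameter", "fraction must be in (0, 1]")
  }
  scores <- as.data.frame(scores)
  n <- nrow(scores)
  if (n == 0L) stop_opls("input", "no scores to select from")
  k <- ceiling(fraction * n)
  cutoff <- sort(scores$score, partial = k)[k]
  sel <- scores[scores$score <= cutoff, , drop = FALSE]
  sel <- sel[order(sel$score, sel$protein_id, sel$position), ,
             drop = FALSE]
  rownames(sel) <- NULL
  attr(sel, "nominal_n") <- k
  attr(sel, "cutoff_score") <- cutoff
  sel
}

site_keys <- function(x) {
  if (is.data.frame(x)) paste(x$protein_id, x$position, sep = "@")
  else as.character(x)
}

#' Overlap of selected target sets across kinases
#'
#' Partitions the union of per-kinase target sets into the 2^k - 1
#' nonempty membership patterns (the regions of a k-set Venn diagram) and
#' counts the sites in each. Also reports, for a designated reference
#' kinase, the fraction of its sites shared with at least one other set.
#'
#' @param selected Named list (2 to 6 entries) of selected-site data
#'   frames or site-key character vectors.
#' @param reference Id of the reference kinase; default the first.
#' @return List with `counts` (named numeric vector; names are
#'   `&`-joined member ids), `n_union`, `reference`,
#'   `reference_shared_fraction`.
#' @export
overlap_analysis <- function(selected, reference = NULL) {
  k <- length(selected)
  if (k < 2L || k > 6L) {
    stop_opls("parameter", "overlap_analysis handles 2 to 6 sets, got %d", k)
  }
  ids <- names(selected)
  if (is.null(ids) || anyDuplicated(ids)) {
    stop_opls("input", "selected sets must be uniquely named")
  }
  keysets <- lapply(selected, function(s) unique(site_keys(s)))
  all_keys <- Reduce(union, keysets)
  membership <- vapply(keysets, function(ks) all_keys %in% ks,
                       logical(length(all_keys)))
  if (length(all_keys) == 1L) membership <- matrix(membership, nrow = 1L)
  pattern <- apply(membership, 1L, function(m) {
    paste(ids[m], collapse = "&")
  })
  counts <- table(pattern)
  # order patterns: by member count, then lexicographically
  nm <- names(counts)
  ord <- order(lengths(strsplit(nm, "&", fixed = TRUE)), nm)
  counts <- setNames(as.numeric(counts), nm)[ord]
  reference <- reference %||% ids[1L]
  if (!(reference %in% ids)) {
    stop_opls("parameter", "reference `%s` is not one of the sets", reference)
  }
  ref_keys <- keysets[[reference]]
  others <- Reduce(union, keysets[setdiff(ids, reference)])
  shared <- if (length(ref_keys) == 0L) NA_real_ else
    mean(ref_keys %in% others)
  list(counts = counts, n_union = length(all_keys),
       reference = reference, reference_shared_fraction = shared)
}

#' Pearson correlation between two kinases' site scores
#'
#' @param scores_a,scores_b [score_sites()] data frames over the same
#'   site keys (order may differ).
#' @return List with `r` (Pearson), `n`, and the aligned `pairs` data
#'   frame (`key`, `score_a`, `score_b`) for scatter export.
#' @export
score_correlation <- function(scores_a, scores_b) {
  ka <- site_keys(scores_a)
  kb <- site_keys(scores_b)
  if (!setequal(ka, kb) || anyDuplicated(ka) || anyDuplicated(kb)) {
    stop_opls("input",
              "score lists must cover identical unique site keys (a: %d, b: %d, common: %d)",
              length(ka), length(kb), length(intersect(ka, kb)))
  }
  m <- match(ka, kb)
  pairs <- data.frame(key = ka, score_a = scores_a$score,
                      score_b = scores_b$score[m],
                      stringsAsFactors = FALSE)
  list(r = stats::cor(pairs$score_a, pairs$score_b), n = nrow(pairs),
       pairs = pairs)
}
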