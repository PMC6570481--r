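#' Normalize a raw spot grid by per-position mean intensity
#'
#' Divides every spot intensity by the mean intensity of all fixed residues
#' at the same flank position, so each position row has mean exactly 1.
#' This removes per-blot exposure differences (the transform is invariant
#' to any global rescaling of the grid) and puts all positions on a common
#' preference scale. Missing spots (`NA`) are excluded from the position
#' mean and stay `NA`; a completeness count is attached.
#'
#' @param grid A [spot_grid()].
#' @return A [motif_matrix()] at stage `normalized`. The acceptor pools, if
#'   present, are carried through normalized by the mean of the pools
#'   present (see [acceptor_preference()]).
#' @examples
#' g <- simulate_spot_grids(make_true_motif("NEKX", seed = 1),
#'                          noise_model(sigma_log = 0), n_replicates = 1)[[1]]
#' m <- normalize_spot_grid(g)
#' rowMeans(m$values)   # all exactly 1
#' @export
normalize_spot_grid <- function(grid) {
  if (!inherits(grid, "SpotGrid")) {
    stop_opls("input", "normalize_spot_grid expects a SpotGrid")
  }
  raw <- grid$flank
  mu <- rowMeans(raw, na.rm = TRUE)
  bad <- !is.finite(mu) | mu <= 0
  if (any(bad)) {
    stop_opls("degenerate",
              "position(s) %s have no positive spot intensity; cannot normalize",
              paste(rownames(raw)[bad], collapse = ", "))
  }
  values <- raw / mu
  acc <- NULL
  if (!is.null(grid$acceptor)) {
    acc <- grid$acceptor / mean(grid$acceptor)
  }
  m <- motif_matrix(grid$kinase_id, values, stage = "normalized",
                    library = grid$library, acceptor = acc,
                    n_replicates = 1L)
  m$n_missing <- sum(is.na(values))
  m
}

#' Average normalized replicates element-wise
#'
#' Takes the unweighted arithmetic mean of two or more normalized replicate
#' matrices from the same kinase and library. Cells missing in a replicate
#' are excluded from that cell's mean. A single replicate is accepted with
#' a warning; the screen design calls for at least two.
#'
#' @param motifs List of [motif_matrix()] objects at stage `normalized`.
#' @return A [motif_matrix()] at stage `averaged` with `n_replicates` set.
#' @export
average_replicates <- function(motifs) {
  if (!is.list(motifs) || length(motifs) == 0L) {
    stop_opls("input", "average_replicates expects a nonempty list")
  }
  for (m in motifs) require_stage(m, "normalized", "average_replicates")
  kin <- unique(vapply(motifs, `[[`, "", "kinase_id"))
  lib <- unique(vapply(motifs, `[[`, "", "library"))
  if (length(kin) != 1L || length(lib) != 1L) {
    stop_opls("input",
              "replicates mix kinases (%s) or libraries (%s)",
              paste(kin, collapse = ","), paste(lib, collapse = ","))
  }
  if (length(motifs) < 2L) {
    warning("averaging a single replicate; the screen design calls for n >= 2",
            call. = FALSE)
  }
  stack <- simplify2array(lapply(motifs, function(m) m$values))
  values <- apply(stack, c(1L, 2L), function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  dimnames(values) <- dimnames(motifs[[1L]]$values)
  acc <- NULL
  accs <- lapply(motifs, `[[`, "acceptor")
  accs <- accs[!vapply(accs, is.null, TRUE)]
  if (length(accs) > 0L) {
    pools <- Reduce(union, lapply(accs, names))
    acc <- vapply(pools, function(p) {
      mean(vapply(accs, function(a) a[[p]] %||% NA_real_, 0), na.rm = TRUE)
    }, 0)
  }
  motif_matrix(kin, values, stage = "averaged", library = lib,
               acceptor = acc, n_replicates = length(motifs))
}

#' Cap acceptor-like fixed residues at 1
#'
#' Peptide pools whose fixed flank residue is itself a phospho-acceptor
#' (Ser or Thr in the ST library; Tyr in the Y library) contain a second
#' acceptor site, so high intensities there need not reflect a true flank
#' preference. Normalized values above 1 at those cells are truncated to 1.
#' Cells listed in `exceptions` are left untouched — used when an
#' above-one value is judged to reflect a genuine preference (e.g. a +1
#' tyrosine for a kinase that strongly favors aromatics there).
#'
#' @param motif A [motif_matrix()] at stage `averaged`.
#' @param exceptions Data frame with columns `position` (signed integer)
#'   and `residue`, or `NULL`.
#' @return A [motif_matrix()] at stage `capped`; `$capped_cells` records
#'   every modified cell with its original value.
#' @export
cap_acceptor_like_residues <- function(motif, exceptions = NULL) {
  require_stage(motif, "averaged", "cap_acceptor_like_residues")
  cap_res <- if (motif$library == "ST") c("S", "T") else "Y"
  values <- motif$values
  keep <- matrix(FALSE, nrow(values), ncol(values),
                 dimnames = dimnames(values))
  if (!is.null(exceptions) && nrow(as.data.frame(exceptions)) > 0L) {
    exceptions <- as.data.frame(exceptions)
    for (i in seq_len(nrow(exceptions))) {
      pos <- sprintf("%+d", as.integer(exceptions$position[i]))
      res <- as.character(exceptions$residue[i])
      if (!(res %in% cap_res) || !(pos %in% rownames(values))) {
        warning(sprintf("exception (%s, %s) names a non-cappable cell; ignored",
                        pos, res), call. = FALSE)
        next
      }
      keep[pos, res] <- TRUE
    }
  }
  cappable <- matrix(FALSE, nrow(values), ncol(values),
                     dimnames = dimnames(values))
  cappable[, cap_res] <- TRUE
  hit <- cappable & !keep & !is.na(values) & values > 1
  record <- data.frame(
    position = rep(rownames(values), times = ncol(values))[as.vector(hit)],
    residue = rep(colnames(values), each = nrow(values))[as.vector(hit)],
    original = values[hit],
    stringsAsFactors = FALSE
  )
  values[hit] <- 1
  motif_matrix(motif$kinase_id, values, stage = "capped",
               library = motif$library, acceptor = motif$acceptor,
               n_replicates = motif$n_replicates, capped_cells = record)
}

#' Log2-transform a capped motif with a positive floor
#'
#' Values below `floor` (including true zeros from blank spots) are raised
#' to `floor` before taking log2, so disfavored residues get a finite
#' negative value. With the default floor of 2^-6 a blank spot maps to -6.
#'
#' @param motif A [motif_matrix()] at stage `capped`.
#' @param floor Positive real, default `2^-6`.
#' @return A [motif_matrix()] at stage `log2` with `$floor` recorded.
#' @export
log_transform <- function(motif, floor = 2^-6) {
  require_stage(motif, "capped", "log_transform")
  assert_scalar_number(floor, "floor", positive = TRUE)
  values <- log2(pmax(motif$values, floor))
  motif_matrix(motif$kinase_id, values, stage = "log2",
               library = motif$library, acceptor = motif$acceptor,
               n_replicates = motif$n_replicates, floor = floor,
               capped_cells = motif$capped_cells)
}

#' Phospho-acceptor preference from the degenerate acceptor pools
#'
#' The three fully degenerate libraries fix only the central residue
#' (S, T or Y). Their intensities report which acceptor the kinase
#' prefers. Mirroring the flank normalization, each pool is divided by the
#' mean of the pools present; raw fractions (summing to 1) are reported
#' alongside.
#'
#' @param x A [spot_grid()] or [motif_matrix()] carrying acceptor pools.
#' @return A list with `normalized` (mean-1 scale) and `fraction`
#'   (sums to 1), both named by acceptor residue.
#' @export
acceptor_preference <- function(x) {
  pools <- x$acceptor
  if (is.null(pools) || length(pools) < 2L) {
    stop_opls("input", "need at least 2 acceptor pools to compute preference")
  }
  pools <- pools[!is.na(pools)]
  if (length(pools) < 2L || sum(pools) <= 0) {
    stop_opls("degenerate", "acceptor pools are all zero or missing")
  }
  list(normalized = pools / mean(pools), fraction = pools / sum(pools))
}

#' Run the full motif pipeline: normalize, average, cap, log2
#'
#' Applies the four processing stages in their fixed order: each replicate
#' grid is normalized per position, the normalized replicates are averaged,
#' acceptor-like fixed residues are capped at 1, and the capped matrix is
#' log2-transformed. The order matters: averaging precedes capping, so a
#' cell with replicate values 1.4 and 0.8 averages to 1.1 and is then
#' capped to 1.0 (capping first would give 0.9).
#'
#' Both the capped (linear) and log2 matrices are returned because
#' downstream uses differ: motif clustering and PSSM scoring use the
#' linear capped values, sequence-logo heights use the log2 values.
#'
#' @param grids List of [spot_grid()] replicates for one kinase.
#' @param cap_exceptions Passed to [cap_acceptor_like_residues()].
#' @param floor Passed to [log_transform()].
#' @return List with elements `capped`, `log2` (both [motif_matrix()]) and
#'   `acceptor_pref` (from [acceptor_preference()], or `NULL` if the grids
#'   carry fewer than two acceptor pools).
#' @export
run_motif_pipeline <- function(grids, cap_exceptions = NULL, floor = 2^-6) {
  if (!is.list(grids) || length(grids) == 0L) {
    stop_opls("input", "run_motif_pipeline expects a nonempty list of grids")
  }
  normalized <- lapply(grids, normalize_spot_grid)
  averaged <- average_replicates(normalized)
  capped <- cap_acceptor_like_residues(averaged, exceptions = cap_exceptions)
  logged <- log_transform(capped, floor = floor)
  apref <- NULL
  if (!is.null(averaged$acceptor) && length(averaged$acceptor) >= 2L) {
    apref <- acceptor_preference(averaged)
  }
  list(capped = capped, log2 = logged, acceptor_pref = apref)
}
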