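#' Construct a MotifMatrix: a processed OPLS motif at a named pipeline stage
#'
#' A `MotifMatrix` carries the same 9 x 22 index set as a [spot_grid()] but
#' in processed space. The `stage` field records how far along the pipeline
#' the values are:
#'
#' * `normalized` — one replicate, each position divided by its mean over
#'   the 22 residues (position means are exactly 1);
#' * `averaged` — element-wise mean of the normalized replicates;
#' * `capped` — acceptor-like fixed residues (S/T in the ST library, Y in
#'   the Y library) truncated at 1, because those spots contain a second
#'   acceptor site and overreport preference;
#' * `log2` — log2 of the capped values with a positive floor.
#'
#' @param kinase_id,library As in [spot_grid()].
#' @param stage One of `"normalized"`, `"averaged"`, `"capped"`, `"log2"`.
#' @param values Numeric 9 x 22 matrix in canonical dimnames.
#' @param acceptor Optional named numeric vector (subset of S/T/Y): acceptor
#'   pool values normalized by the mean of the pools present.
#' @param n_replicates Number of replicates averaged into `values`.
#' @param floor Positive floor applied before log2 (stage `log2` only).
#' @param capped_cells Data frame recording cells modified by capping.
#' @return An object of class `MotifMatrix`.
#' @export
motif_matrix <- function(kinase_id, values,
                         stage = c("normalized", "averaged", "capped", "log2"),
                         library = c("ST", "Y"), acceptor = NULL,
                         n_replicates = 1L, floor = NULL,
                         capped_cells = NULL) {
  stage <- match.arg(stage)
  library <- match.arg(library)
  check_flank_matrix(values, "MotifMatrix `values`")
  if (stage != "log2" && any(values < 0, na.rm = TRUE)) {
    stop_opls("input", "stage `%s` values must be nonnegative", stage)
  }
  if (stage == "normalized") {
    mu <- rowMeans(values, na.rm = TRUE)
    if (any(abs(mu - 1) > 1e-9)) {
      stop_opls("input", "normalized stage requires position means of 1")
    }
  }
  structure(
    list(kinase_id = as.character(kinase_id), library = library,
         stage = stage, values = values, acceptor = acceptor,
         n_replicates = as.integer(n_replicates), floor = floor,
         capped_cells = capped_cells),
    class = "MotifMatrix"
  )
}

#' @export
print.MotifMatrix <- function(x, ...) {
  cat(sprintf("MotifMatrix: kinase %s, %s library, stage %s (n = %d)\n",
              x$kinase_id, x$library, x$stage, x$n_replicates))
  if (!is.null(x$floor)) cat(sprintf("  log2 floor: %g\n", x$floor))
  if (!is.null(x$capped_cells) && nrow(x$capped_cells) > 0) {
    cat(sprintf("  %d cells capped at 1\n", nrow(x$capped_cells)))
  }
  if (!is.null(x$acceptor)) {
    cat("  acceptor (normalized):",
        paste(sprintf("%s=%.4g", names(x$acceptor), x$acceptor),
              collapse = ", "), "\n")
  }
  top <- apply(x$values, 1L, function(r) colnames(x$values)[which.max(r)])
  cat("  favored residue by position:",
      paste(sprintf("%s:%s", rownames(x$values), top), collapse = " "), "\n")
  invisible(x)
}

stage_rank <- function(stage) {
  match(stage, c("normalized", "averaged", "capped", "log2"))
}

require_stage <- function(motif, stage, op) {
  if (!inherits(motif, "MotifMatrix")) {
    stop_opls("input", "%s expects a MotifMatrix", op)
  }
  if (!identical(motif$stage, stage)) {
    stop_opls("stage", "%s expects stage `%s`, got `%s`", op, stage,
              motif$stage)
  }
  invisible(motif)
}
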