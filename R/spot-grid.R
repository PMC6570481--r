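#' Construct a SpotGrid: one replicate's raw OPLS spot intensities
#'
#' A `SpotGrid` holds the raw (un-normalized) intensities of a single
#' oriented-peptide-library blot for one kinase: a 9 x 22 flank grid
#' (positions -5..-1, +1..+4 by the 22 fixed residues) and, optionally, the
#' three fully degenerate acceptor pools (fixed S, T or Y at position 0).
#'
#' @param kinase_id Character scalar naming the kinase.
#' @param flank Numeric 9 x 22 matrix; rows named `-5`..`+4` (as by
#'   [position_labels()] internally, i.e. `"-5"`, ..., `"+4"`), columns the
#'   residues in [OPLS_RESIDUES] order. `NA` marks missing (failed) spots.
#' @param acceptor Optional named numeric vector with some or all of
#'   `S`, `T`, `Y`: intensities of the degenerate acceptor pools.
#' @param library `"ST"` or `"Y"`; decides which fixed residues present a
#'   second acceptor site and so are capped downstream.
#' @param replicate_id Character scalar identifying the blot/replicate.
#' @return An object of class `SpotGrid`.
#' @seealso [normalize_spot_grid()], [simulate_spot_grids()]
#' @export
spot_grid <- function(kinase_id, flank, acceptor = NULL,
                      library = c("ST", "Y"), replicate_id = "rep1") {
  library <- match.arg(library)
  check_flank_matrix(flank, "SpotGrid `flank`")
  if (any(flank < 0, na.rm = TRUE)) {
    stop_opls("input", "spot intensities must be nonnegative")
  }
  if (!is.null(acceptor)) {
    if (is.null(names(acceptor)) || !all(names(acceptor) %in% OPLS_ACCEPTORS)) {
      stop_opls("input", "`acceptor` must be named with a subset of S, T, Y")
    }
    if (any(acceptor < 0, na.rm = TRUE)) {
      stop_opls("input", "acceptor pool intensities must be nonnegative")
    }
    acceptor <- acceptor[intersect(OPLS_ACCEPTORS, names(acceptor))]
  }
  structure(
    list(kinase_id = as.character(kinase_id), library = library,
         replicate_id = as.character(replicate_id),
         flank = flank, acceptor = acceptor),
    class = "SpotGrid"
  )
}

#' @export
print.SpotGrid <- function(x, ...) {
  cat(sprintf("SpotGrid: kinase %s, %s library, replicate %s\n",
              x$kinase_id, x$library, x$replicate_id))
  cat(sprintf("  flank grid: %d x %d (%d missing spots)\n",
              nrow(x$flank), ncol(x$flank), sum(is.na(x$flank))))
  if (!is.null(x$acceptor)) {
    cat("  acceptor pools:",
        paste(sprintf("%s=%.4g", names(x$acceptor), x$acceptor),
              collapse = ", "), "\n")
  }
  invisible(x)
}
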