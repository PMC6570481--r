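#' Residue at a fixed offset from a conserved kinase-domain anchor
#'
#' Eukaryotic protein-kinase domains carry three near-invariant anchors:
#' the catalytic-loop HRD motif, the activation-segment DFG motif and the
#' APE motif closing the activation segment. Residues at fixed offsets
#' from these anchors (e.g. HRD+2, DFG+1, APE-4) sit in the substrate
#' pocket and track phospho-acceptor specificity across the kinome.
#'
#' Offset convention: negative offsets count left from the FIRST residue
#' of the anchor (APE-4 is 4 residues N-terminal of the A), positive
#' offsets count right from the LAST residue (HRD+2 is 2 residues
#' C-terminal of the D; DFG+1 is 1 past the G).
#'
#' @param sequence Unaligned amino-acid string (one kinase domain).
#' @param anchor `"HRD"`, `"APE"` or `"DFG"`.
#' @param offset Signed integer offset (nonzero).
#' @param kinase_id Label carried to the report.
#' @param search_window Optional integer pair `(from, to)` of 1-based
#'   sequence coordinates; required to disambiguate when the anchor occurs
#'   more than once.
#' @return Object of class `AnchorResidueReport`: list with `kinase_id`,
#'   `anchor`, `offset`, `residue`, `anchor_start`.
#' @examples
#' anchor_offset_residue("AAAHRDLKAAA", "HRD", 2L)$residue  # "K"
#' @export
anchor_offset_residue <- function(sequence, anchor = c("HRD", "APE", "DFG"),
                                  offset, kinase_id = "kinase",
                                  search_window = NULL) {
  anchor <- match.arg(anchor)
  offset <- as.integer(offset)
  if (length(offset) != 1L || is.na(offset) || offset == 0L) {
    stop_opls("parameter", "offset must be a single nonzero integer")
  }
  seq <- toupper(as.character(sequence))
  hits <- gregexpr(anchor, seq, fixed = TRUE)[[1L]]
  hits <- hits[hits > 0]
  if (length(hits) == 0L) {
    stop_opls("not_found", "anchor %s not found in %s", anchor, kinase_id)
  }
  if (!is.null(search_window)) {
    hits <- hits[hits >= search_window[1] & hits <= search_window[2]]
    if (length(hits) == 0L) {
      stop_opls("not_found", "anchor %s not found in search window of %s",
                anchor, kinase_id)
    }
  }
  if (length(hits) > 1L) {
    stop_opls("ambiguity",
              "anchor %s occurs %d times in %s (at %s); pass search_window",
              anchor, length(hits), kinase_id,
              paste(hits, collapse = ", "))
  }
  start <- hits[[1L]]
  idx <- if (offset < 0L) start + offset else start + nchar(anchor) - 1L + offset
  if (idx < 1L || idx > nchar(seq)) {
    stop_opls("range", "%s%+d falls outside the sequence of %s",
              anchor, offset, kinase_id)
  }
  structure(
    list(kinase_id = kinase_id, anchor = anchor, offset = offset,
         residue = substr(seq, idx, idx), anchor_start = start),
    class = "AnchorResidueReport"
  )
}

#' @export
print.AnchorResidueReport <- function(x, ...) {
  cat(sprintf("%s: %s%+d = %s (anchor at %d)\n", x$kinase_id, x$anchor,
              x$offset, x$residue, x$anchor_start))
  invisible(x)
}

#' Residue frequencies over a set of anchor-offset reports
#'
#' Summarizes, across a kinase set, which residues occupy a given
#' anchor-relative position (e.g. the fraction of Ser/Thr kinases with a
#' lysine at HRD+2).
#'
#' @param reports List of [anchor_offset_residue()] reports.
#' @return Named numeric vector of fractions over observed residues,
#'   summing to 1, sorted decreasing.
#' @export
anchor_frequency <- function(reports) {
  if (length(reports) == 0L) {
    stop_opls("input", "anchor_frequency needs at least one report")
  }
  res <- vapply(reports, function(r) {
    if (!inherits(r, "AnchorResidueReport")) {
      stop_opls("input", "reports must be AnchorResidueReport objects")
    }
    r$residue
  }, "")
  tab <- table(res)
  sort(setNames(as.numeric(tab) / length(res), names(tab)),
       decreasing = TRUE)
}
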