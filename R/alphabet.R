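#' Residue and position alphabets of the oriented peptide library
#'
#' The serine/threonine (ST) library fixes one residue per peptide pool at
#' one of nine flank positions (-5..-1, +1..+4 relative to the central
#' phospho-acceptor). The fixed residue is one of the 20 natural amino acids
#' or phospho-threonine (`pT`) or phospho-tyrosine (`pY`), giving a
#' 9 x 22 grid of 198 pools, plus three fully degenerate pools that fix only
#' the acceptor (Ser, Thr or Tyr) for phospho-acceptor preference.
#'
#' @format Character/integer vectors:
#' * `OPLS_AA20`: the 20 natural amino acids, alphabetical one-letter codes.
#' * `OPLS_RESIDUES`: the 22 fixed residues (`OPLS_AA20` plus `pT`, `pY`).
#' * `OPLS_POSITIONS`: flank positions as signed integers, no 0.
#' * `OPLS_ACCEPTORS`: the three acceptor residues `S`, `T`, `Y`.
#' @name opls-alphabet
NULL

#' @rdname opls-alphabet
#' @export
OPLS_AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
               "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' @rdname opls-alphabet
#' @export
OPLS_RESIDUES <- c(OPLS_AA20, "pT", "pY")

#' @rdname opls-alphabet
#' @export
OPLS_POSITIONS <- c(-5L, -4L, -3L, -2L, -1L, 1L, 2L, 3L, 4L)

#' @rdname opls-alphabet
#' @export
OPLS_ACCEPTORS <- c("S", "T", "Y")

#' Padding character marking window positions beyond a protein terminus
#' @rdname opls-alphabet
#' @export
OPLS_PAD <- "_"

position_labels <- function(positions = OPLS_POSITIONS) {
  sprintf("%+d", positions)
}

#' Enumerate the peptide-pool design of an oriented peptide library
#'
#' Lists every peptide pool in the library: one pool per
#' (flank position, fixed residue) combination, plus the fully degenerate
#' acceptor pools that fix only the central Ser, Thr or Tyr.
#'
#' @param library `"ST"` (central equimolar Ser/Thr acceptor) or `"Y"`
#'   (central Tyr acceptor).
#' @return A data frame with columns `pool_type` (`"flank"` or
#'   `"acceptor"`), `position` (signed integer, `NA` for acceptor pools) and
#'   `residue`. The ST design has 198 flank pools and 3 acceptor pools.
#' @examples
#' design <- opls_library_design("ST")
#' table(design$pool_type)
#' @export
opls_library_design <- function(library = c("ST", "Y")) {
  library <- match.arg(library)
  flank <- expand.grid(position = OPLS_POSITIONS, residue = OPLS_RESIDUES,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  flank <- flank[order(flank$position, match(flank$residue, OPLS_RESIDUES)), ]
  out <- rbind(
    data.frame(pool_type = "flank", position = flank$position,
               residue = flank$residue, stringsAsFactors = FALSE),
    data.frame(pool_type = "acceptor", position = NA_integer_,
               residue = OPLS_ACCEPTORS, stringsAsFactors = FALSE)
  )
  rownames(out) <- NULL
  attr(out, "library") <- library
  out
}
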