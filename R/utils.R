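# internal helpers shared across modules

stop_opls <- function(category, fmt, ...) {
  msg <- sprintf(fmt, ...)
  cond <- structure(
    class = c(paste0("opls_", category, "_error"), "opls_error",
              "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_scalar_number <- function(x, name, positive = FALSE,
                                 nonnegative = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_opls("parameter", "`%s` must be a single finite number", name)
  }
  if (positive && x <= 0) {
    stop_opls("parameter", "`%s` must be > 0 (got %g)", name, x)
  }
  if (nonnegative && x < 0) {
    stop_opls("parameter", "`%s` must be >= 0 (got %g)", name, x)
  }
  invisible(x)
}

# empty 9 x 22 flank matrix with canonical dimnames
empty_flank_matrix <- function(fill = NA_real_) {
  matrix(fill, nrow = length(OPLS_POSITIONS), ncol = length(OPLS_RESIDUES),
         dimnames = list(position_labels(), OPLS_RESIDUES))
}

check_flank_matrix <- function(values, what = "flank grid") {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_opls("input", "%s must be a numeric matrix", what)
  }
  if (!identical(rownames(values), position_labels()) ||
      !identical(colnames(values), OPLS_RESIDUES)) {
    stop_opls("input",
              "%s must have rows %s and columns the 22 library residues",
              what, paste(position_labels(), collapse = ","))
  }
  invisible(values)
}

format_cells <- function(positions, residues) {
  paste0("(", positions, ",", residues, ")", collapse = ", ")
}
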