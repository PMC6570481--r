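# TSV dialect shared by spot grids, motif matrices and scoring matrices:
#   '# key=value' metadata lines, a header 'position<TAB>residue...',
#   one row per flank position (-5..-1,+1..+4), then an optional acceptor
#   block of 2-field lines keyed S/T/Y. Values are written with 6
#   significant digits; write-read-write is byte-identical.

fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.6g", x))
}

write_grid_tsv <- function(path, meta, values, acceptor = NULL,
                           row_label = "position") {
  lines <- c(
    sprintf("# %s=%s", names(meta), unlist(meta)),
    paste(c(row_label, colnames(values)), collapse = "\t")
  )
  for (i in seq_len(nrow(values))) {
    lines <- c(lines, paste(c(rownames(values)[i], fmt_num(values[i, ])),
                            collapse = "\t"))
  }
  if (!is.null(acceptor)) {
    lines <- c(lines, paste(names(acceptor), fmt_num(acceptor), sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

parse_grid_tsv <- function(path) {
  lines <- readLines(path)
  meta <- list()
  i <- 1L
  while (i <= length(lines) && startsWith(lines[i], "#")) {
    kv <- sub("^#\\s*", "", lines[i])
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) {
      meta[[substr(kv, 1L, eq - 1L)]] <- substr(kv, eq + 1L, nchar(kv))
    }
    i <- i + 1L
  }
  if (i > length(lines)) {
    stop_opls("parse", "%s: no header line found", path)
  }
  header <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
  residues <- header[-1L]
  values <- NULL
  acceptor <- c()
  row_names <- c()
  for (j in seq.int(i + 1L, length.out = length(lines) - i)) {
    if (!nzchar(lines[j])) next
    fields <- strsplit(lines[j], "\t", fixed = TRUE)[[1L]]
    if (fields[1L] %in% OPLS_ACCEPTORS && length(fields) == 2L) {
      acceptor[fields[1L]] <- as.numeric(fields[2L])
      next
    }
    if (length(fields) != length(header)) {
      stop_opls("parse", "%s line %d: expected %d fields, found %d",
                path, j, length(header), length(fields))
    }
    vals <- suppressWarnings(as.numeric(fields[-1L]))
    if (any(is.na(vals) & fields[-1L] != "NA")) {
      stop_opls("parse", "%s line %d: non-numeric value", path, j)
    }
    row_names <- c(row_names, fields[1L])
    values <- rbind(values, vals)
  }
  if (is.null(values)) stop_opls("parse", "%s: no data rows", path)
  dimnames(values) <- list(row_names, residues)
  list(meta = meta, values = values,
       acceptor = if (length(acceptor)) acceptor else NULL)
}

#' Read and write spot-grid TSV files
#'
#' One file per replicate blot: `#` metadata lines (`kinase`, `library`,
#' `replicate`), a header of residue codes, one row per flank position
#' and an optional acceptor block of `S`/`T`/`Y` lines.
#'
#' @param grid A [spot_grid()].
#' @param path File path.
#' @return `write_spot_grid()` returns `path` invisibly;
#'   `read_spot_grid()` returns a [spot_grid()].
#' @export
write_spot_grid <- function(grid, path) {
  if (!inherits(grid, "SpotGrid")) {
    stop_opls("input", "write_spot_grid expects a SpotGrid")
  }
  write_grid_tsv(path,
                 list(kinase = grid$kinase_id, library = grid$library,
                      replicate = grid$replicate_id),
                 grid$flank, grid$acceptor)
}

#' @rdname write_spot_grid
#' @export
read_spot_grid <- function(path) {
  p <- parse_grid_tsv(path)
  check_flank_matrix(p$values, sprintf("%s grid", path))
  spot_grid(p$meta$kinase %||% "unknown", p$values,
            acceptor = p$acceptor,
            library = p$meta$library %||% "ST",
            replicate_id = p$meta$replicate %||% "rep1")
}

#' Read and write motif-matrix TSV files
#'
#' Same layout as the spot-grid TSV plus `stage`, `n_replicates` and
#' (for log2 matrices) `floor` metadata.
#'
#' @param motif A [motif_matrix()].
#' @param path File path.
#' @return `write_motif_matrix()` returns `path` invisibly;
#'   `read_motif_matrix()` returns a [motif_matrix()].
#' @export
write_motif_matrix <- function(motif, path) {
  if (!inherits(motif, "MotifMatrix")) {
    stop_opls("input", "write_motif_matrix expects a MotifMatrix")
  }
  meta <- list(kinase = motif$kinase_id, library = motif$library,
               stage = motif$stage, n_replicates = motif$n_replicates)
  if (!is.null(motif$floor)) meta$floor <- fmt_num(motif$floor)
  write_grid_tsv(path, meta, motif$values, motif$acceptor)
}

#' @rdname write_motif_matrix
#' @export
read_motif_matrix <- function(path) {
  p <- parse_grid_tsv(path)
  check_flank_matrix(p$values, sprintf("%s matrix", path))
  motif_matrix(p$meta$kinase %||% "unknown", p$values,
               stage = p$meta$stage %||% "normalized",
               library = p$meta$library %||% "ST",
               acceptor = p$acceptor,
               n_replicates = as.integer(p$meta$n_replicates %||% "1"),
               floor = if (!is.null(p$meta$floor))
                 as.numeric(p$meta$floor) else NULL)
}

#' Read and write scoring-matrix TSV files
#'
#' The 9 x 20 standard-residue entries and the pT/pY modified-residue
#' columns are written side by side; `acceptor_set` and `floor` travel as
#' metadata.
#'
#' @param matrix A [build_scoring_matrix()] result.
#' @param path File path.
#' @return `write_scoring_matrix()` returns `path` invisibly;
#'   `read_scoring_matrix()` returns a `ScoringMatrix`.
#' @export
write_scoring_matrix <- function(matrix, path) {
  if (!inherits(matrix, "ScoringMatrix")) {
    stop_opls("input", "write_scoring_matrix expects a ScoringMatrix")
  }
  write_grid_tsv(path,
                 list(kinase = matrix$kinase_id,
                      acceptor_set = paste(matrix$acceptor_set,
                                           collapse = ","),
                      floor = fmt_num(matrix$floor),
                      n_replicates = matrix$n_replicates),
                 cbind(matrix$entries, matrix$mod_entries))
}

#' @rdname write_scoring_matrix
#' @export
read_scoring_matrix <- function(path) {
  p <- parse_grid_tsv(path)
  vals <- p$values
  need <- c(OPLS_AA20, "pT", "pY")
  if (!identical(colnames(vals), need)) {
    stop_opls("parse", "%s: scoring matrix must have columns %s",
              path, paste(need, collapse = ","))
  }
  structure(
    list(kinase_id = p$meta$kinase %||% "unknown",
         entries = vals[, OPLS_AA20, drop = FALSE],
         mod_entries = vals[, c("pT", "pY"), drop = FALSE],
         acceptor_set = strsplit(p$meta$acceptor_set %||% "S,T",
                                 ",", fixed = TRUE)[[1L]],
         floor = as.numeric(p$meta$floor %||% fmt_num(2^-6)),
         n_replicates = as.integer(p$meta$n_replicates %||% "1")),
    class = "ScoringMatrix"
  )
}
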