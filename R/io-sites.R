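#' Read and write candidate phosphosites as TSV
#'
#' Tab-separated with header `protein_id`, `position`, `acceptor`,
#' `window` (9-character flank window, `_` padding at termini); extra
#' columns such as `group` or `class` are preserved.
#'
#' @param sites Candidate-site data frame.
#' @param path File path.
#' @return `write_sites_tsv()` returns `path` invisibly;
#'   `read_sites_tsv()` returns the data frame.
#' @export
write_sites_tsv <- function(sites, path) {
  write.table(as.data.frame(sites), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_sites_tsv
#' @export
read_sites_tsv <- function(path) {
  sites <- read.delim(path, stringsAsFactors = FALSE,
                      colClasses = c(window = "character"))
  need <- c("protein_id", "position", "acceptor", "window")
  missing_cols <- setdiff(need, names(sites))
  if (length(missing_cols) > 0L) {
    stop_opls("parse", "%s: missing column(s) %s", path,
              paste(missing_cols, collapse = ", "))
  }
  bad <- which(nchar(sites$window) != 9L)
  if (length(bad) > 0L) {
    stop_opls("parse", "%s row %d: window must be 9 characters",
              path, bad[1L])
  }
  class(sites) <- c("candidate_sites", "data.frame")
  sites
}

#' Read and write candidate phosphosites as FASTA 10-mers
#'
#' Each record is the 10-residue site sequence (-5..+4 including the
#' central acceptor at the sixth character) with a structured header
#' `>protein_id|position|acceptor`.
#'
#' @param sites Candidate-site data frame.
#' @param path File path.
#' @return `write_sites_fasta()` returns `path` invisibly;
#'   `read_sites_fasta()` returns a candidate-site data frame.
#' @export
write_sites_fasta <- function(sites, path) {
  sites <- as.data.frame(sites)
  tenmer <- paste0(substr(sites$window, 1L, 5L), sites$acceptor,
                   substr(sites$window, 6L, 9L))
  lines <- as.vector(rbind(
    sprintf(">%s|%s|%s", sites$protein_id, sites$position, sites$acceptor),
    tenmer))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_sites_fasta
#' @export
read_sites_fasta <- function(path) {
  recs <- Biostrings::readBStringSet(path)
  headers <- names(recs)
  seqs <- as.character(recs)
  parts <- strsplit(headers, "|", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad) > 0L) {
    stop_opls("parse",
              "%s record %d: header must be protein|position|acceptor",
              path, bad[1L])
  }
  bad <- which(nchar(seqs) != 10L)
  if (length(bad) > 0L) {
    stop_opls("parse", "%s record %d: sequence must be a 10-mer",
              path, bad[1L])
  }
  acceptor_hdr <- vapply(parts, `[[`, "", 3L)
  acceptor_seq <- substr(seqs, 6L, 6L)
  if (any(acceptor_hdr != acceptor_seq)) {
    k <- which(acceptor_hdr != acceptor_seq)[1L]
    stop_opls("parse",
              "%s record %d: header acceptor %s disagrees with sequence %s",
              path, k, acceptor_hdr[k], acceptor_seq[k])
  }
  sites <- data.frame(
    protein_id = vapply(parts, `[[`, "", 1L),
    position = as.integer(vapply(parts, `[[`, "", 2L)),
    acceptor = acceptor_hdr,
    window = paste0(substr(seqs, 1L, 5L), substr(seqs, 7L, 10L)),
    stringsAsFactors = FALSE)
  class(sites) <- c("candidate_sites", "data.frame")
  sites
}

#' Read a PhosphoSitePlus-style flat site dump
#'
#' Compatible reader for tab-delimited phosphosite dumps carrying a
#' `MOD_RSD` column (e.g. `S25-p`) and a `SITE_+/-7_AA` column (15-mer
#' centered on the site, `_` padding). The +/-7 window is trimmed to the
#' -5..+4 window used here. Lines before the header row (dump preambles)
#' are skipped automatically.
#'
#' @param path File path.
#' @param protein_col Column to use as protein id (default `ACC_ID`).
#' @return A candidate-site data frame.
#' @export
read_psp_sites <- function(path, protein_col = "ACC_ID") {
  lines <- readLines(path)
  hdr <- grep("SITE_\\+/-7_AA", lines)[1L]
  if (is.na(hdr)) {
    stop_opls("parse", "%s: no SITE_+/-7_AA column found", path)
  }
  tab <- read.delim(text = paste(lines[hdr:length(lines)], collapse = "\n"),
                    stringsAsFactors = FALSE, check.names = FALSE)
  if (!(protein_col %in% names(tab)) || !("MOD_RSD" %in% names(tab))) {
    stop_opls("parse", "%s: need columns %s and MOD_RSD", path, protein_col)
  }
  mod <- tab$MOD_RSD
  acceptor <- substr(mod, 1L, 1L)
  position <- as.integer(sub("^[A-Z]([0-9]+).*$", "\\1", mod))
  win15 <- toupper(tab[["SITE_+/-7_AA"]])
  keep <- acceptor %in% OPLS_ACCEPTORS & !is.na(position) &
    nchar(win15) == 15L
  sites <- data.frame(
    protein_id = tab[[protein_col]][keep],
    position = position[keep],
    acceptor = acceptor[keep],
    window = paste0(substr(win15[keep], 3L, 7L),
                    substr(win15[keep], 9L, 12L)),
    stringsAsFactors = FALSE)
  class(sites) <- c("candidate_sites", "data.frame")
  sites
}

#' Read an aligned (or plain) FASTA of kinase-domain sequences
#'
#' @param path FASTA file; gaps as `-` for alignments.
#' @return Named character vector of sequences.
#' @export
read_fasta_sequences <- function(path) {
  recs <- Biostrings::readBStringSet(path)
  setNames(as.character(recs), sub("\\s.*$", "", names(recs)))
}

#' Read and write assay time courses as CSV
#'
#' Columns `label`, `replicate`, `time_min`, `cpm`; one row per measured
#' timepoint.
#'
#' @param tc Time-course data frame.
#' @param path File path.
#' @return `write_timecourse_csv()` returns `path` invisibly;
#'   `read_timecourse_csv()` returns the data frame.
#' @export
write_timecourse_csv <- function(tc, path) {
  utils::write.csv(as.data.frame(tc), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_timecourse_csv
#' @export
read_timecourse_csv <- function(path) {
  tc <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "replicate", "time_min", "cpm")
  missing_cols <- setdiff(need, names(tc))
  if (length(missing_cols) > 0L) {
    stop_opls("parse", "%s: missing column(s) %s", path,
              paste(missing_cols, collapse = ", "))
  }
  class(tc) <- c("time_course", "data.frame")
  tc
}

#' Export a kinase dendrogram as Newick
#'
#' Writes the ultrametric tree (branch lengths in one-minus-Pearson
#' distance units, node depths equal to half the merge height as usual
#' for UPGMA trees) to a Newick file.
#'
#' @param dendro A [cluster_kinases()] result.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(dendro, path) {
  if (!inherits(dendro, "KinaseDendrogram")) {
    stop_opls("input", "write_dendrogram_newick expects a KinaseDendrogram")
  }
  ape::write.tree(dendro$phylo, file = path)
  invisible(path)
}

#' Write a similarity matrix as TSV
#'
#' @param sim A `SimilarityMatrix`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_similarity_tsv <- function(sim, path) {
  if (!inherits(sim, "SimilarityMatrix")) {
    stop_opls("input", "write_similarity_tsv expects a SimilarityMatrix")
  }
  write_grid_tsv(path, list(metric = sim$metric_tag),
                 structure(sim$values,
                           dimnames = list(sim$ids, sim$ids)),
                 row_label = "id")
  invisible(path)
}

#' Write an overlap analysis as JSON
#'
#' @param overlap An [overlap_analysis()] result.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_overlap_json <- function(overlap, path) {
  jsonlite::write_json(
    list(counts = as.list(overlap$counts),
         n_union = overlap$n_union,
         reference = overlap$reference,
         reference_shared_fraction = overlap$reference_shared_fraction),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
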