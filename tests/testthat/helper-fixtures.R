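# shared fixture builders; everything is generated in code, nothing binary

# raw grid with a prescribed normalized profile per position:
# each row is profile * row_scale so normalize() recovers profile exactly
toy_grid <- function(kinase_id = "TOY", row_scales = rep(1, 9),
                     profile = NULL, acceptor = NULL, library = "ST",
                     replicate_id = "rep1") {
  if (is.null(profile)) profile <- matrix(1, 9, 22)
  flank <- profile * row_scales
  dimnames(flank) <- list(sprintf("%+d", OPLS_POSITIONS), OPLS_RESIDUES)
  spot_grid(kinase_id, flank, acceptor = acceptor, library = library,
            replicate_id = replicate_id)
}

# random raw grid (positive lognormal intensities)
random_grid <- function(seed, kinase_id = "RND", library = "ST") {
  withr::with_seed(seed, {
    flank <- matrix(exp(rnorm(198, 0, 1)), 9, 22)
  })
  dimnames(flank) <- list(sprintf("%+d", OPLS_POSITIONS), OPLS_RESIDUES)
  spot_grid(kinase_id, flank, library = library)
}

# a capped MotifMatrix built directly from a value matrix
as_capped <- function(values, kinase_id = "TOY", library = "ST",
                      acceptor = NULL, n_replicates = 2L) {
  dimnames(values) <- list(sprintf("%+d", OPLS_POSITIONS), OPLS_RESIDUES)
  motif_matrix(kinase_id, values, stage = "capped", library = library,
               acceptor = acceptor, n_replicates = n_replicates)
}

# independent textbook Pearson correlation (sum formulas)
pearson_oracle <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
}

# independent brute-force window scorer against a ScoringMatrix
brute_score <- function(matrix, window) {
  chars <- strsplit(window, "")[[1L]]
  devs <- c()
  for (i in 1:9) {
    ch <- chars[i]
    if (ch == "_") next
    col <- matrix$entries[i, ]
    devs <- c(devs, log2(max(col)) - log2(col[[ch]]))
  }
  mean(devs)
}

# noisy replicate grids + full pipeline for one true motif
recover_motif <- function(truth, sigma = 0.1, n_rep = 3, seed = 1) {
  grids <- simulate_spot_grids(truth, noise_model(sigma_log = sigma),
                               n_replicates = n_rep, seed = seed)
  run_motif_pipeline(grids)
}
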