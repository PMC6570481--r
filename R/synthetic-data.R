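#' Ground-truth kinase motif for simulation
#'
#' Builds a known positional preference profile in normalized space (every
#' position's mean over the 22 fixed residues is exactly 1). A chosen number
#' of positions are "selective": one favored residue gets
#' `preference_strength` times the weight of every other residue before
#' normalization, so after normalization the favored value is exactly
#' `preference_strength` times the column median. The remaining positions
#' are flat (all values 1). This is the shape real screens produce: a few
#' strongly selective flank positions over a near-uniform background.
#'
#' @param kinase_id Character scalar.
#' @param n_selective_positions Number of selective flank positions (0..9).
#' @param preference_strength Fold preference of the favored residue over
#'   the rest of its column; must be > 0. 1 gives a flat motif.
#' @param acceptor_pref Named numeric over S, T, Y summing to 1: the
#'   kinase's phospho-acceptor preference.
#' @param seed Integer seed; the motif is a pure function of the arguments.
#' @return Object of class `TrueMotif` with fields `kinase_id`, `values`
#'   (9 x 22 matrix, position means 1), `acceptor_pref`, and
#'   `selective` (data frame of selective positions and favored residues).
#' @examples
#' tm <- make_true_motif("NEKA", n_selective_positions = 3,
#'                       preference_strength = 5, seed = 42)
#' rowMeans(tm$values)  # all 1
#' @export
make_true_motif <- function(kinase_id,
                            n_selective_positions = 3L,
                            preference_strength = 5,
                            acceptor_pref = c(S = 0.5, T = 0.4, Y = 0.1),
                            seed) {
  assert_scalar_number(preference_strength, "preference_strength",
                       positive = TRUE)
  if (n_selective_positions < 0 ||
      n_selective_positions > length(OPLS_POSITIONS)) {
    stop_opls("parameter", "n_selective_positions must be in 0..%d",
              length(OPLS_POSITIONS))
  }
  if (is.null(names(acceptor_pref)) ||
      !setequal(names(acceptor_pref), OPLS_ACCEPTORS) ||
      any(acceptor_pref <= 0) || abs(sum(acceptor_pref) - 1) > 1e-9) {
    stop_opls("parameter",
              "acceptor_pref must be positive over S, T, Y and sum to 1")
  }
  if (missing(seed)) stop_opls("parameter", "`seed` is required")
  acceptor_pref <- acceptor_pref[OPLS_ACCEPTORS]
  withr::with_seed(as.integer(seed), {
    sel_pos <- sort(sample(seq_along(OPLS_POSITIONS), n_selective_positions))
    fav_res <- sample(OPLS_RESIDUES, n_selective_positions, replace = TRUE)
  })
  values <- empty_flank_matrix(fill = 1)
  for (i in seq_len(n_selective_positions)) {
    values[sel_pos[i], fav_res[i]] <- preference_strength
  }
  values <- values / rowMeans(values)
  structure(
    list(kinase_id = as.character(kinase_id), values = values,
         acceptor_pref = acceptor_pref,
         selective = data.frame(
           position = OPLS_POSITIONS[sel_pos],
           residue = fav_res, stringsAsFactors = FALSE)),
    class = "TrueMotif"
  )
}

#' @export
print.TrueMotif <- function(x, ...) {
  cat(sprintf("TrueMotif: kinase %s, %d selective position(s)\n",
              x$kinase_id, nrow(x$selective)))
  if (nrow(x$selective) > 0) {
    cat("  ", paste(sprintf("%+d:%s", x$selective$position,
                            x$selective$residue), collapse = " "), "\n")
  }
  cat("  acceptor preference:",
      paste(sprintf("%s=%.2f", names(x$acceptor_pref), x$acceptor_pref),
            collapse = " "), "\n")
  invisible(x)
}

#' Noise model for simulated OPLS blots
#'
#' Two noise sources observed on real dot blots: a per-spot multiplicative
#' lognormal term (spotting, incorporation and quantification noise) and a
#' per-blot global scale factor (exposure differences between blots). The
#' normalization pipeline is exactly invariant to the global scale, which
#' is what makes it a useful simulation check.
#'
#' @param sigma_log Standard deviation of the lognormal spot noise on the
#'   natural-log scale; 0 gives noiseless spots.
#' @param blot_scale_range Length-2 positive vector `(low, high)`; each
#'   replicate's global scale is drawn uniformly from it.
#' @return Object of class `NoiseModel`.
#' @export
noise_model <- function(sigma_log = 0.1, blot_scale_range = c(0.5, 2)) {
  assert_scalar_number(sigma_log, "sigma_log", nonnegative = TRUE)
  if (length(blot_scale_range) != 2L || any(blot_scale_range <= 0) ||
      blot_scale_range[1] > blot_scale_range[2]) {
    stop_opls("parameter",
              "blot_scale_range must be positive with low <= high")
  }
  structure(list(sigma_log = sigma_log,
                 blot_scale_range = as.numeric(blot_scale_range)),
            class = "NoiseModel")
}

#' Simulate replicate OPLS spot grids from a ground-truth motif
#'
#' Each replicate's raw intensity at (position, residue) is
#' `blot_scale * truth * exp(N(0, sigma_log))`, with one `blot_scale` drawn
#' per replicate. The acceptor pools are generated the same way from the
#' motif's acceptor preference. Raw grids are deliberately not normalized:
#' their position means differ from 1 whenever `blot_scale != 1`.
#'
#' @param truth A [make_true_motif()] object.
#' @param noise A [noise_model()].
#' @param n_replicates At least 1.
#' @param seed Integer seed (required for reproducibility).
#' @param library Library type stamped on the grids.
#' @return List of [spot_grid()] objects, one per replicate.
#' @export
simulate_spot_grids <- function(truth, noise = noise_model(),
                                n_replicates = 2L, seed = 1L,
                                library = c("ST", "Y")) {
  library <- match.arg(library)
  if (!inherits(truth, "TrueMotif")) {
    stop_opls("input", "simulate_spot_grids expects a TrueMotif")
  }
  if (!inherits(noise, "NoiseModel")) {
    stop_opls("input", "`noise` must be a noise_model()")
  }
  if (n_replicates < 1L) stop_opls("parameter", "n_replicates must be >= 1")
  withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_replicates), function(r) {
      scale <- runif(1, noise$blot_scale_range[1], noise$blot_scale_range[2])
      eps <- matrix(exp(rnorm(length(truth$values), 0, noise$sigma_log)),
                    nrow(truth$values), ncol(truth$values))
      flank <- scale * truth$values * eps
      dimnames(flank) <- dimnames(truth$values)
      acc <- scale * truth$acceptor_pref *
        exp(rnorm(length(truth$acceptor_pref), 0, noise$sigma_log))
      spot_grid(truth$kinase_id, flank, acceptor = acc, library = library,
                replicate_id = sprintf("rep%d", r))
    })
  })
}

#' Specification of a synthetic candidate-site database
#'
#' @param n_background Number of background sites (windows drawn i.i.d.
#'   from `background_freqs`).
#' @param n_implanted_per_kinase Number of motif-matching sites implanted
#'   per ground-truth motif.
#' @param background_freqs Named probabilities over the 20 amino acids;
#'   default uniform.
#' @param acceptor_rule Which acceptor residues sites carry; sampled
#'   uniformly for background sites and from the motif's acceptor
#'   preference (restricted to `acceptor_rule`) for implanted sites.
#' @return Object of class `SiteDatabaseSpec`.
#' @export
site_database_spec <- function(n_background = 950L,
                               n_implanted_per_kinase = 50L,
                               background_freqs = NULL,
                               acceptor_rule = c("S", "T")) {
  if (n_background < 0 || n_implanted_per_kinase < 0) {
    stop_opls("parameter", "site counts must be >= 0")
  }
  if (is.null(background_freqs)) {
    background_freqs <- setNames(rep(1 / 20, 20), OPLS_AA20)
  }
  if (is.null(names(background_freqs)) ||
      !setequal(names(background_freqs), OPLS_AA20) ||
      any(background_freqs < 0) ||
      abs(sum(background_freqs) - 1) > 1e-9) {
    stop_opls("parameter",
              "background_freqs must be probabilities over the 20 amino acids summing to 1")
  }
  if (length(acceptor_rule) == 0L ||
      !all(acceptor_rule %in% OPLS_ACCEPTORS)) {
    stop_opls("parameter", "acceptor_rule must be a nonempty subset of S,T,Y")
  }
  structure(list(n_background = as.integer(n_background),
                 n_implanted_per_kinase = as.integer(n_implanted_per_kinase),
                 background_freqs = background_freqs[OPLS_AA20],
                 acceptor_rule = acceptor_rule),
            class = "SiteDatabaseSpec")
}

# sample one 9-residue flank window, one column of probs per position
sample_window <- function(prob_by_pos) {
  paste(vapply(seq_len(9L), function(i) {
    sample(OPLS_AA20, 1L, prob = prob_by_pos[[i]])
  }, ""), collapse = "")
}

#' Simulate a candidate phosphosite database with implanted motif matches
#'
#' Background windows are drawn i.i.d. from the background residue
#' frequencies. Implanted windows are drawn per position from a motif's
#' column values renormalized to probabilities over the 20 amino acids —
#' the better a kinase prefers a residue, the more often implanted sites
#' carry it. Every site gets a unique `(protein_id, position)` key and a
#' `group` column (`"background"` or the implanting kinase id) recording
#' ground truth.
#'
#' @param spec A [site_database_spec()].
#' @param implant_motifs List of [make_true_motif()] objects (may be empty).
#' @param seed Integer seed.
#' @return Data frame of class `candidate_sites` with columns
#'   `protein_id`, `position`, `acceptor`, `window`, `group`.
#' @export
simulate_site_database <- function(spec, implant_motifs = list(), seed = 1L) {
  if (!inherits(spec, "SiteDatabaseSpec")) {
    stop_opls("input", "simulate_site_database expects a SiteDatabaseSpec")
  }
  total <- spec$n_background +
    spec$n_implanted_per_kinase * length(implant_motifs)
  if (total == 0L) stop_opls("parameter", "site database would be empty")
  withr::with_seed(as.integer(seed), {
    rows <- list()
    if (spec$n_background > 0L) {
      wins <- vapply(seq_len(spec$n_background), function(i) {
        paste(sample(OPLS_AA20, 9L, replace = TRUE,
                     prob = spec$background_freqs), collapse = "")
      }, "")
      rows[[1L]] <- data.frame(
        protein_id = sprintf("BG%05d", seq_len(spec$n_background)),
        position = sample(10:800, spec$n_background, replace = TRUE),
        acceptor = sample(spec$acceptor_rule, spec$n_background,
                          replace = TRUE),
        window = wins, group = "background", stringsAsFactors = FALSE)
    }
    for (k in seq_along(implant_motifs)) {
      tm <- implant_motifs[[k]]
      if (!inherits(tm, "TrueMotif")) {
        stop_opls("input", "implant_motifs must be TrueMotif objects")
      }
      if (spec$n_implanted_per_kinase == 0L) next
      probs <- lapply(seq_len(9L), function(i) {
        v <- tm$values[i, OPLS_AA20]
        v / sum(v)
      })
      wins <- vapply(seq_len(spec$n_implanted_per_kinase), function(i) {
        sample_window(probs)
      }, "")
      apref <- tm$acceptor_pref[spec$acceptor_rule]
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = sprintf("IMP_%s_%04d", tm$kinase_id,
                             seq_len(spec$n_implanted_per_kinase)),
        position = sample(10:800, spec$n_implanted_per_kinase,
                          replace = TRUE),
        acceptor = sample(spec$acceptor_rule,
                          spec$n_implanted_per_kinase, replace = TRUE,
                          prob = apref / sum(apref)),
        window = wins, group = tm$kinase_id, stringsAsFactors = FALSE)
    }
  })
  sites <- do.call(rbind, rows)
  rownames(sites) <- NULL
  class(sites) <- c("candidate_sites", "data.frame")
  sites
}

#' Simulate a kinase-assay time course
#'
#' Scintillation counts rise linearly with incubation time during the
#' initial-rate phase; Gaussian noise models counting and pipetting error.
#'
#' @param rate True phosphorylation rate, CPM per minute.
#' @param intercept Background counts at time 0.
#' @param timepoints Numeric vector of at least 2 distinct times (minutes).
#' @param noise_sd Standard deviation of additive Gaussian noise (CPM).
#' @param seed Integer seed.
#' @param label,replicate_id Labels carried on the output.
#' @return Data frame of class `time_course` with columns `label`,
#'   `replicate`, `time_min`, `cpm`.
#' @export
simulate_timecourse <- function(rate, intercept = 0,
                                timepoints = c(0, 5, 10, 15, 20),
                                noise_sd = 0, seed = 1L,
                                label = "peptide", replicate_id = "rep1") {
  assert_scalar_number(rate, "rate")
  assert_scalar_number(noise_sd, "noise_sd", nonnegative = TRUE)
  if (length(unique(timepoints)) < 2L) {
    stop_opls("parameter", "need at least 2 distinct timepoints")
  }
  counts <- withr::with_seed(as.integer(seed), {
    intercept + rate * timepoints + rnorm(length(timepoints), 0, noise_sd)
  })
  tc <- data.frame(label = label, replicate = replicate_id,
                   time_min = as.numeric(timepoints), cpm = counts,
                   stringsAsFactors = FALSE)
  class(tc) <- c("time_course", "data.frame")
  tc
}
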