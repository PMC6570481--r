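pipeline_config_keys <- list(
  seed = "integer (required)",
  sigma_log = "lognormal spot-noise sd",
  blot_scale_range = "length-2 positive range",
  n_replicates = "replicates per kinase",
  floor = "log2 floor",
  cap_exceptions = "list of {position, residue}",
  include_acceptor = "use acceptor pools in clustering",
  min_overlap = "minimum complete cells per correlation pair",
  fraction = "percentile selection fraction(s)",
  n_background = "background sites",
  n_implanted_per_kinase = "implanted sites per kinase",
  kinases = "kinase ids to simulate",
  n_selective_positions = "selective positions per true motif",
  preference_strength = "fold preference of favored residues",
  out_dir = "output directory",
  paths = "named input paths"
)

#' Read and validate a pipeline configuration JSON
#'
#' A flat JSON object of pipeline parameters. `seed` is mandatory
#' (every stochastic stage derives its stream from it) and unknown keys
#' are rejected so typos fail loudly rather than silently using defaults.
#'
#' @param path JSON file path.
#' @return Named list of validated configuration values, with defaults
#'   filled in for absent keys.
#' @export
read_pipeline_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  validate_pipeline_config(cfg)
}

#' @rdname read_pipeline_config
#' @param cfg Named list as parsed from JSON.
#' @export
validate_pipeline_config <- function(cfg) {
  unknown <- setdiff(names(cfg), names(pipeline_config_keys))
  if (length(unknown) > 0L) {
    stop_opls("config", "unknown configuration key(s): %s",
              paste(unknown, collapse = ", "))
  }
  if (is.null(cfg$seed)) {
    stop_opls("config", "`seed` is required in the configuration")
  }
  cfg$seed <- as.integer(cfg$seed)
  defaults <- list(sigma_log = 0.1, blot_scale_range = c(0.5, 2),
                   n_replicates = 3L, floor = 2^-6,
                   include_acceptor = TRUE, min_overlap = 150L,
                   fraction = 0.10, n_background = 950L,
                   n_implanted_per_kinase = 50L,
                   kinases = c("KIN_A", "KIN_B"),
                   n_selective_positions = 3L,
                   preference_strength = 5)
  for (k in names(defaults)) {
    if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  }
  assert_scalar_number(cfg$sigma_log, "sigma_log", nonnegative = TRUE)
  assert_scalar_number(cfg$floor, "floor", positive = TRUE)
  if (any(cfg$fraction <= 0 | cfg$fraction > 1)) {
    stop_opls("config", "`fraction` values must be in (0, 1]")
  }
  cfg
}
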