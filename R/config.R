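#' Default run configuration
#'
#' Permutation defaults follow standard practice for this kind of survey:
#' 10,000 permutations for F_ST/AMOVA significance and 1,000 for Mantel
#' tests. The Hardy-Weinberg exact test defaults are desk-scale
#' (100,000 Monte-Carlo samples, 1,000 burn-in) and can be raised to the
#' full-scale 10,000,000 / 10,000 via the config file or `full = TRUE` in
#' [run_pipeline()].
#'
#' @return a `run_config` list.
#' @export
default_config <- function() {
  structure(list(
    genotypes = NULL,          # path to genepop file (NULL = simulate)
    phenotypes = NULL,         # path to phenotype table
    preset = NULL,             # e.g. "lucerne3"
    seed = 1L,
    fst_permutations = 10000L,
    mantel_permutations = 1000L,
    amova_permutations = 10000L,
    hwe_samples = 100000L,
    hwe_burnin = 1000L,
    ld_permutations = 499L,
    bootstrap_replicates = 1000L,
    fdr_q = 0.05,
    rarefaction_g = NULL,      # NULL = smallest group gene count
    min_cluster_frac = 0.10,
    mixture_k_max = 3L
  ), class = "run_config")
}

#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON) config file, fills unset keys from
#' [default_config()], warns on unknown keys and fails on invalid values
#' (permutation counts below 99, rarefaction size below 2 genes).
#'
#' @param path path to a YAML config file, or `NULL` for pure defaults.
#' @return a validated `run_config`.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) abort(paste0("no such config file: ", path))
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown)) {
      warn(paste0("ignoring unknown config keys: ", paste(unknown, collapse = ", ")))
    }
    for (k in intersect(names(user), names(cfg))) cfg[[k]] <- user[[k]]
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  int_keys <- c("seed", "fst_permutations", "mantel_permutations",
                "amova_permutations", "hwe_samples", "hwe_burnin",
                "ld_permutations", "bootstrap_replicates", "mixture_k_max")
  for (k in int_keys) cfg[[k]] <- as.integer(cfg[[k]])
  for (k in c("fst_permutations", "mantel_permutations", "amova_permutations",
              "ld_permutations")) {
    if (cfg[[k]] < 99L) abort(sprintf("%s must be at least 99 (got %d)", k, cfg[[k]]))
  }
  if (!is.null(cfg$rarefaction_g) && cfg$rarefaction_g < 2) {
    abort("rarefaction_g must be at least 2 genes")
  }
  if (cfg$fdr_q <= 0 || cfg$fdr_q >= 1) abort("fdr_q must be in (0, 1)")
  if (cfg$min_cluster_frac <= 0 || cfg$min_cluster_frac > 0.5) {
    abort("min_cluster_frac must be in (0, 0.5]")
  }
  cfg
}
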