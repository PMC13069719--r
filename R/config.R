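#' Pipeline configuration
#'
#' Collects the tuning constants of the variability-calling pipeline in one
#' validated object.  Defaults follow the study design this package
#' implements: 10% of samples removed per downsample, ten repeats, top and
#' bottom SD deciles, a 500 bp cis window for SNP-CpG pairs, an epiallele
#' candidate window of mean beta in [0.40, 0.60], and a dip-test alpha of
#' 0.05 with a Monte-Carlo null of 2000 draws.
#'
#' @param drop_fraction fraction of samples removed in each downsample,
#'   in \[0, 1); 0 disables downsampling.
#' @param n_repeats number of downsampling repeats per cohort.
#' @param decile_fraction fraction `q` of probes labelled VMP (highest SD)
#'   and SMP (lowest SD) in each run, in (0, 1).
#' @param cis_window_bp SNP-CpG distance (bp) at or below which a pair is
#'   classified cis.
#' @param epiallele_mean_window inclusive mean-beta window for epiallele
#'   candidates.
#' @param dip_alpha significance threshold for the dip test.
#' @param dip_mc_reps Monte-Carlo replicates for the dip null.
#' @param permutation_reps replicates for permutation enrichment tests.
#' @param rng_seed integer seed controlling all randomised stages.
#' @param max_missing_fraction probes with a larger fraction of missing
#'   betas are dropped before analysis.
#' @param sum_tolerance allowed deviation of the six cell proportions from
#'   summing to 1.
#' @return an object of class `methvar_config` (a validated named list).
#' @export
methvar_config <- function(drop_fraction = 0.10,
                           n_repeats = 10L,
                           decile_fraction = 0.10,
                           cis_window_bp = 500L,
                           epiallele_mean_window = c(0.40, 0.60),
                           dip_alpha = 0.05,
                           dip_mc_reps = 2000L,
                           permutation_reps = 1000L,
                           rng_seed = 1L,
                           max_missing_fraction = 0.05,
                           sum_tolerance = 0.05) {
  cfg <- list(drop_fraction = as.numeric(drop_fraction),
              n_repeats = as.integer(n_repeats),
              decile_fraction = as.numeric(decile_fraction),
              cis_window_bp = as.integer(cis_window_bp),
              epiallele_mean_window = as.numeric(epiallele_mean_window),
              dip_alpha = as.numeric(dip_alpha),
              dip_mc_reps = as.integer(dip_mc_reps),
              permutation_reps = as.integer(permutation_reps),
              rng_seed = as.integer(rng_seed),
              max_missing_fraction = as.numeric(max_missing_fraction),
              sum_tolerance = as.numeric(sum_tolerance))
  validate_config(cfg)
  class(cfg) <- "methvar_config"
  cfg
}

validate_config <- function(cfg) {
  stopifnot(cfg$drop_fraction >= 0, cfg$drop_fraction < 1,
            cfg$decile_fraction > 0, cfg$decile_fraction < 1,
            cfg$n_repeats >= 1L, cfg$cis_window_bp >= 0L,
            length(cfg$epiallele_mean_window) == 2L,
            cfg$epiallele_mean_window[1] <= cfg$epiallele_mean_window[2],
            cfg$dip_alpha > 0, cfg$dip_alpha < 1,
            cfg$dip_mc_reps >= 1L, cfg$permutation_reps >= 1L,
            cfg$max_missing_fraction >= 0, cfg$max_missing_fraction <= 1)
  invisible(cfg)
}

#' Read a pipeline configuration from a YAML file
#'
#' Fields absent from the file keep their [methvar_config()] defaults;
#' entries in `overrides` (e.g. from command-line flags) win over the file.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @param overrides named list of fields overriding the file.
#' @return a `methvar_config` object.
#' @export
read_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    vals <- yaml::read_yaml(path)
    bad <- setdiff(names(vals), names(formals(methvar_config)))
    if (length(bad))
      stop("unknown config fields: ", paste(bad, collapse = ", "))
  }
  vals[names(overrides)] <- overrides
  do.call(methvar_config, vals)
}

#' Write a configuration as YAML
#'
#' @param config a `methvar_config` object.
#' @param path output path.
#' @export
write_config <- function(config, path) {
  validate_config(config)
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
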