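# Putative epiallele screen: VMPs with intermediate mean methylation whose
# cross-individual beta distribution is bimodal by the dip test.

#' Screen VMPs for putative epialleles
#'
#' Candidates are the catalogue's final VMPs whose mean beta (over the
#' supplied, typically cohort-pooled, matrix) lies inside the inclusive
#' `epiallele_mean_window`.  Each candidate's betas are dip-tested against
#' a shared Monte-Carlo uniform null of `dip_mc_reps` draws (one null per
#' screen, all candidates share the same sample size).  A probe is flagged
#' as a putative epiallele iff it is a candidate and its dip p-value is
#' below `dip_alpha`.  Non-candidates are reported with NA dip values and
#' `is_epiallele = FALSE`; degenerate (constant) candidates are reported,
#' never an error.  A Benjamini-Hochberg column over the tested candidates
#' is supplied for reference but takes no part in the flag.
#'
#' @param betas probe-by-sample matrix (pool the cohorts with `cbind` to
#'   mirror the catalogue's combined call).
#' @param catalog a `variability_catalog` over the same probes.
#' @param config a [methvar_config()] object (window, alpha, B, seed).
#' @return data.frame: probe_id, mean_beta, tested, dip_stat, dip_p,
#'   dip_p_bh, is_epiallele.
#' @export
screen_epialleles <- function(betas, catalog, config = methvar_config()) {
  validate_config(config)
  vmps <- vmp_ids(catalog)
  missing_probes <- setdiff(vmps, rownames(betas))
  if (length(missing_probes))
    stop("catalogue VMP(s) absent from beta matrix: ",
         paste(head(missing_probes, 3), collapse = ", "))
  w <- config$epiallele_mean_window
  mean_beta <- rowMeans(betas, na.rm = TRUE)

  out <- data.frame(probe_id = rownames(betas),
                    mean_beta = mean_beta,
                    tested = FALSE,
                    dip_stat = NA_real_, dip_p = NA_real_,
                    dip_p_bh = NA_real_, is_epiallele = FALSE,
                    row.names = NULL, stringsAsFactors = FALSE)
  cand <- out$probe_id %in% vmps &
    mean_beta >= w[1] & mean_beta <= w[2]
  out$tested <- cand
  if (any(cand)) {
    n_samp <- ncol(betas)
    null_dips <- dip_null_distribution(n_samp, config$dip_mc_reps,
                                       rng_seed = config$rng_seed)
    idx <- which(cand)
    for (i in idx) {
      vals <- betas[i, ]
      vals <- vals[!is.na(vals)]
      out$dip_stat[i] <- as.numeric(dip_statistic(vals))
      if (length(vals) == n_samp) {
        out$dip_p[i] <- dip_pvalue(out$dip_stat[i], length(vals),
                                   null_dips = null_dips)
      } else {
        # incomplete probe: the shared null has the wrong sample size
        out$dip_p[i] <- dip_pvalue(out$dip_stat[i], length(vals),
                                   B = config$dip_mc_reps,
                                   rng_seed = config$rng_seed + i)
      }
    }
    out$dip_p_bh[idx] <- p.adjust(out$dip_p[idx], method = "BH")
    out$is_epiallele[idx] <- out$dip_p[idx] < config$dip_alpha
  }
  out
}
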