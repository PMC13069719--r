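# VMP/SMP identification: per-probe SD, repeated downsampling, decile
# selection, intersection across repeats and cohorts.

#' Per-probe standard deviation
#'
#' Sample SD (n - 1 denominator) of each probe across its non-missing
#' samples, computed with a two-pass algorithm.
#'
#' @param betas probe-by-sample numeric matrix.
#' @return named numeric vector of SDs.
#' @export
probe_sd <- function(betas) {
  nn <- rowSums(!is.na(betas))
  if (any(nn < 2L))
    stop("probe(s) with fewer than 2 non-missing values: ",
         paste(head(rownames(betas)[nn < 2L], 3), collapse = ", "))
  mu <- rowMeans(betas, na.rm = TRUE)
  dev <- betas - mu
  dev[is.na(dev)] <- 0
  sq <- rowSums(dev^2)
  setNames(sqrt(sq / (nn - 1L)), rownames(betas))
}

#' One downsampled VMP/SMP call
#'
#' Removes `floor(drop_fraction * n_samples)` samples uniformly without
#' replacement (the draw is keyed to sorted sample ids, so column order is
#' irrelevant), recomputes per-probe SD on the remainder, and labels the
#' `floor(q * n_probes)` probes of highest SD as VMPs and of lowest SD as
#' SMPs.  Ties at the cut are broken towards the lexicographically smaller
#' probe id.
#'
#' @param betas probe-by-sample matrix.
#' @param drop_fraction fraction of samples removed, in \[0, 1).
#' @param q decile fraction, in (0, 1).
#' @param rng_seed seed for the downsampling draw.
#' @return list with `vmp`, `smp` (sorted probe id vectors), `sd` (the SD
#'   vector on the retained samples) and `dropped` (removed sample ids).
#' @export
call_single_run <- function(betas, drop_fraction, q, rng_seed) {
  stopifnot(drop_fraction >= 0, drop_fraction < 1, q > 0, q < 1)
  P <- nrow(betas)
  k <- floor(q * P)
  if (k < 1L) stop("too few probes for decile fraction q = ", q)
  ids_sorted <- sort(colnames(betas))
  n_drop <- floor(drop_fraction * length(ids_sorted))
  set.seed(rng_seed)
  dropped <- if (n_drop > 0) sort(sample(ids_sorted, n_drop)) else character(0)
  keep <- setdiff(colnames(betas), dropped)
  sds <- probe_sd(betas[, keep, drop = FALSE])
  ord_hi <- order(-sds, rownames(betas))
  ord_lo <- order(sds, rownames(betas))
  list(vmp = sort(rownames(betas)[ord_hi[seq_len(k)]]),
       smp = sort(rownames(betas)[ord_lo[seq_len(k)]]),
       sd = sds, dropped = dropped)
}

#' Build the VMP/SMP catalogue from two cohorts
#'
#' Runs `n_repeats` downsampled calls per cohort (repeat `i` of the
#' discovery cohort is seeded `rng_seed + i`, repeat `i` of the validation
#' cohort `rng_seed + n_repeats + i`), keeps only probes appearing in all
#' repeats of a cohort, and intersects the two cohorts for the final call.
#' Probes with more than `max_missing_fraction` missing betas in either
#' cohort are dropped beforehand (their call is `NA`).
#'
#' @param discovery,validation probe-by-sample matrices over the same
#'   probes.
#' @param config a [methvar_config()] object.
#' @return a `variability_catalog` data.frame with per-probe SDs, per-run
#'   membership counts, per-cohort and combined calls; the configuration is
#'   attached as attribute `config`.
#' @export
call_catalog <- function(discovery, validation, config = methvar_config()) {
  validate_config(config)
  if (!setequal(rownames(discovery), rownames(validation)))
    stop("cohort probe sets differ (symmetric difference of size ",
         length(setdiff(rownames(discovery), rownames(validation))) +
           length(setdiff(rownames(validation), rownames(discovery))), ")")
  validation <- validation[rownames(discovery), , drop = FALSE]

  frac_na <- pmax(rowMeans(is.na(discovery)), rowMeans(is.na(validation)))
  keep <- frac_na <= config$max_missing_fraction
  if (!any(keep)) stop("all probes exceed the missingness threshold")
  dropped_probes <- rownames(discovery)[!keep]
  discovery <- discovery[keep, , drop = FALSE]
  validation <- validation[keep, , drop = FALSE]

  run_cohort <- function(betas, seed0) {
    runs <- lapply(seq_len(config$n_repeats), function(i)
      call_single_run(betas, config$drop_fraction, config$decile_fraction,
                      seed0 + i))
    vmp_counts <- table(factor(unlist(lapply(runs, `[[`, "vmp")),
                               levels = rownames(betas)))
    smp_counts <- table(factor(unlist(lapply(runs, `[[`, "smp")),
                               levels = rownames(betas)))
    list(vmp_runs = as.integer(vmp_counts), smp_runs = as.integer(smp_counts),
         runs = runs)
  }
  dsc <- run_cohort(discovery, config$rng_seed)
  val <- run_cohort(validation, config$rng_seed + config$n_repeats)

  call_of <- function(vr, sr) {
    ifelse(vr == config$n_repeats, "VMP",
           ifelse(sr == config$n_repeats, "SMP", "neither"))
  }
  call_d <- call_of(dsc$vmp_runs, dsc$smp_runs)
  call_v <- call_of(val$vmp_runs, val$smp_runs)
  combined <- ifelse(call_d == "VMP" & call_v == "VMP", "VMP",
                     ifelse(call_d == "SMP" & call_v == "SMP", "SMP",
                            "neither"))

  cat_df <- data.frame(
    probe_id = rownames(discovery),
    sd_discovery = probe_sd(discovery),
    sd_validation = probe_sd(validation),
    runs_vmp_discovery = dsc$vmp_runs,
    runs_smp_discovery = dsc$smp_runs,
    runs_vmp_validation = val$vmp_runs,
    runs_smp_validation = val$smp_runs,
    call_discovery = call_d,
    call_validation = call_v,
    call = combined,
    row.names = NULL, stringsAsFactors = FALSE)
  if (length(dropped_probes)) {
    pad <- data.frame(probe_id = dropped_probes, sd_discovery = NA_real_,
                      sd_validation = NA_real_, runs_vmp_discovery = NA_integer_,
                      runs_smp_discovery = NA_integer_,
                      runs_vmp_validation = NA_integer_,
                      runs_smp_validation = NA_integer_,
                      call_discovery = NA_character_,
                      call_validation = NA_character_, call = NA_character_,
                      stringsAsFactors = FALSE)
    cat_df <- rbind(cat_df, pad)
  }
  attr(cat_df, "config") <- config
  attr(cat_df, "runs_discovery") <- lapply(dsc$runs, `[`, c("vmp", "smp"))
  attr(cat_df, "runs_validation") <- lapply(val$runs, `[`, c("vmp", "smp"))
  class(cat_df) <- c("variability_catalog", "data.frame")
  cat_df
}

#' Extract final VMP / SMP probe ids from a catalogue
#' @param catalog a `variability_catalog`.
#' @return character vector of probe ids.
#' @export
vmp_ids <- function(catalog) catalog$probe_id[!is.na(catalog$call) & catalog$call == "VMP"]

#' @rdname vmp_ids
#' @export
smp_ids <- function(catalog) catalog$probe_id[!is.na(catalog$call) & catalog$call == "SMP"]

#' Overlap of the VMP set with labelled CpG lists
#'
#' Upset-style exclusive counts of VMPs per combination of list
#' memberships, plus the pairwise intersection matrix.  Ids in the lists
#' that are not VMPs simply count as non-members; unknown ids (absent from
#' the catalogue) are tallied in `unknown_ids`.
#'
#' @param catalog a `variability_catalog`.
#' @param cpg_lists named list of probe id vectors.
#' @return list with `exclusive` (data.frame of membership patterns and
#'   counts over the VMP set), `pairwise` (matrix of intersection sizes,
#'   including the VMP set itself) and `unknown_ids`.
#' @export
overlap_report <- function(catalog, cpg_lists) {
  stopifnot(length(cpg_lists) >= 1, !is.null(names(cpg_lists)))
  vmps <- vmp_ids(catalog)
  membership <- vapply(cpg_lists, function(ids) vmps %in% ids,
                       logical(length(vmps)))
  if (length(vmps) == 1L) membership <- matrix(membership, nrow = 1L,
                                               dimnames = list(NULL, names(cpg_lists)))
  pattern <- apply(membership, 1L, function(r)
    paste(ifelse(r, names(cpg_lists), ""), collapse = "")[1])
  pattern[pattern == ""] <- "(none)"
  exclusive <- as.data.frame(table(pattern), stringsAsFactors = FALSE)
  names(exclusive) <- c("combination", "n_vmp")

  sets <- c(list(VMP = vmps), cpg_lists)
  pairwise <- outer(seq_along(sets), seq_along(sets),
                    Vectorize(function(i, j) length(intersect(sets[[i]], sets[[j]]))))
  dimnames(pairwise) <- list(names(sets), names(sets))

  known <- catalog$probe_id
  unknown <- sum(!unlist(cpg_lists) %in% known)
  list(exclusive = exclusive, pairwise = pairwise, unknown_ids = unknown)
}
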