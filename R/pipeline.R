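# End-to-end orchestration: read inputs, run every stage in study order,
# write result tables plus the configuration snapshot.  All outputs are
# deterministic functions of (inputs, config$rng_seed); no timestamps are
# written, so reruns are byte-identical.

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full pipeline on files
#'
#' Stages, in order: variability catalogue (raw), cell correction and a
#' second catalogue on corrected betas, catalogue sensitivity report,
#' genomic-context enrichment of VMPs and SMPs (with an imprinted-overlap
#' permutation test), optional phenotype-list overlap, mQTL cis/trans
#' classification with TAD/loop co-occupancy, epiallele screen, and
#' methylation-expression correlation (variation mode over epialleles;
#' level mode when the matrices share samples).  Any stage failure aborts
#' with the stage name.
#'
#' @param config a [methvar_config()] object.
#' @param inputs named list of file paths: `betas_discovery`,
#'   `betas_validation`, `manifest`, `samples`, `mqtl`, `tads`, `loops`,
#'   `expression`; optionally `cpg_lists` (named list of files, one probe
#'   id per line).
#' @param out_dir output directory.
#' @return invisibly, a named list of the objects written.
#' @export
run_pipeline <- function(config, inputs, out_dir) {
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  need <- c("betas_discovery", "betas_validation", "manifest", "samples",
            "mqtl", "tads", "loops", "expression")
  miss <- setdiff(need, names(inputs))
  if (length(miss)) stop("missing inputs: ", paste(miss, collapse = ", "))

  dat <- run_stage("read_inputs", {
    list(bd = read_beta_matrix(inputs$betas_discovery),
         bv = read_beta_matrix(inputs$betas_validation),
         manifest = read_probe_manifest(inputs$manifest),
         sheet = read_sample_sheet(inputs$samples, config$sum_tolerance),
         mqtl = read_mqtl_table(inputs$mqtl),
         tads = read_intervals(inputs$tads, "bed"),
         loops = read_intervals(inputs$loops, "bedpe"),
         expr = read_expression_matrix(inputs$expression))
  })

  catalog <- run_stage("variability_catalog",
    call_catalog(dat$bd, dat$bv, config))

  cell <- run_stage("cell_adjustment", {
    fitD <- fit_cell_model(dat$bd, dat$sheet)
    fitV <- fit_cell_model(dat$bv, dat$sheet)
    corrD <- corrected_betas(fitD)
    corrV <- corrected_betas(fitV)
    cat_adj <- call_catalog(corrD, corrV, config)
    list(catalog_adjusted = cat_adj,
         report = cell_sensitivity_report(catalog, cat_adj),
         out_of_range = c(discovery = attr(corrD, "out_of_range_rate"),
                          validation = attr(corrV, "out_of_range_rate")))
  })

  enr <- run_stage("enrichment", {
    vmps <- vmp_ids(catalog); smps <- smp_ids(catalog)
    imprinted_ids <- annotation_probes(dat$manifest, "imprinted")
    list(vmp = enrichment_table(vmps, dat$manifest),
         smp = enrichment_table(smps, dat$manifest),
         imprinted_perm = permutation_enrichment(
           vmps, dat$manifest$probe_id, imprinted_ids,
           n_reps = config$permutation_reps, rng_seed = config$rng_seed))
  })

  overlap <- NULL
  if (!is.null(inputs$cpg_lists)) {
    overlap <- run_stage("overlap_report", {
      lists <- lapply(inputs$cpg_lists, function(p)
        readLines(p, warn = FALSE))
      overlap_report(catalog, lists)
    })
  }

  mq <- run_stage("mqtl_chromatin", {
    pairs <- classify_pairs(dat$mqtl, dat$manifest, config$cis_window_bp)
    pairs <- annotate_pairs(pairs, dat$tads, dat$loops)
    vmps <- vmp_ids(catalog); smps <- smp_ids(catalog)
    pv <- pairs[pairs$cpg_id %in% vmps, , drop = FALSE]
    ps <- pairs[pairs$cpg_id %in% smps, , drop = FALSE]
    trans <- pairs[pairs$pair_class == "trans", , drop = FALSE]
    co <- list()
    if (nrow(pv[pv$pair_class == "trans", ]))
      co$vmp <- co_occupancy_enrichment(pv[pv$pair_class == "trans", ], trans)
    if (nrow(ps[ps$pair_class == "trans", ]))
      co$smp <- co_occupancy_enrichment(ps[ps$pair_class == "trans", ], trans)
    list(pairs = pairs, summary = summarize_cpg_mqtl(pairs),
         co_occupancy = co,
         vmp_linked_fraction = mean(vmps %in% pairs$cpg_id),
         smp_linked_fraction = mean(smps %in% pairs$cpg_id))
  })

  epi <- run_stage("epialleles",
    screen_epialleles(cbind(dat$bd, dat$bv), catalog, config))

  expr_link <- run_stage("expression_link", {
    epi_ids <- epi$probe_id[epi$is_epiallele]
    vv <- if (length(epi_ids) >= 3)
      correlate_variation(epi_ids, cbind(dat$bd, dat$bv), dat$expr,
                          dat$manifest) else NULL
    ll <- if (length(epi_ids) >= 1 &&
              length(intersect(colnames(dat$bd), colnames(dat$expr))) >= 3)
      correlate_levels(epi_ids, dat$bd, dat$expr, dat$manifest) else NULL
    list(variation = vv, levels = ll)
  })

  ## ---- write everything -------------------------------------------------
  paths <- c()
  paths["catalog"] <- write_tsv(as.data.frame(catalog),
                                file.path(out_dir, "catalog.tsv"))
  paths["catalog_cellcorrected"] <- write_tsv(
    as.data.frame(cell$catalog_adjusted),
    file.path(out_dir, "catalog_cellcorrected.tsv"))
  sens <- data.frame(
    metric = c("lost_vmp", "gained_vmp", "lost_smp", "gained_smp",
               "lost_vmp_fraction", "lost_smp_fraction"),
    value = c(length(cell$report$lost_vmp), length(cell$report$gained_vmp),
              length(cell$report$lost_smp), length(cell$report$gained_smp),
              cell$report$fractions[["lost_vmp"]],
              cell$report$fractions[["lost_smp"]]))
  paths["cell_sensitivity"] <- write_tsv(sens,
    file.path(out_dir, "cell_sensitivity.tsv"))
  paths["enrichment_vmp"] <- write_tsv(enr$vmp,
    file.path(out_dir, "enrichment_vmp.tsv"))
  paths["enrichment_smp"] <- write_tsv(enr$smp,
    file.path(out_dir, "enrichment_smp.tsv"))
  paths["imprinted_permutation"] <- write_tsv(
    data.frame(observed = enr$imprinted_perm$observed,
               expected = enr$imprinted_perm$expected,
               perm_p = enr$imprinted_perm$perm_p),
    file.path(out_dir, "imprinted_permutation.tsv"))
  if (!is.null(overlap))
    paths["overlap_vmp"] <- write_tsv(overlap$exclusive,
      file.path(out_dir, "overlap_vmp.tsv"))
  paths["mqtl_pairs"] <- write_tsv(mq$pairs,
    file.path(out_dir, "mqtl_pairs.tsv"))
  paths["mqtl_cpg_summary"] <- write_tsv(mq$summary,
    file.path(out_dir, "mqtl_cpg_summary.tsv"))
  if (length(mq$co_occupancy)) {
    co <- do.call(rbind, lapply(names(mq$co_occupancy), function(s)
      cbind(set = s, mq$co_occupancy[[s]])))
    paths["co_occupancy"] <- write_tsv(co,
      file.path(out_dir, "co_occupancy.tsv"))
  }
  paths["epialleles"] <- write_tsv(epi, file.path(out_dir, "epialleles.tsv"))
  if (!is.null(expr_link$variation))
    paths["correlation_variation"] <- write_tsv(expr_link$variation,
      file.path(out_dir, "correlation_variation.tsv"))
  if (!is.null(expr_link$levels)) {
    paths["correlation_levels_groups"] <- write_tsv(expr_link$levels$groups,
      file.path(out_dir, "correlation_levels_groups.tsv"))
    paths["correlation_levels_pairs"] <- write_tsv(expr_link$levels$pairs,
      file.path(out_dir, "correlation_levels_pairs.tsv"))
  }
  write_config(config, file.path(out_dir, "config_used.yaml"))
  log_lines <- c("methvar pipeline run",
                 paste0("rng_seed: ", config$rng_seed),
                 paste0("stage outputs: ", length(paths)),
                 paste0("  - ", names(paths)))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))

  invisible(list(catalog = catalog, cell = cell, enrichment = enr,
                 overlap = overlap, mqtl = mq, epialleles = epi,
                 expression = expr_link, paths = paths))
}
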