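# EPIC-like synthetic bundles with planted ground truth.
#
# Probe classes and their beta-family parameterisation (mean mu,
# concentration k; shape1 = mu*k, shape2 = (1-mu)*k):
#   stable_low / stable_high  -- mu near 0.05 / 0.95, high concentration
#   variable_unimodal         -- mu in [0.4, 0.6], low concentration
#   epiallele_bimodal         -- two-component mixture, per-sample component
#   cell_driven               -- mu = baseline + effect * cell proportion
#   mqtl_driven               -- mu = baseline + effect * genotype (0/1/2),
#                                genotypes Hardy-Weinberg at the given MAF
# Out-of-range means are clipped into (0, 1) and the clip rate recorded.

#' Design of a synthetic EPIC-like bundle
#'
#' Holds every knob of the generator.  Defaults describe a desk-scale blood
#' methylation study: 2000 probes, 400 + 400 samples in two cohorts, a
#' class mix dominated by unimodal variable and stable probes, bimodal
#' epiallele mixtures at modes 0.25/0.75, a granulocyte-driven cell class,
#' Hardy-Weinberg genotype effects at MAF 0.3, 21% cis mQTL pairs within
#' 500 bp, 90% of trans pairs sharing a TAD, and methylation-SD to
#' expression-CV coupling of rho = 0.6 through a Gaussian copula.
#'
#' @param n_probes number of probes.
#' @param n_samples_discovery,n_samples_validation cohort sizes.
#' @param class_mix named fractions over the six probe classes; must sum
#'   to 1.
#' @param stable_concentration,variable_concentration,bimodal_concentration,
#'   cell_concentration,mqtl_concentration beta concentrations per class;
#'   `variable_concentration` may be a length-2 range from which each
#'   unimodal variable probe draws its own concentration, giving a
#'   continuous SD spectrum.
#' @param cell_dirichlet_concentration concentration of the Dirichlet that
#'   generates the six cell proportions (smaller = more interindividual
#'   compositional variability).
#' @param bimodal_modes,bimodal_weight two component means and the weight of
#'   the lower component.
#' @param cell_driver driven cell type (one of the five modelled
#'   proportions), `cell_effect` its slope on the beta scale (a scalar, or
#'   a length-2 range from which each cell-driven probe draws its own
#'   slope).
#' @param mqtl_effect per-allele beta shift (scalar or per-probe range);
#'   `mqtl_maf` minor allele frequency; `mqtl_extra_fraction` fraction of
#'   non-mqtl-driven probes
#'   that still receive (effect-free) mQTL records, forming the background
#'   pair set.
#' @param cis_fraction fraction of mQTL pairs within the cis window;
#'   `trans_tad_share` fraction of trans pairs placed in a shared TAD;
#'   `trans_loop_share` fraction of trans pairs connected by a planted
#'   loop; `trans_crosschrom_fraction` fraction of trans pairs on a
#'   different chromosome.
#' @param expr_coupling_rho target Spearman-scale coupling between per-probe
#'   methylation SD and per-gene expression CV.
#' @param level_coupling_slope slope (beta units, negative) of the planted
#'   expression-on-methylation dependence at 5'UTR epiallele probes.
#' @param rng_seed integer seed.
#' @return a validated `simulation_design` object.
#' @export
simulation_design <- function(n_probes = 2000L,
                              n_samples_discovery = 400L,
                              n_samples_validation = 400L,
                              class_mix = c(stable_low = 0.20,
                                            stable_high = 0.20,
                                            variable_unimodal = 0.35,
                                            epiallele_bimodal = 0.05,
                                            cell_driven = 0.10,
                                            mqtl_driven = 0.10),
                              stable_concentration = 200,
                              variable_concentration = c(6, 40),
                              cell_dirichlet_concentration = 30,
                              bimodal_modes = c(0.25, 0.75),
                              bimodal_weight = 0.5,
                              bimodal_concentration = 50,
                              cell_driver = "Gran",
                              cell_effect = c(0.8, 2.0),
                              cell_concentration = 150,
                              mqtl_effect = c(0.10, 0.25),
                              mqtl_maf = 0.3,
                              mqtl_concentration = 100,
                              mqtl_extra_fraction = 0.10,
                              cis_fraction = 0.21,
                              trans_tad_share = 0.90,
                              trans_loop_share = 0.10,
                              trans_crosschrom_fraction = 0.05,
                              expr_coupling_rho = 0.6,
                              level_coupling_slope = -1.0,
                              rng_seed = 1L) {
  classes <- c("stable_low", "stable_high", "variable_unimodal",
               "epiallele_bimodal", "cell_driven", "mqtl_driven")
  if (!setequal(names(class_mix), classes))
    stop("class_mix must name exactly the six probe classes")
  class_mix <- class_mix[classes]
  if (abs(sum(class_mix) - 1) > 1e-8) stop("class_mix must sum to 1")
  if (any(class_mix < 0)) stop("class_mix fractions must be non-negative")
  mixture_mean <- bimodal_weight * bimodal_modes[1] +
    (1 - bimodal_weight) * bimodal_modes[2]
  if (mixture_mean <= 0 || mixture_mean >= 1)
    stop("infeasible bimodal mixture mean")
  if (!cell_driver %in% setdiff(CELL_TYPES, "NK"))
    stop("cell_driver must be one of the five modelled proportions")
  design <- as.list(environment())
  design$classes <- classes
  class(design) <- "simulation_design"
  design
}

rbeta_mu <- function(n, mu, k) {
  mu <- pmin(pmax(mu, 1e-3), 1 - 1e-3)
  rbeta(n, mu * k, (1 - mu) * k)
}

dirichlet_props <- function(n, means, concentration = 60) {
  draws <- vapply(means, function(m) rgamma(n, shape = m * concentration),
                  numeric(n))
  draws / rowSums(draws)
}

#' Simulate a complete synthetic bundle
#'
#' Generates two cohort beta matrices, the probe manifest, sample sheet,
#' mQTL table, TADs, loops, an expression matrix and the ground truth, all
#' deterministically from `design$rng_seed`.
#'
#' @param design a [simulation_design()] object.
#' @return a list of class `methvar_bundle` with elements
#'   `betas_discovery`, `betas_validation`, `manifest`, `samples`, `mqtl`,
#'   `tads`, `loops`, `expression`, `truth` and `clip_rate`.
#' @export
simulate_bundle <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  set.seed(design$rng_seed)
  P <- design$n_probes
  nD <- design$n_samples_discovery
  nV <- design$n_samples_validation

  counts <- diff(c(0L, floor(cumsum(design$class_mix) * P + 1e-9)))
  probe_class <- sample(rep(design$classes, counts))
  probe_ids <- sprintf("cg%06d", seq_len(P))

  ## ---- sample sheets ----------------------------------------------------
  cell_means <- c(CD8T = 0.09, CD4T = 0.17, NK = 0.05, B = 0.06,
                  Mono = 0.08, Gran = 0.55)
  mk_sheet <- function(prefix, n, cohort) {
    props <- dirichlet_props(n, cell_means,
                             design$cell_dirichlet_concentration)
    colnames(props) <- names(cell_means)
    data.frame(sample_id = sprintf("%s%04d", prefix, seq_len(n)),
               cohort = cohort,
               sex = sample(c("F", "M"), n, replace = TRUE),
               age = sample(25:75, n, replace = TRUE),
               smoking = sample(c("never", "former", "current"), n,
                                replace = TRUE, prob = c(0.55, 0.25, 0.20)),
               props, stringsAsFactors = FALSE)
  }
  sheet <- rbind(mk_sheet("D", nD, "discovery"), mk_sheet("V", nV, "validation"))

  ## ---- per-probe parameters --------------------------------------------
  base_mu <- numeric(P)
  driver <- rep(NA_character_, P)
  base_mu[probe_class == "stable_low"] <-
    runif(sum(probe_class == "stable_low"), 0.03, 0.07)
  base_mu[probe_class == "stable_high"] <-
    runif(sum(probe_class == "stable_high"), 0.93, 0.97)
  n_var <- sum(probe_class == "variable_unimodal")
  base_mu[probe_class == "variable_unimodal"] <- runif(n_var, 0.4, 0.6)
  vr <- range(design$variable_concentration)
  var_conc <- setNames(runif(n_var, vr[1], vr[2]),
                       probe_ids[probe_class == "variable_unimodal"])
  # cell-driven probes: mu = baseline + effect * proportion, with the
  # baseline chosen so the population-average methylation sits mid-range
  # (avoids saturating the beta scale at large slopes)
  n_cell <- sum(probe_class == "cell_driven")
  cr <- range(design$cell_effect)
  cell_eff <- setNames(runif(n_cell, cr[1], cr[2]),
                       probe_ids[probe_class == "cell_driven"])
  cell_target <- runif(n_cell, 0.35, 0.60)
  base_mu[probe_class == "cell_driven"] <-
    cell_target - cell_eff * cell_means[[design$cell_driver]]
  n_mq <- sum(probe_class == "mqtl_driven")
  base_mu[probe_class == "mqtl_driven"] <- runif(n_mq, 0.15, 0.30)
  mr <- range(design$mqtl_effect)
  mqtl_eff <- setNames(runif(n_mq, mr[1], mr[2]),
                       probe_ids[probe_class == "mqtl_driven"])
  driver[probe_class == "cell_driven"] <- design$cell_driver

  ## ---- genotypes and mQTL records --------------------------------------
  maf <- design$mqtl_maf
  hw <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
  mqtl_probes <- which(probe_class == "mqtl_driven")
  geno <- list(
    discovery = matrix(sample(0:2, length(mqtl_probes) * nD, TRUE, hw),
                       nrow = length(mqtl_probes)),
    validation = matrix(sample(0:2, length(mqtl_probes) * nV, TRUE, hw),
                        nrow = length(mqtl_probes)))
  rownames(geno$discovery) <- rownames(geno$validation) <- probe_ids[mqtl_probes]

  ## ---- betas ------------------------------------------------------------
  clip_lo <- 0.001; clip_hi <- 0.999
  n_clipped <- 0; n_drawn <- 0
  draw_cohort <- function(n, props, geno_mat) {
    mat <- matrix(NA_real_, P, n)
    for (i in seq_len(P)) {
      cls <- probe_class[i]
      mu <- switch(cls,
        stable_low = ,
        stable_high = rep(base_mu[i], n),
        variable_unimodal = rep(base_mu[i], n),
        epiallele_bimodal = ifelse(
          runif(n) < design$bimodal_weight,
          design$bimodal_modes[1], design$bimodal_modes[2]),
        cell_driven = base_mu[i] + cell_eff[[probe_ids[i]]] *
          props[, design$cell_driver],
        mqtl_driven = base_mu[i] + mqtl_eff[[probe_ids[i]]] *
          geno_mat[probe_ids[i], ])
      k <- switch(cls,
        stable_low = , stable_high = design$stable_concentration,
        variable_unimodal = var_conc[[probe_ids[i]]],
        epiallele_bimodal = design$bimodal_concentration,
        cell_driven = design$cell_concentration,
        mqtl_driven = design$mqtl_concentration)
      n_drawn <<- n_drawn + n
      n_clipped <<- n_clipped + sum(mu < clip_lo | mu > clip_hi)
      mat[i, ] <- rbeta_mu(n, mu, k)
    }
    rownames(mat) <- probe_ids
    mat
  }
  sheetD <- sheet[sheet$cohort == "discovery", ]
  sheetV <- sheet[sheet$cohort == "validation", ]
  betasD <- draw_cohort(nD, as.matrix(sheetD[, CELL_TYPES]), geno$discovery)
  betasV <- draw_cohort(nV, as.matrix(sheetV[, CELL_TYPES]), geno$validation)
  colnames(betasD) <- sheetD$sample_id
  colnames(betasV) <- sheetV$sample_id

  ## ---- genome layout: chromosomes, TADs, loops, positions ---------------
  n_chrom <- 22L
  tad_width <- 1e6; tad_gap <- 5e4; tads_per_chrom <- 20L
  tad_starts0 <- (seq_len(tads_per_chrom) - 1L) * (tad_width + tad_gap)
  tads <- GenomicRanges::GRanges(
    rep(paste0("chr", seq_len(n_chrom)), each = tads_per_chrom),
    IRanges::IRanges(start = rep(tad_starts0 + 1, n_chrom),
                     end = rep(tad_starts0 + tad_width, n_chrom)))

  chrom <- paste0("chr", sample.int(n_chrom, P, replace = TRUE))
  tad_idx <- sample.int(tads_per_chrom, P, replace = TRUE)
  # keep CpGs away from TAD edges so planted same-TAD partners fit inside
  pos <- as.integer(tad_starts0[tad_idx] + floor(runif(P, 5e4, tad_width - 5e4)) + 1L)

  ## ---- manifest annotations ---------------------------------------------
  variable_cls <- probe_class %in%
    c("variable_unimodal", "epiallele_bimodal", "cell_driven", "mqtl_driven")
  island_rel <- character(P)
  island_rel[variable_cls] <- sample(ISLAND_LEVELS, sum(variable_cls), TRUE,
                                     prob = c(0.15, 0.35, 0.15, 0.35))
  island_rel[!variable_cls] <- sample(ISLAND_LEVELS, sum(!variable_cls), TRUE,
                                      prob = c(0.45, 0.10, 0.10, 0.35))
  base_feats <- c("exon", "intron", "promoter", "intergenic", "TE", "3UTR")
  features <- vapply(seq_len(P), function(i) {
    f <- sample(base_feats, sample(1:2, 1))
    if (variable_cls[i] && runif(1) < 0.40) f <- c(f, "enhancer")
    if (!variable_cls[i] && runif(1) < 0.10) f <- c(f, "enhancer")
    if (probe_class[i] == "epiallele_bimodal" && runif(1) < 0.30)
      f <- "5UTR"  # exclusive, so the planted level-coupling stays in one group
    paste(sort(unique(f)), collapse = ";")
  }, character(1))
  imprinted <- runif(P) < ifelse(variable_cls, 0.02, 0.001)
  non_cpg <- runif(P) < ifelse(probe_class %in% c("stable_low", "stable_high"),
                               0.02, 0.005)
  gene <- sprintf("GENE%05d", seq_len(P))
  manifest <- data.frame(
    probe_id = probe_ids, chrom = chrom, pos = pos,
    island_relation = island_rel, features = features, gene = gene,
    imprinted = imprinted, non_cpg = non_cpg,
    on_450k = runif(P) < 0.5, stringsAsFactors = FALSE)

  ## ---- mQTL pair placement ----------------------------------------------
  extra_probes <- sample(which(probe_class != "mqtl_driven"),
                         floor(design$mqtl_extra_fraction * P))
  pair_cpg_idx <- c(mqtl_probes[rep(seq_along(mqtl_probes),
                                    1L + rpois(length(mqtl_probes), 0.5))],
                    extra_probes)
  n_pair <- length(pair_cpg_idx)
  is_cis <- runif(n_pair) < design$cis_fraction
  snp_chrom <- chrom[pair_cpg_idx]
  snp_pos <- integer(n_pair)
  pair_same_tad <- rep(NA, n_pair)
  loop_rows <- list()
  for (p in seq_len(n_pair)) {
    ci <- pair_cpg_idx[p]
    if (is_cis[p]) {
      snp_pos[p] <- pos[ci] + sample(c(-1, 1), 1) * sample.int(design$cis_window_bp %||% 500L, 1)
      pair_same_tad[p] <- NA  # cis: co-occupancy reported for trans pairs
      next
    }
    if (runif(1) < design$trans_crosschrom_fraction) {
      snp_chrom[p] <- paste0("chr", sample(setdiff(seq_len(n_chrom),
        as.integer(sub("chr", "", chrom[ci]))), 1))
      ti <- sample.int(tads_per_chrom, 1)
      snp_pos[p] <- as.integer(tad_starts0[ti] + floor(runif(1, 5e4, tad_width - 5e4)) + 1L)
      pair_same_tad[p] <- FALSE
      next
    }
    same <- runif(1) < design$trans_tad_share
    ti <- if (same) tad_idx[ci] else
      sample(setdiff(seq_len(tads_per_chrom), tad_idx[ci]), 1)
    repeat {
      cand <- as.integer(tad_starts0[ti] + floor(runif(1, 5e4, tad_width - 5e4)) + 1L)
      if (abs(cand - pos[ci]) > 500L || !same) break
    }
    snp_pos[p] <- cand
    pair_same_tad[p] <- same
    if (runif(1) < design$trans_loop_share && abs(cand - pos[ci]) > 3e4) {
      loop_rows[[length(loop_rows) + 1L]] <-
        data.frame(chrom = chrom[ci],
                   s1 = snp_pos[p] - 5e3, e1 = snp_pos[p] + 5e3,
                   s2 = pos[ci] - 5e3, e2 = pos[ci] + 5e3)
    }
  }
  mqtl <- data.frame(
    snp_id = sprintf("rs%06d", seq_len(n_pair)),
    snp_chrom = snp_chrom, snp_pos = pmax(1L, snp_pos),
    cpg_id = probe_ids[pair_cpg_idx], stringsAsFactors = FALSE)
  # one driving SNP per mqtl_driven probe is flagged in the truth table
  driving_snp <- mqtl$snp_id[match(probe_ids[mqtl_probes], mqtl$cpg_id)]
  driver[mqtl_probes] <- driving_snp

  loops <- if (length(loop_rows)) {
    lr <- do.call(rbind, loop_rows)
    structure(list(
      anchor1 = GenomicRanges::GRanges(lr$chrom,
        IRanges::IRanges(start = pmax(1, lr$s1), end = lr$e1)),
      anchor2 = GenomicRanges::GRanges(lr$chrom,
        IRanges::IRanges(start = pmax(1, lr$s2), end = lr$e2))),
      class = "methvar_loops")
  } else {
    structure(list(anchor1 = GenomicRanges::GRanges(),
                   anchor2 = GenomicRanges::GRanges()),
              class = "methvar_loops")
  }

  ## ---- expression with copula-coupled dispersion -------------------------
  sd_meth <- probe_sd(betasD)
  z1 <- qnorm(rank(sd_meth, ties.method = "average") / (P + 1))
  z2 <- design$expr_coupling_rho * z1 +
    sqrt(1 - design$expr_coupling_rho^2) * rnorm(P)
  cv_target <- exp(log(0.25) + 0.4 * z2)
  gene_mean <- exp(rnorm(P, log(100), 0.5))
  expr <- matrix(NA_real_, P, nD,
                 dimnames = list(gene, sheetD$sample_id))
  shape <- 1 / cv_target^2
  for (i in seq_len(P))
    expr[i, ] <- rgamma(nD, shape = shape[i], rate = shape[i] / gene_mean[i])
  # planted negative level-coupling at 5'UTR epialleles
  coupled <- which(probe_class == "epiallele_bimodal" &
                     grepl("(^|;)5UTR(;|$)", features))
  for (i in coupled) {
    b <- betasD[i, ]
    expr[i, ] <- gene_mean[i] * (1.5 + design$level_coupling_slope * b) +
      rnorm(nD, 0, 0.05 * gene_mean[i])
    expr[i, ] <- pmax(expr[i, ], 0)
  }

  truth <- data.frame(probe_id = probe_ids, class = probe_class,
                      driver = driver, gene = gene,
                      cv_target = cv_target, stringsAsFactors = FALSE)

  structure(list(betas_discovery = betasD, betas_validation = betasV,
                 manifest = manifest, samples = sheet, mqtl = mqtl,
                 tads = tads, loops = loops, expression = expr,
                 truth = truth, clip_rate = n_clipped / n_drawn,
                 design = design),
            class = "methvar_bundle")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sample labelled CpG lists from planted classes
#'
#' Stands in for external phenotype-associated CpG catalogues (age, sex,
#' smoking, cell type): each list is a random sample of the probes of a
#' designated true class.
#'
#' @param truth ground-truth data.frame from [simulate_bundle()].
#' @param fractions named fractions in \[0, 1\], one per list.
#' @param classes named character vector (same names) giving the true class
#'   to sample each list from.
#' @param rng_seed integer seed.
#' @return named list of probe id vectors.
#' @export
plant_phenotype_cpg_lists <- function(truth, fractions, classes, rng_seed = 1L) {
  stopifnot(setequal(names(fractions), names(classes)),
            all(fractions >= 0), all(fractions <= 1))
  set.seed(rng_seed)
  out <- list()
  for (nm in names(fractions)) {
    pool <- truth$probe_id[truth$class == classes[[nm]]]
    k <- floor(fractions[[nm]] * length(pool))
    if (k > length(pool)) stop("fraction exceeds available probes")
    out[[nm]] <- sort(sample(pool, k))
  }
  out
}

#' Write a bundle to disk in the pipeline's file formats
#'
#' @param bundle a `methvar_bundle`.
#' @param dir output directory (created if needed).
#' @return named vector of file paths, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    betas_discovery = file.path(dir, "betas_discovery.tsv"),
    betas_validation = file.path(dir, "betas_validation.tsv"),
    manifest = file.path(dir, "manifest.csv"),
    samples = file.path(dir, "samples.csv"),
    mqtl = file.path(dir, "mqtl.tsv"),
    tads = file.path(dir, "tads.bed"),
    loops = file.path(dir, "loops.bedpe"),
    expression = file.path(dir, "expression.tsv"),
    truth = file.path(dir, "truth.tsv"))
  write_beta_matrix(bundle$betas_discovery, paths["betas_discovery"])
  write_beta_matrix(bundle$betas_validation, paths["betas_validation"])
  write_probe_manifest(bundle$manifest, paths["manifest"])
  write_sample_sheet(bundle$samples, paths["samples"])
  write_mqtl_table(bundle$mqtl, paths["mqtl"])
  write_intervals(bundle$tads, paths["tads"])
  write_intervals(bundle$loops, paths["loops"])
  write_expression_matrix(bundle$expression, paths["expression"])
  write.table(bundle$truth, paths["truth"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}
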