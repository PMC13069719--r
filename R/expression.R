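# Methylation-expression integration: dispersion-vs-dispersion in
# unmatched cohorts (per-probe SD against per-gene CV) and
# level-vs-level across matched samples, stratified by genomic feature.

#' Per-gene coefficient of variation
#'
#' CV = sample SD / mean, per gene.  Genes with non-positive mean are
#' excluded (their count is attached as attribute `n_excluded`); an error
#' is raised if nothing remains.
#'
#' @param expr gene-by-sample matrix.
#' @return named numeric vector of CVs.
#' @export
expression_cv <- function(expr) {
  mu <- rowMeans(expr)
  keep <- mu > 0
  if (!any(keep)) stop("no genes with positive mean expression")
  sds <- apply(expr[keep, , drop = FALSE], 1L, sd)
  out <- sds / mu[keep]
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Map probes to target genes and features
#'
#' One row per (probe, feature) combination: probes carrying several
#' features contribute to each group.  Probes with an empty gene field
#' are dropped (count in attribute `n_dropped`); a multi-gene field
#' ("A;B") resolves to the first listed gene.
#'
#' @param probe_ids probes to map.
#' @param manifest probe manifest.
#' @return data.frame: probe_id, gene, feature.
#' @export
map_probe_to_gene <- function(probe_ids, manifest) {
  idx <- match(probe_ids, manifest$probe_id)
  if (anyNA(idx))
    stop("probe id(s) missing from manifest: ",
         paste(head(probe_ids[is.na(idx)], 3), collapse = ", "))
  gene <- vapply(strsplit(manifest$gene[idx], ";"),
                 function(g) if (length(g)) g[[1]] else "", character(1))
  keep <- !is.na(gene) & gene != ""
  n_dropped <- sum(!keep)
  feats <- strsplit(manifest$features[idx], ";")
  rows <- lapply(which(keep), function(i) {
    f <- feats[[i]]
    if (!length(f) || identical(f, "")) f <- "(none)"
    data.frame(probe_id = probe_ids[i], gene = gene[i], feature = f,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(probe_id = character(0), gene = character(0),
               feature = character(0), stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- n_dropped
  out
}

pearson_with_p <- function(x, y) {
  n <- length(x)
  if (n < 3L || sd(x) == 0 || sd(y) == 0)
    return(c(r = NA_real_, p = NA_real_, n = n))
  r <- cor(x, y)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  c(r = r, p = 2 * pt(-abs(tt), df = n - 2), n = n)
}

#' Correlate methylation variability with expression variability
#'
#' Unmatched-cohort mode: for each feature group, the Pearson correlation
#' across probe-gene pairs between the probe's methylation SD and the
#' target gene's expression CV (cohorts need not share samples).  Groups
#' with fewer than 3 pairs are reported with NA.
#'
#' @param probe_ids probes to analyse (e.g. putative epialleles or VMPs).
#' @param betas probe-by-sample matrix supplying methylation SD.
#' @param expr gene-by-sample expression matrix supplying CV.
#' @param manifest probe manifest for the gene/feature mapping.
#' @param overall also emit an "(all)" row pooling every pair.
#' @return data.frame: feature, n_pairs, pearson_r, r_p_value, mode.
#' @export
correlate_variation <- function(probe_ids, betas, expr, manifest,
                                overall = TRUE) {
  mapping <- map_probe_to_gene(probe_ids, manifest)
  mapping <- mapping[mapping$probe_id %in% rownames(betas) &
                       mapping$gene %in% rownames(expr), , drop = FALSE]
  sds <- probe_sd(betas[unique(mapping$probe_id), , drop = FALSE])
  cvs <- expression_cv(expr)
  groups <- split(mapping, mapping$feature)
  if (overall) groups <- c(groups, list("(all)" = unique(mapping[, c("probe_id", "gene")])))
  rows <- lapply(names(groups), function(g) {
    mp <- unique(groups[[g]][, c("probe_id", "gene")])
    stat <- pearson_with_p(sds[mp$probe_id], cvs[mp$gene])
    data.frame(feature = g, n_pairs = as.integer(stat["n"]),
               pearson_r = stat[["r"]], r_p_value = stat[["p"]],
               mode = "variation_vs_variation", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Correlate methylation level with expression level in matched samples
#'
#' For every probe-gene pair, the Pearson correlation between the probe's
#' betas and the gene's expression across the samples shared by the two
#' matrices (at least 3 required), plus per-feature-group summaries
#' (mean r over the group's pairs).
#'
#' @param probe_ids probes to analyse.
#' @param betas probe-by-sample matrix.
#' @param expr gene-by-sample matrix sharing sample ids with `betas`.
#' @param manifest probe manifest.
#' @return list with `pairs` (per probe-gene records) and `groups`
#'   (per-feature mean r), both carrying mode "level_vs_level".
#' @export
correlate_levels <- function(probe_ids, betas, expr, manifest) {
  shared <- intersect(colnames(betas), colnames(expr))
  if (length(shared) < 3L) stop("fewer than 3 shared samples")
  mapping <- map_probe_to_gene(probe_ids, manifest)
  mapping <- mapping[mapping$probe_id %in% rownames(betas) &
                       mapping$gene %in% rownames(expr), , drop = FALSE]
  uniq <- unique(mapping[, c("probe_id", "gene")])
  stats <- t(vapply(seq_len(nrow(uniq)), function(i) {
    b <- betas[uniq$probe_id[i], shared]
    e <- expr[uniq$gene[i], shared]
    ok <- !is.na(b) & !is.na(e)
    pearson_with_p(b[ok], e[ok])
  }, numeric(3)))
  pair_df <- data.frame(uniq, pearson_r = stats[, "r"],
                        r_p_value = stats[, "p"],
                        n_samples = as.integer(stats[, "n"]),
                        mode = "level_vs_level", stringsAsFactors = FALSE)
  key <- paste(mapping$probe_id, mapping$gene)
  pkey <- paste(pair_df$probe_id, pair_df$gene)
  groups <- do.call(rbind, lapply(split(key, mapping$feature), function(k) {
    r <- pair_df$pearson_r[match(unique(k), pkey)]
    data.frame(n_pairs = length(unique(k)), mean_r = mean(r, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  groups <- data.frame(feature = rownames(groups), groups,
                       mode = "level_vs_level",
                       row.names = NULL, stringsAsFactors = FALSE)
  list(pairs = pair_df, groups = groups)
}
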