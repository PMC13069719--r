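# Genomic-context enrichment of probe sets against the array background:
# log2(observed/expected) fractions, Fisher's exact test on the 2x2
# contrast (the background column excludes the test set, so the two
# columns are disjoint), and a permutation test for annotation overlap.

#' Resolve an annotation name to the probes carrying it
#'
#' `annotation` may be an island relation ("island", "shore", "shelf",
#' "open_sea"), a genomic feature ("exon", "intron", "5UTR", "3UTR",
#' "promoter", "enhancer", "intergenic", "TE"; probes may carry several),
#' or a flag ("imprinted", "non_cpg", "on_450k").
#'
#' @param manifest probe manifest.
#' @param annotation annotation name.
#' @return character vector of probe ids.
#' @export
annotation_probes <- function(manifest, annotation) {
  if (annotation %in% ISLAND_LEVELS)
    return(manifest$probe_id[manifest$island_relation == annotation])
  if (annotation %in% FEATURE_LEVELS)
    return(manifest$probe_id[grepl(paste0("(^|;)", annotation, "(;|$)"),
                                   manifest$features)])
  if (annotation %in% c("imprinted", "non_cpg", "on_450k"))
    return(manifest$probe_id[manifest[[annotation]]])
  stop("unknown annotation: ", annotation)
}

#' log2 observed/expected enrichment of a set against a background
#'
#' `log2((n_in_set/n_set) / (n_in_background/n_background))`; marked
#' undefined (NA with `undefined = TRUE`) when either fraction is zero.
#'
#' @param set_ids probe ids of the test set (must be a subset of the
#'   background).
#' @param background_ids probe ids of the background universe.
#' @param annotated_ids probe ids carrying the annotation.
#' @return list: counts, `log2_ratio`, `undefined`.
#' @export
log2_obs_exp <- function(set_ids, background_ids, annotated_ids) {
  if (!length(set_ids) || !length(background_ids))
    stop("empty set or background")
  if (!all(set_ids %in% background_ids))
    stop("set must be a subset of the background")
  n_set <- length(set_ids)
  n_bg <- length(background_ids)
  n_in_set <- sum(set_ids %in% annotated_ids)
  n_in_bg <- sum(background_ids %in% annotated_ids)
  undefined <- n_in_set == 0L || n_in_bg == 0L
  ratio <- if (undefined) NA_real_ else
    log2((n_in_set / n_set) / (n_in_bg / n_bg))
  list(n_in_set = n_in_set, n_set = n_set,
       n_in_background = n_in_bg, n_background = n_bg,
       log2_ratio = ratio, undefined = undefined)
}

#' Fisher's exact test for set-vs-background annotation enrichment
#'
#' Two-sided p-value for the 2x2 table contrasting the test set with the
#' background *excluding* the set (set is a subset of the background):
#' rows set / background-without-set, columns annotated / not.
#'
#' @param n_in_set annotated probes inside the set.
#' @param n_set set size.
#' @param n_in_background annotated probes in the full background
#'   (including the set).
#' @param n_background background size (including the set).
#' @return two-sided p-value.
#' @export
fisher_enrichment <- function(n_in_set, n_set, n_in_background, n_background) {
  a <- n_in_set
  b <- n_set - n_in_set
  cc <- n_in_background - n_in_set
  d <- (n_background - n_set) - cc
  if (min(a, b, cc, d) < 0) stop("negative cell in derived 2x2 table")
  fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE))$p.value
}

#' Permutation test for annotation overlap
#'
#' Draws `n_reps` random sets of the observed size from the background
#' (without replacement) and reports the add-one permutation p-value for
#' the observed annotation overlap being high:
#' `(1 + #draws with overlap >= observed) / (n_reps + 1)`.
#'
#' @param set_ids test set (subset of background).
#' @param background_ids background universe.
#' @param annotated_ids probes carrying the annotation.
#' @param n_reps number of permutations.
#' @param rng_seed seed.
#' @return list: `observed`, `expected` (mean permuted overlap), `perm_p`.
#' @export
permutation_enrichment <- function(set_ids, background_ids, annotated_ids,
                                   n_reps = 1000L, rng_seed = 1L) {
  if (n_reps < 1L) stop("n_reps must be >= 1")
  if (length(set_ids) > length(background_ids))
    stop("set larger than background")
  observed <- sum(set_ids %in% annotated_ids)
  is_annot <- background_ids %in% annotated_ids
  k <- length(set_ids)
  set.seed(rng_seed)
  perm <- vapply(seq_len(n_reps),
                 function(i) sum(is_annot[sample.int(length(is_annot), k)]),
                 integer(1))
  list(observed = observed, expected = mean(perm),
       perm_p = (1 + sum(perm >= observed)) / (n_reps + 1))
}

#' Enrichment table for a probe set over a collection of annotations
#'
#' One row per annotation: counts, log2 observed/expected and the
#' two-sided Fisher p-value against the (autosomal array) background.
#'
#' @param set_ids test set.
#' @param manifest probe manifest.
#' @param background_ids background universe (default: all manifest
#'   probes).
#' @param annotations annotation names (default: island relations,
#'   features and flags).
#' @return data.frame of enrichment records.
#' @export
enrichment_table <- function(set_ids, manifest, background_ids = NULL,
                             annotations = NULL) {
  if (is.null(background_ids)) background_ids <- manifest$probe_id
  if (is.null(annotations))
    annotations <- c(ISLAND_LEVELS, FEATURE_LEVELS,
                     "imprinted", "non_cpg", "on_450k")
  rows <- lapply(annotations, function(ann) {
    ann_ids <- annotation_probes(manifest, ann)
    le <- log2_obs_exp(set_ids, background_ids, ann_ids)
    p <- fisher_enrichment(le$n_in_set, le$n_set,
                           le$n_in_background, le$n_background)
    data.frame(annotation = ann, n_in_set = le$n_in_set, n_set = le$n_set,
               n_in_background = le$n_in_background,
               n_background = le$n_background,
               log2_ratio = le$log2_ratio, undefined = le$undefined,
               fisher_p = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Housekeeping versus tissue-specific gene labels
#'
#' A gene is housekeeping iff its within-tissue percentile rank (average
#' ranks for ties) is at least `1 - top_fraction` in every tissue, i.e.
#' its expression sits in the top `top_fraction` everywhere; all other
#' genes are tissue-specific.  A constant tissue column leaves every gene
#' tied, and all genes pass for that tissue.
#'
#' @param expr_by_tissue genes x tissues matrix.
#' @param top_fraction fraction defining "top" expression (default 0.40).
#' @return named character vector, "housekeeping" or "tissue_specific".
#' @export
label_housekeeping <- function(expr_by_tissue, top_fraction = 0.40) {
  if (ncol(expr_by_tissue) < 2L) stop("need at least two tissues")
  n <- nrow(expr_by_tissue)
  pass <- vapply(seq_len(ncol(expr_by_tissue)), function(j) {
    colv <- expr_by_tissue[, j]
    if (length(unique(colv)) == 1L) return(rep(TRUE, n))
    rank(colv, ties.method = "average") / n >= 1 - top_fraction
  }, logical(n))
  hk <- rowSums(pass) == ncol(expr_by_tissue)
  setNames(ifelse(hk, "housekeeping", "tissue_specific"),
           rownames(expr_by_tissue))
}
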