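# SNP-CpG pair classification and 3D-chromatin co-occupancy.
#
# "cis" follows the nucleosome-scale definition used throughout this
# package: same chromosome and |snp_pos - cpg_pos| <= cis_window_bp
# (default 500 bp, roughly three nucleosomes).  Everything else -- larger
# separation or different chromosomes -- is "trans".

#' Classify SNP-CpG pairs as cis or trans
#'
#' Joins CpG coordinates from the manifest onto the mQTL table and
#' classifies every pair.  Distance is defined for same-chromosome pairs
#' only (NA otherwise); a pair at exactly the window boundary is cis.
#'
#' @param mqtl mQTL table (snp_id, snp_chrom, snp_pos, cpg_id).
#' @param manifest probe manifest supplying CpG chrom/pos.
#' @param cis_window_bp cis window in bp.
#' @return data.frame of pair records: ids, coordinates, `distance_bp`,
#'   `pair_class` ("cis"/"trans").
#' @export
classify_pairs <- function(mqtl, manifest, cis_window_bp = 500L) {
  idx <- match(mqtl$cpg_id, manifest$probe_id)
  if (anyNA(idx))
    stop("mQTL CpG id(s) missing from manifest: ",
         paste(head(mqtl$cpg_id[is.na(idx)], 3), collapse = ", "))
  if (anyNA(mqtl$snp_pos)) stop("missing SNP position")
  pairs <- data.frame(
    snp_id = mqtl$snp_id, cpg_id = mqtl$cpg_id,
    snp_chrom = normalize_chrom(mqtl$snp_chrom, warn = FALSE),
    snp_pos = mqtl$snp_pos,
    cpg_chrom = normalize_chrom(manifest$chrom[idx], warn = FALSE),
    cpg_pos = manifest$pos[idx], stringsAsFactors = FALSE)
  same_chrom <- pairs$snp_chrom == pairs$cpg_chrom
  pairs$distance_bp <- ifelse(same_chrom,
                              abs(pairs$snp_pos - pairs$cpg_pos), NA_real_)
  pairs$pair_class <- ifelse(same_chrom & pairs$distance_bp <= cis_window_bp,
                             "cis", "trans")
  pairs
}

#' Per-CpG mQTL summary
#'
#' Counts cis and trans partners for every CpG in the pair table and
#' assigns the CpG class: "cis", "trans", or "cis_and_trans" when both
#' partner kinds occur.  CpGs in `universe` without any pair are reported
#' as "none".
#'
#' @param pairs classified pair records from [classify_pairs()].
#' @param universe optional CpG ids to report even without pairs.
#' @return data.frame: cpg_id, n_cis_partners, n_trans_partners,
#'   cpg_class.
#' @export
summarize_cpg_mqtl <- function(pairs, universe = NULL) {
  ids <- unique(c(pairs$cpg_id, universe))
  n_cis <- table(factor(pairs$cpg_id[pairs$pair_class == "cis"], levels = ids))
  n_trans <- table(factor(pairs$cpg_id[pairs$pair_class == "trans"], levels = ids))
  cls <- ifelse(n_cis > 0 & n_trans > 0, "cis_and_trans",
                ifelse(n_cis > 0, "cis", ifelse(n_trans > 0, "trans", "none")))
  data.frame(cpg_id = ids, n_cis_partners = as.integer(n_cis),
             n_trans_partners = as.integer(n_trans),
             cpg_class = as.character(cls),
             row.names = NULL, stringsAsFactors = FALSE)
}

tad_index_of <- function(chrom, pos, tads) {
  gr <- positions_granges(chrom, pos)
  # disjoint seqlevels (cross-chromosome queries) are expected, not an error
  hits <- suppressWarnings(GenomicRanges::findOverlaps(gr, tads))
  idx <- rep(NA_integer_, length(gr))
  idx[S4Vectors::queryHits(hits)] <- S4Vectors::subjectHits(hits)
  idx
}

#' Same-TAD flag for SNP-CpG pairs
#'
#' TRUE iff one TAD interval contains both positions.  TAD BED intervals
#' are half-open: a 1-based position p lies in \[start0, end0) iff
#' start0 < p <= end0; a position exactly at the interval end is outside.
#' Overlapping TADs (within a chromosome) are rejected.
#'
#' @param pairs pair records from [classify_pairs()].
#' @param tads `GRanges` of TADs (from [read_intervals()]).
#' @return logical vector along the rows of `pairs`.
#' @export
same_tad <- function(pairs, tads) {
  self <- GenomicRanges::findOverlaps(tads, drop.self = TRUE,
                                      drop.redundant = TRUE)
  if (length(self) > 0) stop("TADs overlap within a chromosome")
  snp_tad <- tad_index_of(pairs$snp_chrom, pairs$snp_pos, tads)
  cpg_tad <- tad_index_of(pairs$cpg_chrom, pairs$cpg_pos, tads)
  !is.na(snp_tad) & !is.na(cpg_tad) & snp_tad == cpg_tad
}

#' Loop-connected flag for SNP-CpG pairs
#'
#' TRUE iff some chromatin loop has the SNP inside one anchor and the CpG
#' inside the other (either orientation).  Both positions inside the same
#' single anchor does not count.
#'
#' @param pairs pair records.
#' @param loops `methvar_loops` (from [read_intervals()]).
#' @return logical vector along the rows of `pairs`.
#' @export
loop_connected <- function(pairs, loops) {
  stopifnot(inherits(loops, "methvar_loops"))
  n_loop <- length(loops$anchor1)
  if (n_loop == 0L) return(rep(FALSE, nrow(pairs)))
  snp_gr <- positions_granges(pairs$snp_chrom, pairs$snp_pos)
  cpg_gr <- positions_granges(pairs$cpg_chrom, pairs$cpg_pos)
  in_anchor <- function(gr, anchor) {
    hits <- suppressWarnings(GenomicRanges::findOverlaps(gr, anchor))
    m <- matrix(FALSE, length(gr), n_loop)
    m[cbind(S4Vectors::queryHits(hits), S4Vectors::subjectHits(hits))] <- TRUE
    m
  }
  s1 <- in_anchor(snp_gr, loops$anchor1); s2 <- in_anchor(snp_gr, loops$anchor2)
  c1 <- in_anchor(cpg_gr, loops$anchor1); c2 <- in_anchor(cpg_gr, loops$anchor2)
  rowSums((s1 & c2) | (s2 & c1)) > 0
}

#' Annotate pairs with TAD and loop co-occupancy
#'
#' @param pairs pair records.
#' @param tads TAD `GRanges`.
#' @param loops `methvar_loops`.
#' @return `pairs` with logical columns `same_tad` and `loop_connected`.
#' @export
annotate_pairs <- function(pairs, tads, loops) {
  pairs$same_tad <- same_tad(pairs, tads)
  pairs$loop_connected <- loop_connected(pairs, loops)
  pairs
}

#' Co-occupancy enrichment of a pair set against a background pair set
#'
#' For each of the same-TAD and loop-connected flags: the fraction in the
#' set and in the background, log2 of their ratio, and the two-sided
#' Fisher p-value of the 2x2 contrast.  Background pairs that also occur
#' in the set (matched on snp_id + cpg_id) are excluded from the
#' background column.
#'
#' @param pairs_set annotated pair records (see [annotate_pairs()]).
#' @param pairs_background annotated background pair records.
#' @return data.frame with one row per flag.
#' @export
co_occupancy_enrichment <- function(pairs_set, pairs_background) {
  if (!nrow(pairs_set) || !nrow(pairs_background))
    stop("empty pair collection")
  key <- function(p) paste(p$snp_id, p$cpg_id)
  bg <- pairs_background[!key(pairs_background) %in% key(pairs_set), ,
                         drop = FALSE]
  rows <- lapply(c("same_tad", "loop_connected"), function(flag) {
    a <- sum(pairs_set[[flag]]); n1 <- nrow(pairs_set)
    b <- sum(bg[[flag]]); n2 <- nrow(bg)
    f1 <- a / n1; f2 <- b / n2
    p <- fisher.test(matrix(c(a, n1 - a, b, n2 - b), 2, byrow = TRUE))$p.value
    data.frame(flag = flag, n_set = n1, frac_set = f1,
               n_background = n2, frac_background = f2,
               log2_ratio = ifelse(a == 0L || b == 0L, NA_real_,
                                   log2(f1 / f2)),
               fisher_p = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
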