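# TADs (BED) and chromatin loops (BEDPE).  Files are 0-based half-open;
# internally everything is a 1-based GenomicRanges object, so a genomic
# position p (1-based) falls in BED interval [start, end) iff
# start + 1 <= p <= end in GRanges coordinates.  A position exactly at the
# BED end is outside.

#' Read genome intervals (TADs or loops)
#'
#' BED files (>= 3 columns) become a `GRanges`; BEDPE files (>= 6 columns)
#' become a list with class `methvar_loops` holding two parallel `GRanges`
#' anchors.  Intervals with start >= end are rejected; chromosome names are
#' normalised to the "chr" dialect (with a warning when the file mixes
#' dialects); loop anchors must share a chromosome.
#'
#' @param path BED or BEDPE file.
#' @param kind "bed" or "bedpe".
#' @return `GRanges` (bed) or `methvar_loops` (bedpe).
#' @export
read_intervals <- function(path, kind = c("bed", "bedpe")) {
  kind <- match.arg(kind)
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   comment.char = "#")
  if (kind == "bed") {
    if (ncol(df) < 3L) stop("BED needs >= 3 columns")
    bed_to_granges(df[[1]], df[[2]], df[[3]])
  } else {
    if (ncol(df) < 6L) stop("BEDPE needs >= 6 columns")
    a1 <- bed_to_granges(df[[1]], df[[2]], df[[3]])
    a2 <- bed_to_granges(df[[4]], df[[5]], df[[6]])
    if (any(as.character(GenomicRanges::seqnames(a1)) !=
            as.character(GenomicRanges::seqnames(a2))))
      stop("loop anchors must lie on the same chromosome")
    loops <- list(anchor1 = a1, anchor2 = a2)
    class(loops) <- "methvar_loops"
    loops
  }
}

bed_to_granges <- function(chrom, start0, end0) {
  start0 <- as.numeric(start0); end0 <- as.numeric(end0)
  bad <- which(start0 >= end0)
  if (length(bad))
    stop("interval start >= end at line ", bad[1], " (", chrom[bad[1]], ":",
         start0[bad[1]], "-", end0[bad[1]], ")")
  GenomicRanges::GRanges(normalize_chrom(chrom),
                         IRanges::IRanges(start = start0 + 1, end = end0))
}

granges_to_bed <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr))
}

#' Write genome intervals
#'
#' Inverse of [read_intervals()]: `GRanges` to BED, `methvar_loops` to
#' BEDPE (0-based half-open).
#'
#' @param x `GRanges` or `methvar_loops`.
#' @param path output path.
#' @export
write_intervals <- function(x, path) {
  if (inherits(x, "methvar_loops")) {
    df <- cbind(granges_to_bed(x$anchor1), granges_to_bed(x$anchor2))
  } else {
    df <- granges_to_bed(x)
  }
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# GRanges of width-1 loci at 1-based positions
positions_granges <- function(chrom, pos) {
  GenomicRanges::GRanges(normalize_chrom(chrom, warn = FALSE),
                         IRanges::IRanges(start = pos, width = 1L))
}
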