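# Readers and writers for every flat-file format the pipeline touches.
# Conventions: beta/expression/mQTL/result tables are TSV, manifest and
# sample sheet are CSV; manifest and mQTL coordinates are 1-based;
# chromosome names are normalised to the "chr" dialect on read.

ISLAND_LEVELS <- c("island", "shore", "shelf", "open_sea")
FEATURE_LEVELS <- c("exon", "intron", "5UTR", "3UTR", "promoter",
                    "enhancer", "intergenic", "TE")
CELL_TYPES <- c("CD8T", "CD4T", "NK", "B", "Mono", "Gran")

#' Normalise chromosome names to the "chr" dialect
#'
#' @param x character vector of chromosome names ("1" or "chr1").
#' @param warn warn when the input mixes dialects.
#' @return character vector with a "chr" prefix.
#' @export
normalize_chrom <- function(x, warn = TRUE) {
  x <- as.character(x)
  has <- startsWith(x, "chr")
  if (warn && any(has) && !all(has))
    warning("mixed chromosome naming; normalising to 'chr' prefix")
  ifelse(has, x, paste0("chr", x))
}

#' Read a probe-by-sample beta matrix
#'
#' Tab-separated, probe ids in the first column, sample ids in the header.
#' Values must lie in \[0, 1\]; empty cells or `NA` become missing values.
#' Violations are reported with the offending probe and sample.
#'
#' @param path TSV file.
#' @return numeric matrix (probes x samples) with dimnames.
#' @export
read_beta_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("beta matrix needs a probe id column and at least one sample")
  if (nrow(df) == 0L) stop("no probes in ", path)
  ids <- as.character(df[[1L]])
  mat <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- ids
  validate_beta_matrix(mat)
  mat
}

#' Validate a beta matrix
#'
#' Checks unique probe/sample ids and that all non-missing values lie in
#' \[0, 1\], naming the first offending cell otherwise.
#'
#' @param mat numeric matrix with probe rownames and sample colnames.
#' @param range allowed closed range (cell-corrected matrices may pass a
#'   wider one).
#' @return the matrix, invisibly.
#' @export
validate_beta_matrix <- function(mat, range = c(0, 1)) {
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop("beta matrix must carry probe and sample ids as dimnames")
  if (anyDuplicated(rownames(mat)))
    stop("duplicate probe ids: ",
         paste(unique(rownames(mat)[duplicated(rownames(mat))])[1:3], collapse = ", "))
  if (anyDuplicated(colnames(mat)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(mat)[duplicated(colnames(mat))])[1:3], collapse = ", "))
  bad <- which(!is.na(mat) & (mat < range[1] | mat > range[2]), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("beta value out of [%g, %g] at probe '%s', sample '%s' (value %g)",
                 range[1], range[2], rownames(mat)[bad[1, 1]],
                 colnames(mat)[bad[1, 2]], mat[bad[1, , drop = FALSE]]))
  }
  invisible(mat)
}

#' @rdname read_beta_matrix
#' @param mat matrix to write.
#' @param path output path.
#' @export
write_beta_matrix <- function(mat, path) {
  df <- data.frame(probe_id = rownames(mat), full_precision(mat),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# render doubles so they survive a write/read round trip bit-exactly
full_precision <- function(mat) {
  out <- matrix(sprintf("%.17g", mat), nrow(mat), dimnames = dimnames(mat))
  out[is.na(mat)] <- NA_character_
  out
}

#' Read / write the probe manifest
#'
#' CSV with columns probe_id, chrom, pos (1-based), island_relation
#' (island/shore/shelf/open_sea), features (semicolon-separated subset of
#' exon, intron, 5UTR, 3UTR, promoter, enhancer, intergenic, TE), gene
#' (empty allowed), and logical flags imprinted, non_cpg, on_450k.
#'
#' @param path CSV file.
#' @return data.frame with one row per probe.
#' @export
read_probe_manifest <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_probe_manifest(df)
}

#' @rdname read_probe_manifest
#' @param manifest manifest data.frame.
#' @export
validate_probe_manifest <- function(manifest) {
  need <- c("probe_id", "chrom", "pos", "island_relation", "features",
            "gene", "imprinted", "non_cpg", "on_450k")
  miss <- setdiff(need, names(manifest))
  if (length(miss)) stop("manifest lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(manifest$probe_id)) stop("duplicate probe ids in manifest")
  if (any(manifest$pos < 1L)) stop("manifest positions must be >= 1")
  bad <- setdiff(unique(manifest$island_relation), ISLAND_LEVELS)
  if (length(bad)) stop("unknown island_relation value(s): ", paste(bad, collapse = ", "))
  feats <- setdiff(unlist(strsplit(manifest$features[manifest$features != ""], ";")),
                   FEATURE_LEVELS)
  if (length(feats)) stop("unknown feature value(s): ", paste(feats, collapse = ", "))
  manifest$chrom <- normalize_chrom(manifest$chrom, warn = FALSE)
  for (fl in c("imprinted", "non_cpg", "on_450k"))
    manifest[[fl]] <- as.logical(manifest[[fl]])
  manifest
}

#' @rdname read_probe_manifest
#' @export
write_probe_manifest <- function(manifest, path) {
  write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write the sample sheet
#'
#' CSV with sample_id, cohort (discovery/validation), optional covariates
#' (sex, age, smoking) and the six Houseman cell-type proportions CD8T,
#' CD4T, NK, B, Mono, Gran, each in \[0, 1\] and summing to 1 within
#' `sum_tolerance`.
#'
#' @param path CSV file.
#' @param sum_tolerance allowed |sum - 1| for the six proportions.
#' @return data.frame with one row per sample.
#' @export
read_sample_sheet <- function(path, sum_tolerance = 0.05) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_sample_sheet(df, sum_tolerance)
}

#' @rdname read_sample_sheet
#' @param sheet sample sheet data.frame.
#' @export
validate_sample_sheet <- function(sheet, sum_tolerance = 0.05) {
  need <- c("sample_id", "cohort", CELL_TYPES)
  miss <- setdiff(need, names(sheet))
  if (length(miss)) stop("sample sheet lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(sheet$sample_id)) stop("duplicate sample ids in sheet")
  props <- as.matrix(sheet[, CELL_TYPES])
  if (any(props < 0 | props > 1)) stop("cell proportions must lie in [0, 1]")
  off <- abs(rowSums(props) - 1) > sum_tolerance
  if (any(off))
    stop("cell proportions do not sum to 1 (tolerance ", sum_tolerance,
         ") for sample(s): ", paste(head(sheet$sample_id[off], 3), collapse = ", "))
  sheet
}

#' @rdname read_sample_sheet
#' @export
write_sample_sheet <- function(sheet, path) {
  write.csv(sheet, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write an mQTL table
#'
#' TSV with snp_id, snp_chrom, snp_pos (1-based), cpg_id; (snp, cpg) pairs
#' must be unique.
#'
#' @param path TSV file.
#' @return data.frame of SNP-CpG records.
#' @export
read_mqtl_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("snp_id", "snp_chrom", "snp_pos", "cpg_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("mQTL table lacks columns: ", paste(miss, collapse = ", "))
  if (any(df$snp_pos < 1L)) stop("mQTL SNP positions must be >= 1")
  if (anyDuplicated(df[, c("snp_id", "cpg_id")]))
    stop("duplicate (snp_id, cpg_id) pairs in mQTL table")
  df$snp_chrom <- normalize_chrom(df$snp_chrom, warn = FALSE)
  df
}

#' @rdname read_mqtl_table
#' @param mqtl mQTL data.frame.
#' @export
write_mqtl_table <- function(mqtl, path) {
  write.table(mqtl, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a gene expression matrix
#'
#' TSV, gene ids in the first column, sample ids in the header; values must
#' be finite and non-negative.
#'
#' @param path TSV file.
#' @return numeric matrix (genes x samples).
#' @export
read_expression_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("no genes in ", path)
  mat <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- as.character(df[[1L]])
  if (anyDuplicated(rownames(mat))) stop("duplicate gene ids")
  if (any(!is.finite(mat))) stop("expression values must be finite")
  if (any(mat < 0)) stop("expression values must be non-negative")
  mat
}

#' @rdname read_expression_matrix
#' @param mat matrix to write.
#' @export
write_expression_matrix <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), full_precision(mat),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
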