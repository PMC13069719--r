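toy_manifest <- function() {
  data.frame(probe_id = c("cg1", "cg2", "cg3"),
             chrom = c("chr1", "chr1", "chr2"),
             pos = c(10000L, 20000L, 150L),
             island_relation = "open_sea", features = "intergenic",
             gene = "", imprinted = FALSE, non_cpg = FALSE, on_450k = TRUE,
             stringsAsFactors = FALSE)
}

test_that("cis/trans classification is exact at the window boundary", {
  mf <- toy_manifest()
  mq <- data.frame(snp_id = c("rs1", "rs2", "rs3"),
                   snp_chrom = c("chr1", "chr1", "chr1"),
                   snp_pos = c(10500L, 10501L, 99L),
                   cpg_id = c("cg1", "cg1", "cg3"),
                   stringsAsFactors = FALSE)
  pairs <- classify_pairs(mq, mf, cis_window_bp = 500L)
  expect_equal(pairs$pair_class, c("cis", "trans", "trans"))
  expect_equal(pairs$distance_bp, c(500, 501, NA))  # interchromosomal: NA
  expect_error(classify_pairs(
    data.frame(snp_id = "rsX", snp_chrom = "chr1", snp_pos = NA_integer_,
               cpg_id = "cg1"), mf), "missing SNP position")
  expect_error(classify_pairs(
    data.frame(snp_id = "rsX", snp_chrom = "chr1", snp_pos = 5L,
               cpg_id = "cgZ"), mf), "missing from manifest")
})

test_that("window monotonicity: a wider window never turns cis into trans", {
  b <- test_bundle()
  p500 <- classify_pairs(b$mqtl, b$manifest, 500L)
  p5000 <- classify_pairs(b$mqtl, b$manifest, 5000L)
  expect_true(all(p5000$pair_class[p500$pair_class == "cis"] == "cis"))
  expect_equal(sum(p500$pair_class %in% c("cis", "trans")), nrow(p500))
})

test_that("per-CpG summaries assign cis/trans/cis_and_trans/none", {
  pairs <- data.frame(
    snp_id = paste0("rs", 1:6),
    cpg_id = c("cgA", "cgA", "cgB", "cgC", "cgC", "cgC"),
    pair_class = c("cis", "trans", "cis", "trans", "trans", "trans"),
    stringsAsFactors = FALSE)
  s <- summarize_cpg_mqtl(pairs, universe = c("cgA", "cgB", "cgC", "cgD"))
  expect_equal(s$cpg_class[match(c("cgA", "cgB", "cgC", "cgD"), s$cpg_id)],
               c("cis_and_trans", "cis", "trans", "none"))
  expect_equal(s$n_trans_partners[s$cpg_id == "cgC"], 3L)
})

test_that("same_tad honours the half-open BED convention", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200", "chr1\t200\t300"), f)
  tads <- read_intervals(f, "bed")
  mk <- function(spos, cpos, schr = "chr1", cchr = "chr1")
    data.frame(snp_id = "rs", cpg_id = "cg", snp_chrom = schr,
               snp_pos = spos, cpg_chrom = cchr, cpg_pos = cpos,
               stringsAsFactors = FALSE)
  expect_true(same_tad(mk(150, 180), tads))     # both inside [100,200)
  expect_false(same_tad(mk(150, 201), tads))    # 201 is 0-based 200: excluded
  expect_true(same_tad(mk(201, 250), tads))     # both in the second TAD
  expect_false(same_tad(mk(150, 250), tads))    # different TADs
  expect_false(same_tad(mk(150, 150, cchr = "chr2"), tads))  # cross-chrom
  # a position exactly at a BED start (0-based) is outside the left TAD
  expect_false(same_tad(mk(150, 100), tads))
  # overlapping TADs are rejected
  writeLines(c("chr1\t100\t200", "chr1\t150\t300"), f)
  expect_error(same_tad(mk(150, 180), read_intervals(f, "bed")), "overlap")
})

test_that("loop connectivity requires opposite anchors", {
  f <- withr::local_tempfile(fileext = ".bedpe")
  writeLines("chr1\t100\t200\tchr1\t1000\t1100", f)
  loops <- read_intervals(f, "bedpe")
  mk <- function(spos, cpos)
    data.frame(snp_id = "rs", cpg_id = "cg", snp_chrom = "chr1",
               snp_pos = spos, cpg_chrom = "chr1", cpg_pos = cpos,
               stringsAsFactors = FALSE)
  expect_true(loop_connected(mk(150, 1050), loops))   # A then B
  expect_true(loop_connected(mk(1050, 150), loops))   # B then A
  expect_false(loop_connected(mk(150, 180), loops))   # both in anchor A
  expect_false(loop_connected(mk(5000, 6000), loops)) # in no anchor
})

test_that("co-occupancy enrichment agrees with the shared Fisher oracle", {
  set.seed(12)
  mk_pairs <- function(n, tad_rate, tag) {
    data.frame(snp_id = paste0(tag, seq_len(n)), cpg_id = paste0("c", tag, seq_len(n)),
               same_tad = runif(n) < tad_rate,
               loop_connected = runif(n) < 0.05, stringsAsFactors = FALSE)
  }
  st <- mk_pairs(200, 0.9, "s")
  bg <- rbind(st, mk_pairs(400, 0.5, "b"))
  enr <- co_occupancy_enrichment(st, bg)
  row <- enr[enr$flag == "same_tad", ]
  a <- sum(st$same_tad); b_ <- sum(!st$same_tad)
  bgo <- bg[!paste(bg$snp_id, bg$cpg_id) %in% paste(st$snp_id, st$cpg_id), ]
  cc <- sum(bgo$same_tad); d <- sum(!bgo$same_tad)
  m <- a + cc; n_ <- b_ + d; k <- a + b_
  support <- max(0, k - n_):min(k, m)
  probs <- dhyper(support, m, n_, k)
  oracle_p <- sum(probs[probs <= dhyper(a, m, n_, k) * (1 + 1e-7)])
  expect_equal(row$fisher_p, oracle_p, tolerance = 1e-12)
  expect_lt(row$fisher_p, 0.001)       # planted 90% vs 50% at n >= 200
  expect_equal(row$frac_set, mean(st$same_tad))
  # equal fractions with large counts: p near 1, ratio ~ 0
  same <- mk_pairs(400, 0.6, "x")
  bg2 <- rbind(same, mk_pairs(400, 0.6, "y"))
  enr2 <- co_occupancy_enrichment(same, bg2)
  expect_gt(enr2$fisher_p[enr2$flag == "same_tad"], 0.05)
  expect_error(co_occupancy_enrichment(st[0, ], bg), "empty")
})

test_that("planted same-TAD share is recovered within the binomial CI", {
  b <- test_bundle()
  pairs <- classify_pairs(b$mqtl, b$manifest, 500L)
  pairs <- annotate_pairs(pairs, b$tads, b$loops)
  trans <- pairs[pairs$pair_class == "trans" &
                   pairs$snp_chrom == pairs$cpg_chrom, ]
  phat <- mean(trans$same_tad)
  n <- nrow(trans)
  ci <- phat + c(-1.96, 1.96) * sqrt(phat * (1 - phat) / n)
  expect_gte(b$design$trans_tad_share, ci[1])
  expect_lte(b$design$trans_tad_share, ci[2])
  # interchromosomal pairs can never share a TAD
  cross <- pairs[pairs$snp_chrom != pairs$cpg_chrom, ]
  expect_true(all(!cross$same_tad))
  # loop-connected implies opposite anchors exist: planted loops recovered
  expect_gt(sum(trans$loop_connected), 0)
})
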