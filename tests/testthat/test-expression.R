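test_that("expression CV matches closed forms and a brute-force oracle", {
  m <- rbind(gConst = rep(3, 4), gPair = c(1, 3, 1, 3))
  colnames(m) <- paste0("s", 1:4)
  cvs <- expression_cv(m)
  expect_equal(cvs[["gConst"]], 0)
  expect_equal(expression_cv(rbind(g = c(1, 3)))[["g"]], sqrt(2) / 2,
               tolerance = 1e-12)
  set.seed(15)
  big <- matrix(rlnorm(200), 20, 10,
                dimnames = list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:10)))
  oracle <- apply(big, 1, function(r) sd(r) / mean(r))
  expect_equal(expression_cv(big), oracle, tolerance = 1e-12,
               ignore_attr = TRUE)
  zero <- matrix(0, 2, 3, dimnames = list(c("a", "b"), c("x", "y", "z")))
  expect_error(expression_cv(zero), "positive mean")
})

test_that("probe-to-gene mapping applies the stated rules", {
  mf <- data.frame(probe_id = c("cg1", "cg2", "cg3"),
                   chrom = "chr1", pos = 1:3,
                   island_relation = "island",
                   features = c("5UTR;promoter", "exon", "intron"),
                   gene = c("TACSTD2", "", "A;B"),
                   imprinted = FALSE, non_cpg = FALSE, on_450k = TRUE,
                   stringsAsFactors = FALSE)
  mp <- map_probe_to_gene(c("cg1", "cg2", "cg3"), mf)
  expect_equal(attr(mp, "n_dropped"), 1L)          # empty gene dropped
  expect_false("cg2" %in% mp$probe_id)
  expect_equal(unique(mp$gene[mp$probe_id == "cg3"]), "A")  # first listed
  expect_setequal(mp$feature[mp$probe_id == "cg1"], c("5UTR", "promoter"))
})

test_that("variation mode recovers exact and planted couplings", {
  b <- test_bundle()
  # constructed pairs with CV exactly linear in SD -> r = 1
  sds <- probe_sd(b$betas_discovery)
  probes <- names(sds)[1:50]
  genes <- b$truth$gene[match(probes, b$truth$probe_id)]
  fake_expr <- matrix(1, length(genes), 10,
                      dimnames = list(genes, paste0("x", 1:10)))
  # build expression rows whose CV is exactly 2 * SD of the probe
  base <- seq(-1, 1, length.out = 10); base <- base / sd(base)
  for (i in seq_along(genes)) {
    cv <- 2 * sds[probes[i]]
    fake_expr[i, ] <- 100 * (1 + cv * base)
  }
  out <- correlate_variation(probes, b$betas_discovery, fake_expr, b$manifest)
  expect_equal(out$pearson_r[out$feature == "(all)"], 1, tolerance = 1e-9)

  # degenerate: constant SD across pairs -> undefined r
  const <- matrix(0.5, 5, 8,
                  dimnames = list(names(sds)[1:5], paste0("s", 1:8)))
  out2 <- correlate_variation(names(sds)[1:5], const,
                              fake_expr, b$manifest)
  expect_true(is.na(out2$pearson_r[out2$feature == "(all)"]))
})

test_that("planted SD-CV coupling is recovered near rho = 0.6", {
  b <- cached("bundle_coupling", simulate_bundle(simulation_design(
    n_probes = 800L, n_samples_discovery = 150L, n_samples_validation = 10L,
    rng_seed = 21L)))
  plain <- b$truth$probe_id[!(b$truth$class == "epiallele_bimodal" &
                                grepl("(^|;)5UTR(;|$)", b$manifest$features))]
  set.seed(30)
  probes <- sample(plain, 300)
  out <- correlate_variation(probes, b$betas_discovery, b$expression,
                             b$manifest)
  r <- out$pearson_r[out$feature == "(all)"]
  n <- out$n_pairs[out$feature == "(all)"]
  # Fisher CI around the target
  ci <- tanh(atanh(0.6) + c(-1.96, 1.96) / sqrt(n - 3))
  expect_gte(r, ci[1] - 0.05)
  expect_lte(r, ci[2] + 0.05)
})

test_that("matched mode: exact negative linear dependence gives r = -1", {
  b <- test_bundle()
  probes <- b$truth$probe_id[1:5]
  genes <- b$truth$gene[1:5]
  expr <- matrix(0, 5, ncol(b$betas_discovery),
                 dimnames = list(genes, colnames(b$betas_discovery)))
  for (i in 1:5) expr[i, ] <- 10 - 4 * b$betas_discovery[probes[i], ]
  out <- correlate_levels(probes, b$betas_discovery, expr, b$manifest)
  expect_true(all(abs(out$pairs$pearson_r + 1) < 1e-9))
  expect_error(correlate_levels(probes, b$betas_discovery,
                                expr[, 1:2], b$manifest), "shared samples")
})

test_that("matched mode isolates the planted negative 5'UTR coupling", {
  b <- test_bundle()
  epi_5utr <- b$truth$class == "epiallele_bimodal" &
    grepl("(^|;)5UTR(;|$)", b$manifest$features)
  expect_gte(sum(epi_5utr), 3)  # deterministic under the fixture seed
  probes <- b$truth$probe_id[b$truth$class %in%
                               c("epiallele_bimodal", "variable_unimodal")]
  out <- correlate_levels(probes, b$betas_discovery, b$expression, b$manifest)
  g5 <- out$groups[out$groups$feature == "5UTR", ]
  others <- out$groups[!out$groups$feature %in% c("5UTR", "(none)"), ]
  expect_lt(g5$mean_r, -0.5)
  expect_lt(max(abs(others$mean_r)), 0.2)
})

test_that("unmatched mode ignores sample order; matched mode needs joint order only", {
  b <- test_bundle()
  probes <- b$truth$probe_id[b$truth$class == "variable_unimodal"][1:30]
  r1 <- correlate_variation(probes, b$betas_discovery, b$expression,
                            b$manifest)
  perm <- sample(ncol(b$betas_discovery))
  r2 <- correlate_variation(probes, b$betas_discovery[, perm],
                            b$expression, b$manifest)
  expect_equal(r1, r2)
  l1 <- correlate_levels(probes, b$betas_discovery, b$expression, b$manifest)
  l2 <- correlate_levels(probes, b$betas_discovery[, perm],
                         b$expression, b$manifest)
  expect_equal(l1$pairs$pearson_r, l2$pairs$pearson_r, tolerance = 1e-12)
})
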