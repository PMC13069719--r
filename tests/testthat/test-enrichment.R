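test_that("log2 observed/expected follows its closed forms", {
  bg <- sprintf("p%03d", 1:100)
  ann <- bg[1:10]                       # background fraction 0.1
  set_eq <- c(bg[1:2], bg[11:28])       # set fraction 0.1 -> ratio 0
  r <- log2_obs_exp(set_eq, bg, ann)
  expect_equal(r$log2_ratio, 0)
  set_2x <- c(bg[1:4], bg[11:26])       # set fraction 0.2 -> log2(2) = 1
  expect_equal(log2_obs_exp(set_2x, bg, ann)$log2_ratio, 1)
  r0 <- log2_obs_exp(bg[31:40], bg, ann)
  expect_true(r0$undefined)
  expect_true(is.na(r0$log2_ratio))
  expect_error(log2_obs_exp(character(0), bg, ann), "empty")
  expect_error(log2_obs_exp("q999", bg, ann), "subset")
})

test_that("fisher_enrichment matches hypergeometric enumeration exactly", {
  # balanced table: p = 1
  expect_equal(fisher_enrichment(1, 2, 2, 4), 1)
  # [[5,0],[0,5]]: p = 2/choose(10,5)
  expect_equal(fisher_enrichment(5, 5, 5, 10), 2 / choose(10, 5),
               tolerance = 1e-12)
  set.seed(9)
  for (i in 1:300) {
    a <- sample(0:20, 1); b <- sample(0:20, 1)
    cc <- sample(0:20, 1); d <- sample(0:20, 1)
    if (a + b == 0 || cc + d == 0 || a + cc == 0 || b + d == 0) next
    p_pkg <- fisher_enrichment(a, a + b, a + cc, a + b + cc + d)
    expect_equal(p_pkg, fisher_oracle(a, b, cc, d), tolerance = 1e-12)
  }
})

test_that("the Fisher p is symmetric under transposing the 2x2 table", {
  set.seed(10)
  for (i in 1:50) {
    a <- sample(0:15, 1); b <- sample(1:15, 1)
    cc <- sample(1:15, 1); d <- sample(1:15, 1)
    p1 <- fisher_oracle(a, b, cc, d)
    p2 <- fisher_oracle(a, cc, b, d)   # transpose
    expect_equal(p1, p2, tolerance = 1e-12)
  }
  expect_error(fisher_enrichment(5, 4, 10, 100), "negative cell")
})

test_that("permutation p-values respect their structural bounds", {
  bg <- sprintf("p%03d", 1:200)
  ann <- bg[1:20]
  # observed overlap 0: every draw ties or exceeds -> p = 1
  r <- permutation_enrichment(bg[21:30], bg, ann, n_reps = 200, rng_seed = 1)
  expect_equal(r$perm_p, 1)
  # set = exactly the annotated probes, annotation rare -> minimal p
  r2 <- permutation_enrichment(ann, bg, ann, n_reps = 200, rng_seed = 1)
  expect_equal(r2$perm_p, 1 / 201)
  # bounds hold for arbitrary sets
  set.seed(2)
  for (i in 1:20) {
    s <- sample(bg, 30)
    p <- permutation_enrichment(s, bg, ann, n_reps = 99, rng_seed = i)$perm_p
    expect_gte(p, 1 / 100)
    expect_lte(p, 1)
  }
  expect_error(permutation_enrichment(bg[1:5], bg, ann, n_reps = 0), "n_reps")
})

test_that("null permutation p-values are approximately uniform", {
  # configuration chosen so the overlap statistic has wide support (its
  # discreteness would otherwise dominate the KS distance)
  bg <- sprintf("p%04d", 1:5000)
  ann <- bg[1:2000]
  set.seed(3)
  pvals <- vapply(1:500, function(i) {
    s <- sample(bg, 400)   # a null "observed" set
    permutation_enrichment(s, bg, ann, n_reps = 999,
                           rng_seed = 1000 + i)$perm_p
  }, numeric(1))
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("partitioning annotations conserve counts in enrichment tables", {
  b <- test_bundle()
  catal <- test_catalog()
  vmps <- vmp_ids(catal)
  tab <- enrichment_table(vmps, b$manifest,
                          annotations = c("island", "shore", "shelf",
                                          "open_sea"))
  expect_equal(sum(tab$n_in_set), length(vmps))
  expect_equal(sum(tab$n_in_background), nrow(b$manifest))
  expect_true(all(tab$n_in_set <= tab$n_set))
})

test_that("planted shore/enhancer bias surfaces as top VMP enrichment", {
  b <- test_bundle()
  catal <- test_catalog()
  tab <- enrichment_table(vmp_ids(catal), b$manifest,
                          annotations = c("island", "shore", "shelf",
                                          "open_sea", "enhancer",
                                          "promoter", "exon"))
  shore <- tab$log2_ratio[tab$annotation == "shore"]
  enh <- tab$log2_ratio[tab$annotation == "enhancer"]
  island <- tab$log2_ratio[tab$annotation == "island"]
  expect_gt(shore, 0)
  expect_gt(enh, 0)
  expect_gt(shore, island)
})

test_that("housekeeping labels match a brute-force percentile check", {
  set.seed(6)
  expr <- matrix(rlnorm(10 * 3), 10, 3,
                 dimnames = list(sprintf("g%02d", 1:10), c("t1", "t2", "t3")))
  labels <- label_housekeeping(expr, top_fraction = 0.40)
  for (g in rownames(expr)) {
    ok <- all(vapply(1:3, function(j)
      rank(expr[, j], ties.method = "average")[g] / 10 >= 0.6, logical(1)))
    expect_equal(unname(labels[g]),
                 if (ok) "housekeeping" else "tissue_specific")
  }
  # top-10% everywhere -> housekeeping; bottom-half in one tissue kills it
  expr2 <- expr
  expr2["g01", ] <- apply(expr, 2, max) * 1.1
  expect_equal(unname(label_housekeeping(expr2)["g01"]), "housekeeping")
  expr2["g01", 2] <- min(expr[, 2]) * 0.5
  expect_equal(unname(label_housekeeping(expr2)["g01"]), "tissue_specific")
})

test_that("a constant tissue column passes every gene for that tissue", {
  expr <- cbind(t1 = c(5, 5, 5, 5), t2 = c(1, 2, 3, 4))
  rownames(expr) <- paste0("g", 1:4)
  labels <- label_housekeeping(expr, top_fraction = 0.40)
  # only t2 discriminates: its top 40% (ranks >= 0.6) are g3, g4
  expect_equal(unname(labels), c("tissue_specific", "tissue_specific",
                                 "housekeeping", "housekeeping"))
  expect_error(label_housekeeping(expr[, 1, drop = FALSE]), "two tissues")
})
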