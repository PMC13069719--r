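test_that("probe_sd matches closed forms and a brute-force oracle", {
  m <- rbind(cgA = c(0.5, 0.5, 0.5), cgB = c(0, 1, NA))
  colnames(m) <- paste0("s", 1:3)
  sds <- probe_sd(m)
  expect_equal(sds[["cgA"]], 0)
  expect_equal(sds[["cgB"]], sqrt(0.5), tolerance = 1e-6)

  set.seed(5)
  big <- matrix(runif(100 * 50), 100,
                dimnames = list(sprintf("p%03d", 1:100), sprintf("s%02d", 1:50)))
  big[sample(length(big), 40)] <- NA
  oracle <- apply(big, 1, sd, na.rm = TRUE)   # independent two-pass per row
  expect_equal(probe_sd(big), oracle, tolerance = 1e-12)

  m2 <- rbind(cgA = c(0.2, NA, NA))
  colnames(m2) <- paste0("s", 1:3)
  expect_error(probe_sd(m2), "cgA")
})

test_that("a single run returns exactly the floor(q P) extreme-SD probes", {
  set.seed(8)
  P <- 100
  mu <- runif(P, 0.3, 0.7)
  noise <- seq(0.005, 0.2, length.out = P)       # strictly distinct SD scale
  m <- t(vapply(seq_len(P), function(i) pmin(pmax(
    rnorm(60, mu[i], noise[i]), 0), 1), numeric(60)))
  dimnames(m) <- list(sprintf("p%03d", seq_len(P)), sprintf("s%02d", 1:60))
  run <- call_single_run(m, drop_fraction = 0, q = 0.10, rng_seed = 1)
  sds <- probe_sd(m)
  expect_setequal(run$vmp, names(sort(sds, decreasing = TRUE))[1:10])
  expect_setequal(run$smp, names(sort(sds))[1:10])
  expect_length(run$vmp, floor(0.10 * P))
  expect_length(run$smp, floor(0.10 * P))
  expect_length(intersect(run$vmp, run$smp), 0L)
})

test_that("ties at the decile cut are broken lexicographically", {
  # two probes with *identical* values hence identical SDs at ranks 1-2
  base <- c(0.2, 0.4, 0.6, 0.8)
  m <- rbind(cgZ = base, cgA = base,
             cgM = c(0.45, 0.5, 0.5, 0.55),
             cgN = c(0.48, 0.5, 0.5, 0.52))
  colnames(m) <- paste0("s", 1:4)
  run <- call_single_run(m, drop_fraction = 0, q = 0.25, rng_seed = 1)
  expect_identical(run$vmp, "cgA")   # lexicographically before cgZ
  run2 <- call_single_run(m[c(4, 3, 2, 1), ], 0, 0.25, 1)
  expect_identical(run2$vmp, "cgA")  # row order irrelevant
})

test_that("too few probes for the decile is an error", {
  m <- toy_betas(3, 6)
  expect_error(call_single_run(m, 0.1, 0.1, 1), "too few probes")
})

test_that("downsampling draws are keyed to sample ids, not column order", {
  m <- toy_betas(20, 30, seed = 2)
  r1 <- call_single_run(m, 0.2, 0.2, rng_seed = 42)
  perm <- sample(ncol(m))
  r2 <- call_single_run(m[, perm], 0.2, 0.2, rng_seed = 42)
  expect_identical(r1$dropped, r2$dropped)
  expect_identical(r1$vmp, r2$vmp)
  expect_identical(r1$smp, r2$smp)
})

test_that("catalogue reduces to a single run when repeats=1 and no drop", {
  b <- test_bundle()
  cfg <- methvar_config(n_repeats = 1L, drop_fraction = 0, rng_seed = 7L)
  cat1 <- call_catalog(b$betas_discovery, b$betas_validation, cfg)
  runD <- call_single_run(b$betas_discovery, 0, cfg$decile_fraction,
                          cfg$rng_seed + 1L)
  runV <- call_single_run(b$betas_validation, 0, cfg$decile_fraction,
                          cfg$rng_seed + cfg$n_repeats + 1L)
  expect_setequal(vmp_ids(cat1), intersect(runD$vmp, runV$vmp))
  expect_setequal(smp_ids(cat1), intersect(runD$smp, runV$smp))
})

test_that("final sets are subsets of every per-repeat set, disjoint", {
  catal <- test_catalog()
  vmps <- vmp_ids(catal); smps <- smp_ids(catal)
  expect_length(intersect(vmps, smps), 0L)
  for (runs in list(attr(catal, "runs_discovery"),
                    attr(catal, "runs_validation"))) {
    for (r in runs) {
      expect_true(all(vmps %in% r$vmp))
      expect_true(all(smps %in% r$smp))
    }
  }
  # per-run membership counts are consistent with the calls
  expect_true(all(catal$runs_vmp_discovery[catal$call == "VMP"] ==
                    attr(catal, "config")$n_repeats))
})

test_that("cohort probe mismatch reports the symmetric difference size", {
  b <- test_bundle()
  expect_error(
    call_catalog(b$betas_discovery[-(1:3), ], b$betas_validation,
                 methvar_config()),
    "symmetric difference of size 3")
})

test_that("probes exceeding the missingness threshold are dropped with NA calls", {
  b <- test_bundle()
  bd <- b$betas_discovery
  bd[1, seq_len(ceiling(0.2 * ncol(bd)))] <- NA
  catal <- call_catalog(bd, b$betas_validation, methvar_config(rng_seed = 7L))
  expect_true(is.na(catal$call[catal$probe_id == rownames(bd)[1]]))
  expect_equal(nrow(catal), nrow(bd))
})

test_that("overlap_report matches brute-force membership enumeration", {
  catal <- test_catalog()
  vmps <- vmp_ids(catal)
  set.seed(33)
  lists <- list(A = sample(catal$probe_id, 150),
                B = sample(catal$probe_id, 80),
                C = character(0))
  rep_ <- overlap_report(catal, lists)
  # brute force: every VMP lands in exactly one exclusive cell
  expect_equal(sum(rep_$exclusive$n_vmp), length(vmps))
  key <- vapply(vmps, function(p) {
    k <- paste(ifelse(c(p %in% lists$A, p %in% lists$B, p %in% lists$C),
                      c("A", "B", "C"), ""), collapse = "")
    if (k == "") "(none)" else k
  }, character(1))
  brute <- table(key)
  for (nm in names(brute))
    expect_equal(rep_$exclusive$n_vmp[rep_$exclusive$combination == nm],
                 as.integer(brute[[nm]]))
  # pairwise intersections against brute force
  expect_equal(rep_$pairwise["VMP", "A"], length(intersect(vmps, lists$A)))
  expect_equal(rep_$pairwise["A", "B"],
               length(intersect(lists$A, lists$B)))
  # a list equal to the VMP set occupies a single exclusive cell
  rep2 <- overlap_report(catal, list(self = vmps))
  expect_equal(rep2$exclusive$n_vmp[rep2$exclusive$combination == "self"],
               length(vmps))
})

test_that("disjoint covering lists partition the VMP set", {
  catal <- test_catalog()
  vmps <- vmp_ids(catal)
  half <- seq_len(floor(length(vmps) / 2))
  lists <- list(L1 = vmps[half], L2 = setdiff(vmps, vmps[half]))
  rep_ <- overlap_report(catal, lists)
  expect_setequal(rep_$exclusive$combination, c("L1", "L2"))
  expect_equal(sum(rep_$exclusive$n_vmp), length(vmps))
})
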