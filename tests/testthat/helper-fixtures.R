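# Shared fixtures, built once per test session and cached in the process.

.methvar_cache <- local({
  if (!exists(".methvar_test_cache", envir = globalenv()))
    assign(".methvar_test_cache", new.env(parent = emptyenv()),
           envir = globalenv())
  get(".methvar_test_cache", envir = globalenv())
})

cached <- function(key, expr) {
  if (!exists(key, envir = .methvar_cache))
    assign(key, expr, envir = .methvar_cache)
  get(key, envir = .methvar_cache)
}

# moderate bundle shared by most module tests
test_bundle <- function() {
  cached("bundle", simulate_bundle(simulation_design(
    n_probes = 600L, n_samples_discovery = 120L,
    n_samples_validation = 120L, rng_seed = 7L)))
}

test_catalog <- function() {
  cached("catalog", {
    b <- test_bundle()
    call_catalog(b$betas_discovery, b$betas_validation,
                 methvar_config(rng_seed = 7L))
  })
}

# tiny deterministic beta matrix
toy_betas <- function(nprobe = 8, nsamp = 10, seed = 1) {
  set.seed(seed)
  m <- matrix(runif(nprobe * nsamp), nprobe,
              dimnames = list(sprintf("cg%03d", seq_len(nprobe)),
                              sprintf("S%02d", seq_len(nsamp))))
  m
}

# betas with known cell-proportion structure: one exactly linear probe, one
# pure-noise probe, one mixed
make_cell_fixture <- function(n = 80, seed = 4) {
  set.seed(seed)
  props <- matrix(rgamma(n * 6, shape = rep(c(9, 17, 5, 6, 8, 55), each = n)),
                  n, 6, dimnames = list(NULL, c("CD8T", "CD4T", "NK", "B",
                                                "Mono", "Gran")))
  props <- props / rowSums(props)
  sheet <- data.frame(sample_id = sprintf("s%03d", seq_len(n)),
                      cohort = "discovery", props,
                      stringsAsFactors = FALSE)
  exact <- 0.2 + 0.6 * props[, "CD4T"]              # exact linear in CD4T
  noise <- pmin(pmax(rnorm(n, 0.5, 0.05), 0), 1)    # independent of cells
  betas <- rbind(exact = exact, noise = noise,
                 mixed = pmin(pmax(0.1 + 0.8 * props[, "Gran"] +
                                     rnorm(n, 0, 0.02), 0), 1))
  colnames(betas) <- sheet$sample_id
  list(betas = betas, sheet = sheet)
}

# one full pipeline run on the shared bundle, cached for reuse
pipeline_fixture <- function() {
  cached("pipeline_run", {
    b <- test_bundle()
    dir <- file.path(tempdir(), "methvar_bundle")
    paths <- write_bundle(b, dir)
    cfg <- methvar_config(rng_seed = 7L, dip_mc_reps = 300L,
                          permutation_reps = 300L)
    out1 <- file.path(tempdir(), "methvar_out1")
    res <- run_pipeline(cfg, as.list(paths), out1)
    list(bundle = b, paths = paths, cfg = cfg, out = out1, res = res)
  })
}
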