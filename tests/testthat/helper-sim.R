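# Shared fixtures, built once per test run. The default world (seed 7) is
# the generator's stated configuration; heavy derived objects are memoized.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

default_sim <- function(seed = 7) {
  memo(paste0("sim_", seed), simulate_swissroll(spiral_spec(seed = seed)))
}

default_norm <- function(seed = 7) {
  memo(paste0("norm_", seed), normalize_counts(default_sim(seed)$ds))
}

default_model <- function(seed = 7) {
  memo(paste0("model_", seed), run_nnmf(default_norm(seed), K = 6, seed = 1))
}

# small-but-complete config for pipeline tests
small_config <- function(out_dir, seed = 3L) {
  cfg <- default_config(out_dir, seed)
  cfg$simulate$turns <- 2
  cfg$simulate$spot_step <- 6
  cfg$simulate$jitter <- 1.5
  cfg$simulate$n_genes <- 700
  cfg$enrichment$n_perm <- 100
  cfg$figures$enabled <- FALSE
  cfg
}
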