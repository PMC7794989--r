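# Shared simulation runs for the heavier tests. Each run is computed once
# per session and reused across test files (test_dir runs files in one
# process, so the cache persists).

.run_cache <- new.env(parent = emptyenv())

cached_run <- function(key, expr) {
  if (is.null(.run_cache[[key]])) .run_cache[[key]] <- force(expr)
  .run_cache[[key]]
}

# Reference study conditions at reduced scale: 5 replicates of
# 1,000 models x 100 initial conditions on the base circuit.
base_desk_analysis <- function() {
  cached_run("base_desk", {
    run_full_analysis(run_config("base", n_models = 1000, n_inits = 100,
                                 n_replicates = 5, seed = 1))
  })
}

# Scaled-down perturbation sweeps of the PSF circuits (2 replicates of
# 500 models x 60 initial conditions per fold).
psf_sweep_small <- function(circ) {
  node <- c(grhl2 = "GRHL2", grhl2_kd = "GRHL2", ovol = "OVOL",
            nrf2 = "NRF2")[[circ]]
  cached_run(paste0("sweep_", circ), {
    cfg <- run_config(circ, n_models = 500, n_inits = 60, n_replicates = 2,
                      seed = 5)
    perturbation_sweep(cfg, node, folds = c(0.1, 1, 10))
  })
}

uncoupled_analysis <- function() {
  cached_run("uncoupled", {
    run_full_analysis(run_config("uncoupled", n_models = 800, n_inits = 60,
                                 n_replicates = 1, seed = 3))
  })
}

hybrid_sum <- function(summary, col) {
  sum(summary[[col]][summary$phenotype %in% c("he", "hm")])
}

nonhybrid_sum <- function(summary, col) {
  sum(summary[[col]][summary$phenotype %in% c("e", "m")])
}
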