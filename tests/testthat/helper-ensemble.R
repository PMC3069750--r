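# The paired synthetic ensemble used by the ensemble-level acceptance
# checks (and nothing else). Cached so the two test blocks that share it
# only pay for it once per run.
acceptance_ensemble <- function() {
  if (is.null(.fixture_cache$ensemble))
    .fixture_cache$ensemble <- run_bias_experiment(
      seq(0.5, 3, length.out = 20), dm_options(n_cycles = 20), seed = 101)
  .fixture_cache$ensemble
}

# three high-quality data sets (kappa = 5, initial CPEM ~ 0.89) with
# beta-corrected production runs, for the map-stability check
high_quality_runs <- function() {
  if (is.null(.fixture_cache$hq)) {
    .fixture_cache$hq <- lapply(c(101, 202, 303), function(s) {
      ds <- simulate_toy_dataset(5, seed = s)
      tr <- run_beta_corrected_dm(ds$refl, ds$phases, dm_options(n_cycles = 20))
      list(initial_cpem = phase_error_stats(ds$phases, ds$refl$phi_true)$cpem,
           initial_cc = attr(tr, "initial_map_cc"),
           final_cc = tr$map_cc[nrow(tr)])
    })
  }
  .fixture_cache$hq
}
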