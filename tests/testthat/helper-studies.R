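# Shared simulated-study cache so multi-seed acceptance checks do not
# re-run the pipeline per test block. Keyed by (seed, frac, size preset).

.study_cache <- new.env(parent = emptyenv())

small_config <- function(seed, frac = 1, n_causal = 25) {
  sim_config(
    n_samples = 150, n_snps = 1000, n_events = 100, chrom_length = 1e7,
    ld_block_size = 10, within_block_rho = 0.8, maf_range = c(0.05, 0.5),
    n_causal = n_causal, causal_maf_min = 0.2, effect_size_psi = 8,
    noise_sd = 5, frac_causal_in_gwas_loci = frac,
    n_null_loci = 3, seed = seed
  )
}

cached_study <- function(seed, frac = 1, n_causal = 25) {
  key <- sprintf("s%d_f%s_c%d", seed, format(frac), n_causal)
  if (!exists(key, envir = .study_cache)) {
    st <- suppressWarnings(
      run_sqtl_study(small_config(seed, frac, n_causal)))
    assign(key, st, envir = .study_cache)
  }
  get(key, envir = .study_cache)
}

# scan-only run (no sets/enrichment/triage), used for null-calibration
null_scan <- function(seed, n_snps = 2000, n_events = 200, n_samples = 200) {
  cfg <- sim_config(n_samples = n_samples, n_snps = n_snps,
                    n_events = n_events, n_causal = 0,
                    frac_causal_in_gwas_loci = 0, seed = seed)
  sim <- list(
    genotypes = simulate_genotypes(cfg),
    covariates = simulate_covariates(cfg)
  )
  ps <- simulate_psi(cfg, sim$genotypes, sim$covariates)
  psi_f <- filter_as_events(ps$psi)
  geno_f <- filter_snps(sim$genotypes, psi_f)
  sqtl_scan(geno_f, psi_f, sim$covariates)
}
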