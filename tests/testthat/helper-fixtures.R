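# Fixtures are built in code; nothing is read from disk unless a test writes
# it first.

# Observations lying exactly on the Beer-Lambert curve.
noiseless_dataset <- function(k = c(A = 0.5), lai = seq(0.4, 7.5, length.out = 20)) {
  genotype <- rep(names(k), each = length(lai))
  lai_all <- rep(lai, times = length(k))
  fpari <- beer_lambert_mean(rep(k, each = length(lai)), lai_all)
  canopy_dataset(genotype, lai_all, fpari)
}

# Small beta-noise dataset with a single genotype.
toy_beta_dataset <- function(n = 30, k = 0.5, kappa = 12, seed = 101) {
  simulate_dataset(synthetic_config(true_k = c(A = k), true_dispersion = kappa,
                                    n_per_genotype = n, seed = seed))
}

# Faster optimizer settings for tests that fit many replicates; the start
# range stays at the documented (0.2, 0.8).
quick_optimizer <- function(seed = 1L, n_starts = 3L) {
  optimizer_config(n_starts = n_starts, seed = seed)
}

write_fixture_csv <- function(dir = withr::local_tempdir(), d = toy_beta_dataset()) {
  path <- file.path(dir, "data.csv")
  write_canopy_table(d, path)
  path
}
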