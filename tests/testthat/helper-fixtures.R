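# Shared fixtures, built in code once per test run.

# A small planted-hub cohort used across discovery/validation tests.
small_cohort <- function(rng_seed = 101L) {
  generate_cohort(cohort_params(
    n_samples = 200, n_genes = 400, n_partners = 10,
    rho_high = 0.5, rho_low = 0.05, beta = 1.0,
    censor_frac = 0.3, frac_signaling = 0.2, rng_seed = rng_seed))
}

# Deterministic tiny expression matrix with named genes/samples.
tiny_expr <- function(values, genes, samples) {
  matrix(values, nrow = length(genes), byrow = TRUE,
         dimnames = list(genes, samples))
}

# Independent Spearman oracle: base rank() + cor() (the implementation
# under test uses its own midrank and covariance arithmetic).
oracle_spearman <- function(x, y) {
  stats::cor(rank(x, ties.method = "average"),
             rank(y, ties.method = "average"))
}
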