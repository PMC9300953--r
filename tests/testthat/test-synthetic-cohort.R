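test_that("generate_cohort is deterministic in the seed", {
  p <- cohort_params(n_samples = 60, n_genes = 80, n_partners = 5,
                     rng_seed = 5L)
  a <- generate_cohort(p)
  b <- generate_cohort(p)
  expect_identical(a$expression, b$expression)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$annotation, b$annotation)
  c2 <- generate_cohort(cohort_params(n_samples = 60, n_genes = 80,
                                      n_partners = 5, rng_seed = 6L))
  expect_false(identical(a$expression, c2$expression))
})

test_that("cohort invariants: non-negative expression, valid clinical, truth", {
  co <- small_cohort()
  expect_true(all(co$expression >= 0))
  expect_true(all(is.finite(co$expression)))
  expect_true(all(co$clinical$os_event %in% c(0, 1)))
  expect_true(all(co$clinical$os_months >= 0))
  expect_false(co$truth$seed_gene %in% co$truth$partner_genes)
  expect_true(all(co$truth$partner_genes %in% rownames(co$expression)))
  # all partners are annotated as signaling
  expect_true(all(co$truth$partner_genes %in% co$annotation$gene))
})

test_that("n_partners = 0 yields an empty planted set and zero risk", {
  co <- generate_cohort(cohort_params(n_samples = 50, n_genes = 40,
                                      n_partners = 0, beta = 0, rng_seed = 2L))
  expect_length(co$truth$partner_genes, 0)
  expect_equal(co$truth$latent_risk, rep(0, 50))
})

test_that("parameter invariants are enforced", {
  expect_error(cohort_params(n_partners = 100, n_genes = 50),
               class = "sighub_parameter_error")
  expect_error(cohort_params(rho_high = 0.1, rho_low = 0.3),
               class = "sighub_parameter_error")
  expect_error(cohort_params(censor_frac = 1.2), class = "sighub_parameter_error")
  expect_error(cohort_params(weibull_shape = 0), class = "sighub_parameter_error")
})

test_that("within-stratum Spearman of partners hits the targets", {
  # Monte-Carlo over 20 replicates at the discovery sample size
  rho_hat <- t(vapply(1:20, function(s) {
    co <- generate_cohort(cohort_params(n_samples = 510, n_genes = 60,
                                        n_partners = 5, rho_high = 0.4,
                                        rho_low = 0.05, rng_seed = 300L + s))
    st <- stratify_by_seed(co$expression, co$truth$seed_gene)
    hi <- coexpression_with_seed(co$expression, co$truth$seed_gene, st$high)
    lo <- coexpression_with_seed(co$expression, co$truth$seed_gene, st$low)
    pg <- co$truth$partner_genes
    c(mean(hi$rho[hi$gene %in% pg]), mean(lo$rho[lo$gene %in% pg]))
  }, numeric(2)))
  expect_lt(abs(mean(rho_hat[, 1]) - 0.4), 0.08)
  expect_lt(abs(mean(rho_hat[, 2]) - 0.05), 0.08)
})

test_that("planted-signal fidelity at n = 2000", {
  rho_hat <- t(vapply(1:3, function(s) {
    co <- generate_cohort(cohort_params(n_samples = 2000, n_genes = 60,
                                        n_partners = 10, rho_high = 0.45,
                                        rho_low = 0.05, rng_seed = 400L + s))
    st <- stratify_by_seed(co$expression, co$truth$seed_gene)
    hi <- coexpression_with_seed(co$expression, co$truth$seed_gene, st$high)
    lo <- coexpression_with_seed(co$expression, co$truth$seed_gene, st$low)
    pg <- co$truth$partner_genes
    c(mean(hi$rho[hi$gene %in% pg]), mean(lo$rho[lo$gene %in% pg]))
  }, numeric(2)))
  expect_lt(abs(mean(rho_hat[, 1]) - 0.45), 0.03)
  expect_lt(abs(mean(rho_hat[, 2]) - 0.05), 0.03)
})

test_that("censoring fraction is calibrated", {
  for (target in c(0.2, 0.4)) {
    co <- generate_cohort(cohort_params(n_samples = 600, n_genes = 30,
                                        n_partners = 5, censor_frac = target,
                                        rng_seed = 7L))
    expect_lt(abs(mean(1 - co$clinical$os_event) - target), 0.05)
  }
  co0 <- generate_cohort(cohort_params(n_samples = 100, n_genes = 30,
                                       n_partners = 5, censor_frac = 0,
                                       rng_seed = 8L))
  expect_equal(mean(co0$clinical$os_event), 1)
})

test_that("a Cox fit of the true latent risk recovers beta", {
  est <- vapply(1:60, function(s) {
    co <- generate_cohort(cohort_params(n_samples = 1000, n_genes = 35,
                                        n_partners = 5, beta = 0.5,
                                        rng_seed = 500L + s))
    cox_univariate(co$clinical$os_months, co$clinical$os_event,
                   co$truth$latent_risk / 0.5)$beta
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.5), 0.1)
})

test_that("mutation table respects planted frequencies", {
  ids <- sprintf("S%04d", 1:2000)
  hi <- ids[1:1000]
  mt <- generate_mutation_table(ids, c("EG1", "EG2"), 0.02, 0.20, hi,
                                rng_seed = 9L)
  f_hi <- mean(mt$status[mt$sample_id %in% hi & mt$gene == "EG1"] != "WT")
  f_lo <- mean(mt$status[!mt$sample_id %in% hi & mt$gene == "EG1"] != "WT")
  # binomial 95% bounds at n = 1000 per group
  expect_lt(abs(f_hi - 0.20), 1.96 * sqrt(0.2 * 0.8 / 1000))
  expect_lt(abs(f_lo - 0.02), 1.96 * sqrt(0.02 * 0.98 / 1000))
  all_wt <- generate_mutation_table(ids[1:50], "G1", 0, 0, character(0))
  expect_true(all(all_wt$status == "WT"))
  all_mt <- generate_mutation_table(ids[1:50], "G1", 0, 1, ids[1:50])
  expect_true(all(all_mt$status != "WT"))
  expect_error(generate_mutation_table(ids[1:5], "G1", -0.1, 0.5, ids[1]),
               class = "sighub_parameter_error")
  expect_error(generate_mutation_table(ids[1:5], "G1", 0.1, 0.5, "NOPE"),
               class = "sighub_key_error")
})

test_that("dependency table plants exact values over bounded background", {
  planted <- tibble::tibble(gene = "GA", cell_line = "LX", t_statistic = -3.5)
  dep <- generate_dependency_table(c("LX", "LY"), c("GA", "GB", "GC"),
                                   planted, background_sd = 0.4, rng_seed = 10L)
  expect_equal(dep$t_statistic[dep$gene == "GA" & dep$cell_line == "LX"], -3.5)
  dep2 <- generate_dependency_table(c("LX", "LY"), c("GA", "GB", "GC"),
                                    planted, background_sd = 0.4, rng_seed = 10L)
  expect_identical(dep, dep2)
  # Gaussian tail bound: with no planted pairs max |T| < ~4 sd whp
  big <- generate_dependency_table(sprintf("L%02d", 1:10),
                                   sprintf("G%03d", 1:50),
                                   background_sd = 0.5, rng_seed = 11L)
  expect_lt(max(abs(big$t_statistic)), 4 * 0.5)
  expect_error(
    generate_dependency_table("LX", "GA",
                              tibble::tibble(gene = "NOPE", cell_line = "LX",
                                             t_statistic = -1)),
    class = "sighub_key_error")
})
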