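test_that("stratify_by_seed splits 510 samples into 255/255 and handles edges", {
  set.seed(31)
  m <- matrix(rexp(510 * 2), nrow = 2,
              dimnames = list(c("SEED1", "G1"), sprintf("S%03d", 1:510)))
  st <- stratify_by_seed(m, "SEED1")
  expect_length(st$low, 255)
  expect_length(st$high, 255)
  expect_setequal(c(st$low, st$high), colnames(m))
  m5 <- matrix(c(1, 2, 3, 4, 5, rexp(5)), nrow = 2, byrow = TRUE,
               dimnames = list(c("SEED1", "G1"), paste0("S", 1:5)))
  st5 <- stratify_by_seed(m5, "SEED1")
  expect_equal(sort(c(length(st5$low), length(st5$high))), c(2, 3))
  mc <- matrix(c(rep(1, 5), rexp(5)), nrow = 2, byrow = TRUE,
               dimnames = list(c("SEED1", "G1"), paste0("S", 1:5)))
  expect_error(stratify_by_seed(mc, "SEED1"), class = "sighub_degenerate_error")
  expect_error(stratify_by_seed(m, "ABSENT"), class = "sighub_key_error")
})

test_that("a gene duplicating the seed row ranks first with rho = 1", {
  set.seed(32)
  m <- rbind(SEED1 = rexp(30), COPY = 0, G1 = rexp(30), G2 = rexp(30))
  m["COPY", ] <- m["SEED1", ] * 2          # monotone copy
  colnames(m) <- paste0("S", 1:30)
  cx <- coexpression_with_seed(m, "SEED1")
  expect_equal(cx$gene[1], "COPY")
  expect_equal(cx$rho[1], 1.0)
  expect_false("SEED1" %in% cx$gene)
})

test_that("genes constant within a stratum are excluded from ranking", {
  m <- rbind(SEED1 = c(1, 2, 3, 4, 5, 6), FLAT = rep(3, 6), G1 = c(2, 1, 4, 3, 6, 5))
  colnames(m) <- paste0("S", 1:6)
  cx <- coexpression_with_seed(m, "SEED1")
  expect_true(is.na(cx$rho[cx$gene == "FLAT"]))
  q <- assign_quartiles(cx)
  expect_true(is.na(q$quartile[q$gene == "FLAT"]))
  expect_false("FLAT" %in% top_quartile(cx))
})

test_that("quartile sizes follow the ceil rule and partition the ranking", {
  mk <- function(G) tibble::tibble(gene = sprintf("G%05d", 1:G),
                                   rho = seq(1, -1, length.out = G))
  expect_equal(sum(assign_quartiles(mk(20096))$quartile == 4), 5024)
  expect_equal(length(top_quartile(mk(8))), 2)
  expect_equal(length(top_quartile(mk(10))), 3)
  for (G in c(7, 10, 13, 100)) {
    q <- assign_quartiles(mk(G))
    expect_equal(sort(unique(q$quartile)), 1:4)
    expect_equal(sum(table(q$quartile)), G)          # partition
    expect_true(all(abs(table(q$quartile) - ceiling(G / 4)) <= 1))
  }
  expect_error(assign_quartiles(tibble::tibble(gene = character(0),
                                               rho = numeric(0))),
               class = "sighub_parameter_error")
})

test_that("quartile ties are broken by gene symbol, top quartile first", {
  tbl <- tibble::tibble(gene = c("B", "A", "D", "C"), rho = c(0.5, 0.5, 0.1, 0.1))
  q <- assign_quartiles(tbl)
  expect_equal(q$gene, c("A", "B", "C", "D"))
  expect_equal(q$quartile, c(4L, 3L, 2L, 1L))
})

test_that("signaling_intersect honours annotation and category filters", {
  ann <- tibble::tibble(gene = c("G1", "G2", "G3"),
                        category = c("GPCR", "STK", "GPCR"))
  expect_equal(signaling_intersect(c("G1", "G4"), ann), "G1")
  expect_equal(signaling_intersect(c("G1", "G2"), ann, categories = "STK"), "G2")
  expect_length(signaling_intersect(c("G1", "G2"), ann[0, ]), 0)
  expect_equal(signaling_intersect(c("G1", "G2", "G3"), ann), c("G1", "G2", "G3"))
})

test_that("category_enrichment implements the normalized quartile metric", {
  universe <- sprintf("G%03d", 1:200)
  ann <- tibble::tibble(gene = universe[1:40], category = "GPCR")
  in_top <- function(k) universe[1:k]
  expect_equal(category_enrichment(in_top(10), ann, "GPCR", universe)$metric, 1.0)
  expect_equal(category_enrichment(in_top(40), ann, "GPCR", universe)$metric, 4.0)
  expect_equal(category_enrichment(character(0), ann, "GPCR", universe)$metric, 0.0)
  expect_true(category_enrichment(in_top(11), ann, "GPCR", universe)$preferential)
  expect_error(category_enrichment(in_top(5), ann, "GPCR", universe = "X1"),
               class = "sighub_parameter_error")
})

test_that("contrast_filter applies the 0.2-and-higher-in-high rule", {
  tbl <- tibble::tibble(
    gene = c("KEEP", "LOW_RHO", "NOT_CONTRAST", "NOT_TOP"),
    rho_low = c(0.05, 0.01, 0.35, 0.05),
    rho_high = c(0.25, 0.15, 0.30, 0.25),
    quartile_low = c(4L, 4L, 4L, 4L),
    quartile_high = c(4L, 4L, 4L, 2L))
  expect_equal(contrast_filter(tbl), "KEEP")
  expect_equal(contrast_filter(tbl, min_rho_high = 0.1),
               c("KEEP", "LOW_RHO"))
})

test_that("survival_filter keeps only significantly worse-when-high genes", {
  set.seed(33)
  n <- 200
  risky <- rexp(n)                        # high expression -> high hazard
  protective <- rexp(n)
  tm <- rexp(n, exp(1.5 * scale(risky)[, 1] - 1.5 * scale(protective)[, 1]) / 20)
  ev <- rep(1, n)
  m <- rbind(RISKY = risky, PROT = protective, NOISE = rexp(n))
  colnames(m) <- sprintf("S%03d", 1:n)
  clin <- tibble::tibble(sample_id = colnames(m), os_months = tm, os_event = ev)
  sv <- survival_filter(m, clin, c("RISKY", "PROT", "NOISE"))
  expect_true(sv$retained[sv$gene == "RISKY"])
  expect_equal(sv$direction[sv$gene == "RISKY"], "worse_when_high")
  # protective gene: excluded regardless of its (significant) p-value
  expect_lt(sv$logrank_p[sv$gene == "PROT"], 0.05)
  expect_false(sv$retained[sv$gene == "PROT"])
  expect_equal(sv$direction[sv$gene == "PROT"], "better_when_high")
})

test_that("survival_filter enforces clinical coverage and event presence", {
  m <- tiny_expr(rexp(20), c("G1", "G2"), sprintf("S%02d", 1:10))
  clin <- tibble::tibble(sample_id = sprintf("S%02d", 1:5),
                         os_months = 1:5, os_event = rep(1, 5))
  expect_error(survival_filter(m, clin, "G1"), class = "sighub_parameter_error")
  clin_full <- tibble::tibble(sample_id = sprintf("S%02d", 1:10),
                              os_months = 1:10, os_event = rep(0, 10))
  expect_error(survival_filter(m, clin_full, "G1"),
               class = "sighub_degenerate_error")
})

test_that("expand_phosphosubstrates intersects with the top quartile", {
  ks <- list(K1 = c("S1", "S2"), K2 = c("S2", "S3"))
  out <- expand_phosphosubstrates("K1", ks, top_genes = c("S1", "X"))
  expect_equal(out$gene, "S1")
  expect_equal(out$kinases, "K1")
  expect_equal(nrow(expand_phosphosubstrates(character(0), ks, c("S1"))), 0)
  both <- expand_phosphosubstrates(c("K1", "K2"), ks, c("S1", "S2", "S3"))
  expect_equal(both$kinases[both$gene == "S2"], "K1,K2")
  expect_equal(sum(both$gene == "S2"), 1)
})

test_that("build_hub_signature recovers a planted hub end to end", {
  co <- small_cohort()
  sig <- build_hub_signature(co$expression, co$clinical, co$annotation,
                             co$truth$seed_gene)
  recovered <- intersect(sig$partners$gene, co$truth$partner_genes)
  expect_gte(length(recovered), 7)                 # 10 planted
  expect_lte(nrow(sig$partners) - length(recovered), 3)
  expect_false(co$truth$seed_gene %in% sig$partners$gene)
  expect_true(all(sig$partners$direction == "worse_when_high"))
  expect_true(all(sig$partners$rho_high >= 0.2))
  expect_true(all(sig$partners$logrank_p < 0.05))
  # funnel bookkeeping matches the recomputed stage sets
  p <- sig$provenance
  expect_equal(p$n_partners, nrow(sig$partners))
  expect_equal(p$n_contrast, length(contrast_filter(sig$coexpression)))
  expect_lte(p$n_signaling, p$n_contrast)
})

test_that("filters are monotone: stricter thresholds never add partners", {
  co <- small_cohort()
  base <- build_hub_signature(co$expression, co$clinical, co$annotation,
                              co$truth$seed_gene,
                              min_rho_high = 0.2, alpha = 0.05)
  stricter_rho <- build_hub_signature(co$expression, co$clinical,
                                      co$annotation, co$truth$seed_gene,
                                      min_rho_high = 0.35, alpha = 0.05)
  stricter_alpha <- build_hub_signature(co$expression, co$clinical,
                                        co$annotation, co$truth$seed_gene,
                                        min_rho_high = 0.2, alpha = 0.005)
  expect_true(all(stricter_rho$partners$gene %in% base$partners$gene))
  expect_true(all(stricter_alpha$partners$gene %in% base$partners$gene))
})

test_that("a null cohort yields an (almost) empty signature with a warning", {
  co <- generate_cohort(cohort_params(n_samples = 200, n_genes = 400,
                                      n_partners = 0, beta = 0,
                                      rng_seed = 77L))
  sig <- withCallingHandlers(
    build_hub_signature(co$expression, co$clinical, co$annotation, "SEED1"),
    sighub_empty_signature = function(w) invokeRestart("muffleWarning"))
  expect_lte(nrow(sig$partners), 2)
})

test_that("substrate-expanded genes must independently pass both filters", {
  co <- small_cohort()
  # every partner is a substrate of a fake kinase that is itself a partner;
  # a gene outside the top quartile must never enter via expansion
  sig0 <- build_hub_signature(co$expression, co$clinical, co$annotation,
                              co$truth$seed_gene)
  kin <- sig0$partners$gene[1]
  ks <- list(c("G000399", co$truth$partner_genes))  # G000399: background gene
  names(ks) <- kin
  sig <- build_hub_signature(co$expression, co$clinical, co$annotation,
                             co$truth$seed_gene, ks_map = ks)
  if ("G000399" %in% sig$partners$gene) {
    row <- sig$partners[sig$partners$gene == "G000399", ]
    expect_gte(row$rho_high, 0.2)
    expect_lt(row$logrank_p, 0.05)
  }
  expect_false(co$truth$seed_gene %in% sig$partners$gene)
})

test_that("signature files round-trip", {
  co <- small_cohort()
  sig <- build_hub_signature(co$expression, co$clinical, co$annotation,
                             co$truth$seed_gene)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_signature(sig, path)
  back <- read_signature(path)
  expect_equal(back$seed_gene, sig$seed_gene)
  expect_equal(back$partners$gene, sig$partners$gene)
  expect_equal(back$partners$rho_high, sig$partners$rho_high, tolerance = 1e-6)
})
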