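# Synthetic cohorts with the statistical structure the discovery pipeline
# assumes: a seed gene, a planted partner module whose rank correlation with
# the seed is stratum-dependent, Weibull survival whose log-hazard is driven
# by the planted module, independent uniform right-censoring, and companion
# annotation / mutation / dependency tables. Every output is a pure
# function of the parameters including the RNG seed.

#' Parameters for a synthetic cohort
#'
#' Defaults emulate the discovery-scale study conditions: a 510-patient
#' cohort, 5,000 measured genes, a 30-gene planted hub whose Spearman
#' correlation with the seed is 0.45 in the high-seed half and 0.05 in the
#' low half, a log-hazard of 0.8 per standard deviation of the planted
#' module's mean expression z-score, and ~30% right-censoring.
#'
#' @param n_samples Number of patients.
#' @param n_genes Number of background genes (the seed is added on top).
#' @param n_partners Planted hub size (0 for a null cohort).
#' @param rho_high,rho_low Target within-stratum Spearman correlation of
#'   each partner with the seed, in `[0, 1)`; `rho_high > rho_low` for a
#'   discoverable hub (enforced only when `n_partners > 0`).
#' @param beta Log-hazard per unit of the standardized signature score.
#' @param baseline_scale Weibull scale of the baseline event-time
#'   distribution, in months.
#' @param weibull_shape Weibull shape (> 0).
#' @param censor_frac Target fraction of right-censored samples, in `[0, 1)`.
#' @param frac_signaling Fraction of background genes tagged with a
#'   signaling category (all planted partners are tagged).
#' @param rng_seed Integer RNG seed.
#' @return A validated list of class `cohort_params`.
#' @export
cohort_params <- function(n_samples = 510, n_genes = 5000, n_partners = 30,
                          rho_high = 0.45, rho_low = 0.05, beta = 0.8,
                          baseline_scale = 60, weibull_shape = 1.2,
                          censor_frac = 0.3, frac_signaling = 0.2,
                          rng_seed = 1L) {
  p <- list(n_samples = n_samples, n_genes = n_genes, n_partners = n_partners,
            rho_high = rho_high, rho_low = rho_low, beta = beta,
            baseline_scale = baseline_scale, weibull_shape = weibull_shape,
            censor_frac = censor_frac, frac_signaling = frac_signaling,
            rng_seed = as.integer(rng_seed))
  if (n_samples < 4) stop_param("n_samples must be at least 4")
  if (n_partners < 0 || n_partners >= n_genes) {
    stop_param("n_partners must satisfy 0 <= n_partners < n_genes")
  }
  for (f in c("rho_high", "rho_low", "censor_frac", "frac_signaling")) {
    if (p[[f]] < 0 || p[[f]] >= 1) stop_param(sprintf("%s must be in [0, 1)", f))
  }
  if (n_partners > 0 && rho_high <= rho_low) {
    stop_param("rho_high must exceed rho_low for a discoverable planted hub")
  }
  if (weibull_shape <= 0 || baseline_scale <= 0) {
    stop_param("weibull_shape and baseline_scale must be positive")
  }
  structure(p, class = "cohort_params")
}

# Spearman -> Pearson loading for a bivariate Gaussian copula:
# rho_S = (6/pi) asin(r/2)  =>  r = 2 sin(pi rho_S / 6).
spearman_to_pearson <- function(rho) 2 * sin(pi * rho / 6)

# Per-stratum normal scores of the seed: rank-equivalent to the seed within
# the stratum but marginally standard normal, so a linear loading gives a
# controlled Gaussian copula (hence controlled Spearman) despite the
# truncated seed distribution inside a stratum.
normal_scores <- function(x) qnorm((midrank(x) - 0.5) / length(x))

latent_to_expression <- function(z, meanlog = 5, sdlog = 1) {
  exp(meanlog + sdlog * z)
}

# Calibrate the upper bound c of Uniform(0, c) censoring so the expected
# censored fraction over the simulated event times hits the target.
calibrate_censoring <- function(event_times, censor_frac) {
  if (censor_frac == 0) return(Inf)
  frac_at <- function(cc) mean(pmin(event_times / cc, 1)) - censor_frac
  lo <- min(event_times) * 1e-3 + 1e-9
  hi <- max(event_times) * 1e4
  if (frac_at(hi) > 0) return(hi)
  uniroot(frac_at, c(lo, hi), tol = 1e-8)$root
}

#' Generate a synthetic cohort with a planted signaling hub
#'
#' Gene-level latents are standard Gaussian; inside each seed-expression
#' half, every planted partner loads on the within-stratum normal scores of
#' the seed with loading `2 sin(pi * rho / 6)` so the within-stratum
#' Spearman correlation targets `rho_high` / `rho_low`. Latents are mapped
#' through a log-normal link to a non-negative RSEM-like scale (rank
#' statistics are unaffected). Event times are Weibull with log-hazard
#' `beta` times the standardized mean partner z-score; censoring is
#' `Uniform(0, c)` with `c` calibrated numerically to the target fraction.
#'
#' @param params A [cohort_params()] object.
#' @return List of class `sighub_cohort` with elements `expression`
#'   (matrix), `clinical` (tibble), `annotation` (long tibble), and `truth`
#'   (list: `seed_gene`, `partner_genes`, `latent_risk`, `censor_bound`).
#' @export
generate_cohort <- function(params) {
  if (!inherits(params, "cohort_params")) params <- do.call(cohort_params, params)
  withr::with_seed(params$rng_seed, {
    n <- params$n_samples
    G <- params$n_genes
    sample_ids <- sprintf("S%04d", seq_len(n))
    gene_ids <- sprintf("G%06d", seq_len(G))
    seed_gene <- "SEED1"
    partner_genes <- if (params$n_partners > 0) {
      gene_ids[seq_len(params$n_partners)]
    } else character(0)

    s <- rnorm(n)                       # seed latent
    strata <- median_split(s)           # the 50:50 partition the analysis uses
    z <- matrix(rnorm(G * n), nrow = G, dimnames = list(gene_ids, sample_ids))

    if (params$n_partners > 0) {
      # The hub is a coherent module across the whole cohort (pairwise
      # partner loading lam_mod, taken from rho_high); only its coupling to
      # the seed is stratum-dependent. Within a stratum each partner loads
      # lam_seed on the seed's normal scores and the remaining module
      # variance on a seed-independent shared factor v.
      v <- rnorm(n)
      lam_mod <- spearman_to_pearson(params$rho_high)
      for (lev in c("low", "high")) {
        idx <- which(strata == lev)
        lam_seed <- spearman_to_pearson(
          if (lev == "high") params$rho_high else params$rho_low)
        b <- sqrt(max(0, lam_mod^2 - lam_seed^2))
        u <- normal_scores(s[idx])
        eps <- z[partner_genes, idx, drop = FALSE]
        z[partner_genes, idx] <-
          rep(lam_seed * u + b * v[idx], each = params$n_partners) +
          sqrt(1 - lam_mod^2) * eps
      }
    }

    expr <- latent_to_expression(rbind(z, matrix(s, nrow = 1)))
    rownames(expr) <- c(gene_ids, seed_gene)
    colnames(expr) <- sample_ids

    if (params$n_partners > 0) {
      m <- colMeans(z[partner_genes, , drop = FALSE])
      latent_risk <- params$beta * as.vector(scale(m))
    } else {
      latent_risk <- rep(0, n)
    }

    u_t <- runif(n)
    event_times <- params$baseline_scale *
      (-log(u_t) * exp(-latent_risk))^(1 / params$weibull_shape)
    cens_bound <- calibrate_censoring(event_times, params$censor_frac)
    cens_times <- if (is.finite(cens_bound)) runif(n, 0, cens_bound) else
      rep(Inf, n)
    clinical <- tibble(
      sample_id = sample_ids,
      os_months = pmin(event_times, cens_times),
      os_event = as.numeric(event_times <= cens_times)
    )

    n_bg_sig <- round(params$frac_signaling * (G - params$n_partners))
    bg_pool <- setdiff(gene_ids, partner_genes)
    bg_sig <- sample(bg_pool, n_bg_sig)
    annotated <- c(partner_genes, bg_sig)
    annotation <- tibble(
      gene = annotated,
      category = sample(SIGNALING_CATEGORIES, length(annotated), replace = TRUE)
    ) |> arrange(.data$gene)

    structure(
      list(expression = expr, clinical = clinical, annotation = annotation,
           truth = list(seed_gene = seed_gene, partner_genes = partner_genes,
                        latent_risk = latent_risk, censor_bound = cens_bound),
           params = params),
      class = "sighub_cohort"
    )
  })
}

#' @export
print.sighub_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d genes x %d samples, %d planted partners, seed '%s'\n",
              nrow(x$expression), ncol(x$expression),
              length(x$truth$partner_genes), x$truth$seed_gene))
  cat(sprintf("  events: %d/%d (%.0f%% censored)\n",
              sum(x$clinical$os_event), nrow(x$clinical),
              100 * mean(1 - x$clinical$os_event)))
  invisible(x)
}

#' Generate a synthetic per-sample mutation table
#'
#' Each listed gene is altered independently with probability
#' `alt_freq_high` in the given high-seed samples and `alt_freq_low`
#' elsewhere; altered statuses are drawn uniformly from MT/AMP/DEL.
#'
#' @param sample_ids Character vector of cohort sample IDs.
#' @param genes Genes to simulate.
#' @param alt_freq_low,alt_freq_high Alteration probabilities in `[0, 1]`.
#' @param high_ids Subset of `sample_ids` forming the high-seed group.
#' @param rng_seed Integer RNG seed.
#' @return Tibble `sample_id`, `gene`, `status`.
#' @export
generate_mutation_table <- function(sample_ids, genes, alt_freq_low,
                                    alt_freq_high, high_ids, rng_seed = 1L) {
  if (alt_freq_low < 0 || alt_freq_low > 1 || alt_freq_high < 0 || alt_freq_high > 1) {
    stop_param("alteration frequencies must lie in [0, 1]")
  }
  if (!all(high_ids %in% sample_ids)) {
    stop_key("high_ids must be a subset of sample_ids")
  }
  withr::with_seed(as.integer(rng_seed), {
    grid <- tidyr::expand_grid(sample_id = sample_ids, gene = genes)
    p_alt <- ifelse(grid$sample_id %in% high_ids, alt_freq_high, alt_freq_low)
    altered <- runif(nrow(grid)) < p_alt
    status <- rep("WT", nrow(grid))
    status[altered] <- sample(c("MT", "AMP", "DEL"), sum(altered), replace = TRUE)
    mutate(grid, status = status)
  })
}

#' Generate a synthetic dependency-screen table
#'
#' Planted (gene, cell line) pairs carry their specified T-statistic
#' exactly; all other cells are background noise near zero.
#'
#' @param cell_lines Character vector of cell-line names.
#' @param genes Character vector of gene symbols.
#' @param essential_pairs Tibble with columns `gene`, `cell_line`,
#'   `t_statistic` (may be empty / NULL).
#' @param background_sd Standard deviation of background T-statistics.
#' @param rng_seed Integer RNG seed.
#' @param perturbation Perturbation label for every row (default `crispr`).
#' @return Tibble `cell_line`, `gene`, `t_statistic`, `perturbation`.
#' @export
generate_dependency_table <- function(cell_lines, genes,
                                      essential_pairs = NULL,
                                      background_sd = 0.5, rng_seed = 1L,
                                      perturbation = "crispr") {
  withr::with_seed(as.integer(rng_seed), {
    grid <- tidyr::expand_grid(cell_line = cell_lines, gene = genes)
    grid$t_statistic <- rnorm(nrow(grid), 0, background_sd)
    if (!is.null(essential_pairs) && nrow(essential_pairs) > 0) {
      if (!all(essential_pairs$gene %in% genes) ||
          !all(essential_pairs$cell_line %in% cell_lines)) {
        stop_key("essential_pairs reference unknown genes or cell lines")
      }
      key <- paste(grid$cell_line, grid$gene, sep = "\r")
      pkey <- paste(essential_pairs$cell_line, essential_pairs$gene, sep = "\r")
      grid$t_statistic[match(pkey, key)] <- essential_pairs$t_statistic
    }
    mutate(grid, perturbation = perturbation)
  })
}
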