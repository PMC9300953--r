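# The multi-stage selection procedure at the heart of the package:
# stratify by seed expression -> rank genes by within-stratum Spearman
# coexpression -> top quartile -> signaling intersection -> contrast filter
# -> survival filter -> optional kinase-substrate expansion.

#' Stratify a cohort by seed-gene expression
#'
#' 50:50 percentile split (configurable) of the samples on the seed gene's
#' expression row, using the deterministic [median_split()] tie rule. The
#' partition is exhaustive and disjoint.
#'
#' @param expr Genes x samples expression matrix.
#' @param seed_gene Seed gene symbol (must be a rowname of `expr`).
#' @param percentile Split percentile (default 50).
#' @return List with `low` and `high` sample-ID character vectors.
#' @export
stratify_by_seed <- function(expr, seed_gene, percentile = 50) {
  assert_expression_matrix(expr)
  if (!seed_gene %in% rownames(expr)) {
    stop_key(sprintf("seed gene '%s' absent from expression matrix", seed_gene))
  }
  if (ncol(expr) < 4) stop_param("need at least 4 samples to stratify")
  lab <- median_split(expr[seed_gene, ], percentile)
  list(low = colnames(expr)[lab == "low"],
       high = colnames(expr)[lab == "high"])
}

#' Coexpression of every gene with the seed within one stratum
#'
#' Spearman rho of each non-seed gene against the seed gene across the
#' given samples. Genes constant within the stratum have undefined
#' correlation and are returned with `rho = NA` (they are excluded from
#' quartile ranking downstream).
#'
#' @param expr Expression matrix.
#' @param seed_gene Seed gene symbol.
#' @param samples Sample IDs of the stratum (default: all samples).
#' @return Tibble `gene`, `rho`, ordered by decreasing rho (NA last), ties
#'   broken by gene symbol.
#' @export
coexpression_with_seed <- function(expr, seed_gene, samples = NULL) {
  assert_expression_matrix(expr)
  if (!seed_gene %in% rownames(expr)) {
    stop_key(sprintf("seed gene '%s' absent from expression matrix", seed_gene))
  }
  samples <- samples %||% colnames(expr)
  if (length(samples) < 3) stop_param("stratum needs at least 3 samples")
  sub <- expr[, samples, drop = FALSE]
  seed_vals <- sub[seed_gene, ]
  if (length(unique(seed_vals)) < 2) {
    stop_degenerate("seed gene constant within the stratum")
  }
  genes <- setdiff(rownames(sub), seed_gene)
  rho <- spearman_rows(sub[genes, , drop = FALSE], seed_vals)
  tibble(gene = genes, rho = unname(rho)) |>
    arrange(desc(.data$rho), .data$gene)
}

#' Assign coexpression quartiles
#'
#' Genes are ranked by decreasing rho (ties broken by gene symbol); the
#' first `ceiling(G/4)` genes form quartile 4 (the top quartile), and the
#' remainder is split into quartiles 3, 2, 1 with the quartiles nearer the
#' top absorbing any remainder. Every quartile size is within 1 of
#' `ceiling(G/4)`. Genes with `NA` rho receive `NA` quartile.
#'
#' @param coexpr Tibble with `gene` and `rho` columns.
#' @return The tibble, ranked, with an integer `quartile` column.
#' @export
assign_quartiles <- function(coexpr) {
  if (!all(c("gene", "rho") %in% names(coexpr))) {
    stop_param("coexpr must have columns gene, rho")
  }
  ranked <- coexpr |> filter(!is.na(.data$rho)) |>
    arrange(desc(.data$rho), .data$gene)
  G <- nrow(ranked)
  if (G == 0) stop_param("no ranked genes to assign quartiles")
  top <- ceiling(G / 4)
  rest <- G - top
  base <- rest %/% 3
  rem <- rest %% 3
  sizes <- c(top, base + (rem >= 1), base + (rem >= 2), base)
  ranked$quartile <- rep(c(4L, 3L, 2L, 1L), times = sizes)
  dropped <- coexpr |> filter(is.na(.data$rho)) |>
    mutate(quartile = NA_integer_)
  bind_rows(ranked, dropped)
}

#' Top-quartile gene set
#'
#' @param coexpr Tibble with `gene`, `rho` (quartiles are computed if not
#'   already present).
#' @return Character vector of quartile-4 genes.
#' @export
top_quartile <- function(coexpr) {
  if (!"quartile" %in% names(coexpr)) coexpr <- assign_quartiles(coexpr)
  coexpr$gene[!is.na(coexpr$quartile) & coexpr$quartile == 4L]
}

#' Full two-stratum coexpression table
#'
#' Runs [coexpression_with_seed()] in the low and high strata and merges
#' the results with per-stratum quartile labels.
#'
#' @param expr Expression matrix.
#' @param seed_gene Seed gene symbol.
#' @param strata List with `low`/`high` sample IDs from [stratify_by_seed()].
#' @return Tibble `gene`, `rho_low`, `rho_high`, `quartile_low`,
#'   `quartile_high`.
#' @export
seed_coexpression_table <- function(expr, seed_gene, strata) {
  lo <- assign_quartiles(coexpression_with_seed(expr, seed_gene, strata$low))
  hi <- assign_quartiles(coexpression_with_seed(expr, seed_gene, strata$high))
  lo |>
    rename(rho_low = "rho", quartile_low = "quartile") |>
    left_join(hi |> rename(rho_high = "rho", quartile_high = "quartile"),
              by = "gene") |>
    select("gene", "rho_low", "rho_high", "quartile_low", "quartile_high") |>
    arrange(desc(.data$rho_high), .data$gene)
}

#' Intersect a gene set with the signaling annotation
#'
#' @param genes Character vector of gene symbols.
#' @param annotation Long tibble `gene`, `category`.
#' @param categories Optional character vector restricting to particular
#'   categories; default: any annotated category counts.
#' @return Character vector: genes carrying at least one (matching)
#'   annotation category, in input order.
#' @export
signaling_intersect <- function(genes, annotation, categories = NULL) {
  ann <- annotation
  if (!is.null(categories)) ann <- filter(ann, .data$category %in% categories)
  genes[genes %in% unique(ann$gene)]
}

#' Normalized coexpression of an annotation category in the top quartile
#'
#' The metric equals (category members in the top quartile) divided by one
#' quarter of the category's size among measured genes; 1.0 means the
#' category is represented exactly as a uniform quarter would predict, and
#' values above 1.0 flag preferential coexpression with the seed.
#'
#' @param top_genes Character vector: the top-quartile gene set.
#' @param annotation Long tibble `gene`, `category`.
#' @param category Category label to evaluate.
#' @param universe Character vector of measured genes (the expression
#'   matrix rownames).
#' @return One-row tibble `category`, `n_members`, `n_top`, `metric`,
#'   `preferential`.
#' @export
category_enrichment <- function(top_genes, annotation, category, universe) {
  members <- annotation |>
    filter(.data$category == !!category) |>
    pull("gene") |>
    intersect(universe)
  if (length(members) == 0) {
    stop_param(sprintf("category '%s' has no members in the expression matrix",
                       category))
  }
  n_top <- sum(members %in% top_genes)
  metric <- n_top / (length(members) / 4)
  tibble(category = category, n_members = length(members), n_top = n_top,
         metric = metric, preferential = metric > 1)
}

#' Stratum-contrast filter
#'
#' Keeps genes whose high-stratum coexpression with the seed is at least
#' `min_rho_high`, exceeds their low-stratum coexpression, and who sit in
#' the high-stratum top quartile.
#'
#' @param coexpr Tibble from [seed_coexpression_table()].
#' @param min_rho_high Minimum high-stratum Spearman rho (default 0.2).
#' @return Character vector of retained genes.
#' @export
contrast_filter <- function(coexpr, min_rho_high = 0.2) {
  need <- c("gene", "rho_low", "rho_high", "quartile_high")
  if (!all(need %in% names(coexpr))) {
    stop_param("coexpr must come from seed_coexpression_table()")
  }
  kept <- coexpr |>
    filter(!is.na(.data$rho_high), !is.na(.data$rho_low),
           .data$rho_high >= min_rho_high,
           .data$rho_high > .data$rho_low,
           .data$quartile_high == 4L)
  kept$gene
}

#' Per-gene median-split survival filter
#'
#' For each candidate gene the whole cohort is split 50:50 on that gene's
#' expression, the two halves are compared by the log-rank test, and the
#' direction is the sign of the observed-minus-expected event count in the
#' high half -- equivalent to which Kaplan-Meier curve lies lower whenever
#' the curves do not cross, but robust to tail noise when they do (exact
#' ties fall back to the KM comparison at the last common event time). A
#' gene is retained iff `p < alpha` and its high half fares worse.
#'
#' @param expr Expression matrix.
#' @param clinical Clinical tibble (`sample_id`, `os_months`, `os_event`).
#' @param genes Candidate gene symbols.
#' @param alpha Log-rank significance threshold (default 0.05, on the raw
#'   p-value; BH-adjusted values are reported alongside).
#' @param min_coverage Minimum fraction of expression samples that must
#'   have clinical follow-up (default 0.9).
#' @return Tibble `gene`, `logrank_p`, `logrank_q` (BH), `direction`
#'   (`worse_when_high` / `better_when_high`), `retained`.
#' @export
survival_filter <- function(expr, clinical, genes, alpha = 0.05,
                            min_coverage = 0.9) {
  assert_expression_matrix(expr)
  assert_clinical(clinical)
  shared <- intersect(colnames(expr), clinical$sample_id)
  if (length(shared) < min_coverage * ncol(expr)) {
    stop_param(sprintf(
      "clinical table covers %d/%d expression samples (< %.0f%% required)",
      length(shared), ncol(expr), 100 * min_coverage))
  }
  clin <- clinical[match(shared, clinical$sample_id), ]
  if (sum(clin$os_event) == 0) stop_degenerate("no events in the cohort")
  res <- purrr::map(genes, function(g) {
    if (!g %in% rownames(expr)) {
      stop_key(sprintf("gene '%s' absent from expression matrix", g))
    }
    vals <- expr[g, shared]
    lab <- tryCatch(median_split(vals), sighub_degenerate_error = function(e) NULL)
    if (is.null(lab)) {
      return(tibble(gene = g, logrank_p = NA_real_,
                    direction = NA_character_))
    }
    lo <- lab == "low"; hi <- lab == "high"
    lt <- logrank_test(clin$os_months[hi], clin$os_event[hi],
                       clin$os_months[lo], clin$os_event[lo])
    # Direction: sign of observed-minus-expected events in the high half.
    # This matches "which KM curve lies lower" whenever the curves do not
    # cross, and unlike a tail readout it is not at the mercy of the last
    # handful of at-risk patients. KM comparison breaks exact ties.
    dir <- if (lt$observed_a > lt$expected_a) "worse_when_high"
      else if (lt$observed_a < lt$expected_a) "better_when_high"
      else {
        km_hi <- km_estimate(clin$os_months[hi], clin$os_event[hi])
        km_lo <- km_estimate(clin$os_months[lo], clin$os_event[lo])
        t_star <- min(max(clin$os_months[hi]), max(clin$os_months[lo]))
        if (km_survival_at(km_hi, t_star) <= km_survival_at(km_lo, t_star))
          "worse_when_high" else "better_when_high"
      }
    tibble(gene = g, logrank_p = lt$p_value, direction = dir)
  })
  out <- bind_rows(res)
  if (nrow(out) == 0) {
    return(tibble(gene = character(0), logrank_p = numeric(0),
                  logrank_q = numeric(0), direction = character(0),
                  retained = logical(0)))
  }
  out$logrank_q <- NA_real_
  ok <- !is.na(out$logrank_p)
  out$logrank_q[ok] <- bh_adjust(out$logrank_p[ok])
  out$retained <- ok & out$logrank_p < alpha &
    out$direction == "worse_when_high"
  out[, c("gene", "logrank_p", "logrank_q", "direction", "retained")]
}

#' Expand a kinase set to its coexpressed phosphosubstrates
#'
#' Union of the substrates of the given kinases, restricted to the
#' top-quartile coexpression set; each substrate is annotated with the
#' upstream kinase(s) that target it.
#'
#' @param kinases Character vector of kinase gene symbols.
#' @param ks_map Named list kinase -> substrate character vector.
#' @param top_genes Top-quartile gene set.
#' @return Tibble `gene`, `kinases` (comma-separated upstream kinases).
#' @export
expand_phosphosubstrates <- function(kinases, ks_map, top_genes) {
  kinases <- intersect(kinases, names(ks_map))
  if (length(kinases) == 0) {
    return(tibble(gene = character(0), kinases = character(0)))
  }
  pairs <- purrr::imap(ks_map[kinases], function(subs, k) {
    tibble(gene = subs, kinase = k)
  }) |> bind_rows()
  pairs |>
    filter(.data$gene %in% top_genes) |>
    group_by(.data$gene) |>
    summarise(kinases = paste(sort(unique(.data$kinase)), collapse = ","),
              .groups = "drop") |>
    arrange(.data$gene)
}

KINASE_CATEGORIES <- c("STK", "TyrK", "DK", "RTK")

#' Discover a signaling hub signature around a seed gene
#'
#' Runs the full cascade: stratify by seed expression, rank genes by
#' within-stratum Spearman coexpression, take the high-stratum top
#' quartile, intersect with the signaling annotation, apply the
#' stratum-contrast filter and the median-split log-rank survival filter,
#' and (when a kinase-substrate map is supplied) expand retained kinases to
#' their coexpressed substrates, which must independently pass the contrast
#' and survival filters. An empty result is returned as an empty signature
#' with a structured warning, never as an error.
#'
#' @param expr Expression matrix.
#' @param clinical Clinical tibble.
#' @param annotation Long tibble `gene`, `category`.
#' @param seed_gene Seed gene symbol.
#' @param min_rho_high Contrast-filter threshold (default 0.2).
#' @param alpha Survival-filter significance level (default 0.05).
#' @param percentile Stratification percentile (default 50).
#' @param ks_map Optional named list kinase -> substrates.
#' @param categories Optional restriction of annotation categories.
#' @param kinase_categories Categories treated as kinases for substrate
#'   expansion.
#' @return A `sighub_signature`: list with `seed_gene`, `partners` (tibble
#'   `gene, rho_low, rho_high, quartile_low, quartile_high, logrank_p,
#'   logrank_q, direction, via_kinase`), `coexpression` (full table), and
#'   `provenance` (parameters plus the gene-count funnel).
#' @export
build_hub_signature <- function(expr, clinical, annotation, seed_gene,
                                min_rho_high = 0.2, alpha = 0.05,
                                percentile = 50, ks_map = NULL,
                                categories = NULL,
                                kinase_categories = KINASE_CATEGORIES) {
  assert_expression_matrix(expr)
  assert_clinical(clinical)
  strata <- stratify_by_seed(expr, seed_gene, percentile)
  coexpr <- seed_coexpression_table(expr, seed_gene, strata)
  top_hi <- coexpr$gene[!is.na(coexpr$quartile_high) & coexpr$quartile_high == 4L]
  contrast_ok <- contrast_filter(coexpr, min_rho_high)
  sig_genes <- signaling_intersect(contrast_ok, annotation, categories)

  expanded <- tibble(gene = character(0), kinases = character(0))
  if (!is.null(ks_map)) {
    kin <- signaling_intersect(sig_genes, annotation, kinase_categories)
    expanded <- expand_phosphosubstrates(kin, ks_map, top_hi)
    # substrate candidates must independently pass the contrast filter
    expanded <- filter(expanded,
                       .data$gene %in% contrast_ok,
                       !.data$gene %in% sig_genes,
                       .data$gene != seed_gene)
  }
  candidates <- unique(c(sig_genes, expanded$gene))
  surv <- survival_filter(expr, clinical, candidates, alpha)
  retained <- surv$gene[surv$retained]

  partners <- coexpr |>
    filter(.data$gene %in% retained) |>
    left_join(surv, by = "gene") |>
    left_join(expanded |> rename(via_kinase = "kinases"), by = "gene") |>
    select("gene", "rho_low", "rho_high", "quartile_low", "quartile_high",
           "logrank_p", "logrank_q", "direction", "via_kinase") |>
    arrange(desc(.data$rho_high), .data$gene)

  provenance <- list(
    seed_gene = seed_gene, min_rho_high = min_rho_high, alpha = alpha,
    percentile = percentile,
    categories = categories %||% "any",
    n_samples = ncol(expr),
    n_genes = nrow(expr) - 1L,
    n_ranked_low = sum(!is.na(coexpr$rho_low)),
    n_ranked_high = sum(!is.na(coexpr$rho_high)),
    n_top_quartile_high = length(top_hi),
    n_contrast = length(contrast_ok),
    n_signaling = length(sig_genes),
    n_substrate_expanded = nrow(expanded),
    n_candidates = length(candidates),
    n_partners = length(retained)
  )
  sig <- structure(
    list(seed_gene = seed_gene, partners = partners,
         coexpression = coexpr, survival = surv, provenance = provenance),
    class = "sighub_signature"
  )
  if (nrow(partners) == 0) {
    warn("no genes passed every filter; returning an empty signature",
         class = "sighub_empty_signature")
  }
  sig
}

#' @export
print.sighub_signature <- function(x, ...) {
  p <- x$provenance
  cat(sprintf("Signaling hub signature around '%s': %d partner(s)\n",
              x$seed_gene, p$n_partners))
  cat(sprintf("  funnel: %d genes -> %d top-quartile -> %d contrast -> %d signaling (+%d substrates) -> %d survival-retained\n",
              p$n_genes, p$n_top_quartile_high, p$n_contrast, p$n_signaling,
              p$n_substrate_expanded, p$n_partners))
  if (nrow(x$partners)) print(head(x$partners, 10))
  invisible(x)
}

#' @export
tidy.sighub_signature <- function(x, ...) x$partners

#' @export
glance.sighub_signature <- function(x, ...) {
  as_tibble(x$provenance[c("seed_gene", "n_genes", "n_top_quartile_high",
                           "n_contrast", "n_signaling",
                           "n_substrate_expanded", "n_partners")])
}

#' Write / read a signature table
#'
#' The signature is serialized as a tab-delimited per-gene statistics table
#' with the seed gene and filter parameters in `#`-prefixed header lines.
#'
#' @param signature A `sighub_signature`.
#' @param path Output path.
#' @export
write_signature <- function(signature, path) {
  con <- file(path, "w")
  on.exit(close(con))
  p <- signature$provenance
  writeLines(sprintf("# seed_gene=%s min_rho_high=%g alpha=%g percentile=%g",
                     signature$seed_gene, p$min_rho_high, p$alpha,
                     p$percentile), con)
  utils::write.table(signature$partners, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_signature
#' @param path Path to a signature file.
#' @return `read_signature()` returns a list with `seed_gene` and
#'   `partners`.
#' @export
read_signature <- function(path) {
  header <- readLines(path, n = 1)
  if (!startsWith(header, "# seed_gene=")) {
    stop_format(sprintf("%s: not a signature file", path))
  }
  seed <- sub("^# seed_gene=(\\S+).*$", "\\1", header)
  partners <- as_tibble(read.delim(path, sep = "\t", skip = 1,
                                   stringsAsFactors = FALSE))
  structure(list(seed_gene = seed, partners = partners),
            class = "sighub_signature_file")
}
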