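# Scoring any cohort with a hub signature and testing the score as a
# univariate Cox risk factor, plus cross-cohort coexpression summaries.

signature_genes <- function(signature, include_seed = TRUE) {
  if (inherits(signature, c("sighub_signature", "sighub_signature_file"))) {
    genes <- signature$partners$gene
    seed <- signature$seed_gene
  } else if (is.character(signature)) {
    genes <- signature
    seed <- NULL
  } else {
    stop_param("signature must be a sighub_signature or a character vector")
  }
  if (include_seed && !is.null(seed)) genes <- unique(c(seed, genes))
  genes
}

#' Per-sample risk score for a hub signature
#'
#' The reference score is the mean, over the signature genes present in the
#' cohort, of each gene's per-cohort z-score of `log2(x + 1)` expression;
#' this makes the score invariant to per-gene affine rescaling and
#' comparable across cohorts with different normalizations. A
#' mean-of-raw-expression variant is available via `method = "mean"`.
#' Missing genes are reported, never imputed; genes constant across the
#' cohort are excluded from the mean and reported.
#'
#' @param expr Expression matrix.
#' @param signature A `sighub_signature` or character vector of genes.
#' @param include_seed Include the seed gene in the score (default TRUE).
#' @param method `"zscore"` (reference) or `"mean"` (raw expression mean).
#' @return Tibble `sample_id`, `score`, with attributes `n_genes_used`,
#'   `genes_missing`, `genes_constant`.
#' @export
signature_score <- function(expr, signature, include_seed = TRUE,
                            method = c("zscore", "mean")) {
  assert_expression_matrix(expr)
  method <- match.arg(method)
  genes <- signature_genes(signature, include_seed)
  missing <- setdiff(genes, rownames(expr))
  present <- intersect(genes, rownames(expr))
  if (length(present) == 0) {
    stop_coverage("no signature gene present in the expression matrix")
  }
  sub <- expr[present, , drop = FALSE]
  constant <- rownames(sub)[apply(sub, 1, function(r) length(unique(r)) < 2)]
  used <- setdiff(present, constant)
  if (length(used) == 0) {
    stop_coverage("every present signature gene is constant across samples")
  }
  sub <- sub[used, , drop = FALSE]
  score <- if (method == "zscore") {
    lg <- log2(sub + 1)
    z <- (lg - rowMeans(lg)) / apply(lg, 1, sd)
    colMeans(z)
  } else {
    colMeans(sub)
  }
  out <- tibble(sample_id = colnames(expr), score = unname(score))
  attr(out, "n_genes_used") <- length(used)
  attr(out, "genes_missing") <- missing
  attr(out, "genes_constant") <- constant
  out
}

#' Validate a risk score against survival
#'
#' Fits a univariate Cox model on the continuous score and additionally
#' compares the median-split low-risk and high-risk halves by Kaplan-Meier
#' curves and the log-rank test.
#'
#' @param score Tibble `sample_id`, `score` from [signature_score()].
#' @param clinical Clinical tibble.
#' @return A `sighub_risk` object: `cox` (`sighub_cox`), `km_low`,
#'   `km_high` (`sighub_km`), `logrank` (`sighub_test`), `scores` (tibble
#'   with a `risk_group` column), `n_genes_used`, `genes_missing`.
#' @export
cox_risk_validation <- function(score, clinical) {
  assert_clinical(clinical)
  merged <- dplyr::inner_join(score, clinical, by = "sample_id")
  if (nrow(merged) < 4) stop_param("fewer than 4 samples with both score and survival")
  cox <- cox_univariate(merged$os_months, merged$os_event, merged$score)
  grp <- median_split(merged$score)
  lo <- grp == "low"; hi <- grp == "high"
  km_lo <- km_estimate(merged$os_months[lo], merged$os_event[lo])
  km_hi <- km_estimate(merged$os_months[hi], merged$os_event[hi])
  lr <- logrank_test(merged$os_months[hi], merged$os_event[hi],
                     merged$os_months[lo], merged$os_event[lo])
  structure(
    list(cox = cox, km_low = km_lo, km_high = km_hi, logrank = lr,
         scores = mutate(merged, risk_group = grp),
         n_genes_used = attr(score, "n_genes_used"),
         genes_missing = attr(score, "genes_missing")),
    class = "sighub_risk"
  )
}

#' @export
print.sighub_risk <- function(x, ...) {
  cat("Risk-score survival validation\n")
  print(x$cox)
  cat(sprintf("  median-split log-rank: chi-sq = %.3f, p = %s\n",
              x$logrank$statistic, format.pval(x$logrank$p_value, digits = 4)))
  invisible(x)
}

#' @export
tidy.sighub_risk <- function(x, ...) tidy(x$cox)

#' @export
glance.sighub_risk <- function(x, ...) {
  tibble(n = x$cox$n, n.events = x$cox$n_events,
         hazard.ratio = x$cox$hr, cox.p = x$cox$p_value,
         logrank.p = x$logrank$p_value,
         n.genes.used = x$n_genes_used %||% NA_integer_,
         n.genes.missing = length(x$genes_missing %||% character(0)))
}

#' @export
autoplot.sighub_risk <- function(object, ...) {
  curve_df <- function(km, lab) {
    tibble(time = c(0, km$time), survival = c(1, km$survival),
           risk_group = lab)
  }
  df <- bind_rows(curve_df(object$km_low, "low risk"),
                  curve_df(object$km_high, "high risk"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival,
                                   colour = .data$risk_group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Survival probability",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Signature-vs-seed coexpression in another cohort
#'
#' Spearman rho of every signature gene against the seed over all samples
#' of the given cohort (no stratification). Genes absent from the cohort
#' are flagged with `present = FALSE` and `rho = NA`.
#'
#' @param expr Expression matrix of the cohort to profile.
#' @param signature A `sighub_signature` or character vector of partner
#'   genes.
#' @param seed_gene Seed gene symbol (taken from the signature when
#'   omitted).
#' @return Tibble `gene`, `rho`, `present`.
#' @export
cross_dataset_coexpression <- function(expr, signature, seed_gene = NULL) {
  assert_expression_matrix(expr)
  genes <- signature_genes(signature, include_seed = FALSE)
  if (is.null(seed_gene) &&
      inherits(signature, c("sighub_signature", "sighub_signature_file"))) {
    seed_gene <- signature$seed_gene
  }
  if (is.null(seed_gene) || !seed_gene %in% rownames(expr)) {
    stop_key(sprintf("seed gene '%s' absent from the cohort", seed_gene %||% "<NULL>"))
  }
  seed_vals <- expr[seed_gene, ]
  present <- genes %in% rownames(expr)
  rho <- rep(NA_real_, length(genes))
  if (any(present)) {
    rho[present] <- unname(
      spearman_rows(expr[genes[present], , drop = FALSE], seed_vals))
  }
  tibble(gene = genes, rho = rho, present = present)
}
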