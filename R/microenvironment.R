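# Tumor-microenvironment profiling of a signature: correlation with
# cell-type marker genes and rank-based single-sample immune/stromal
# enrichment scores compared between seed-expression strata.

assert_panel <- function(panel) {
  if (!is.data.frame(panel) || !all(c("marker", "cell_type") %in% names(panel))) {
    stop_param("panel must have columns marker, cell_type")
  }
  if (anyDuplicated(panel$marker)) stop_param("marker genes must be unique")
  invisible(panel)
}

#' Default brain-tumor cell-marker panel
#'
#' One canonical marker per microenvironment cell type: GFAP (astrocyte),
#' MBP (oligodendrocyte), TMEM119 (microglia), ALDH1A1 (cancer stem cell),
#' PECAM1 (endothelial), PTPRC (leukocyte), ITGAM (macrophage), CSPG4
#' (pericyte), EPCAM (epithelial).
#'
#' @return Tibble `marker`, `cell_type`.
#' @export
default_marker_panel <- function() {
  tibble(
    marker = c("GFAP", "MBP", "TMEM119", "ALDH1A1", "PECAM1",
               "PTPRC", "ITGAM", "CSPG4", "EPCAM"),
    cell_type = c("astrocyte", "oligodendrocyte", "microglia",
                  "cancer stem cell", "endothelial", "leukocyte",
                  "macrophage", "pericyte", "epithelial")
  )
}

#' Gene-by-marker Spearman correlation matrix
#'
#' Spearman rho of each query gene against each marker gene over all
#' samples. Markers absent from the matrix are dropped with a warning.
#'
#' @param expr Expression matrix (>= 3 samples).
#' @param genes Query gene symbols (e.g. a hub signature).
#' @param panel Tibble `marker`, `cell_type`.
#' @return Long tibble of class `sighub_marker_cor`: `gene`, `marker`,
#'   `cell_type`, `rho`.
#' @export
marker_correlation_matrix <- function(expr, genes, panel = default_marker_panel()) {
  assert_expression_matrix(expr)
  assert_panel(panel)
  if (ncol(expr) < 3) stop_param("need at least 3 samples")
  absent <- setdiff(panel$marker, rownames(expr))
  if (length(absent)) {
    warn(sprintf("marker(s) absent from expression matrix: %s",
                 paste(absent, collapse = ", ")),
         class = "sighub_missing_markers")
  }
  panel <- filter(panel, .data$marker %in% rownames(expr))
  if (nrow(panel) == 0) stop_coverage("no panel marker present in the expression matrix")
  genes <- intersect(genes, rownames(expr))
  if (length(genes) == 0) stop_coverage("no query gene present in the expression matrix")
  out <- tidyr::expand_grid(gene = genes, marker = panel$marker) |>
    left_join(panel, by = "marker")
  out$rho <- purrr::map2_dbl(out$gene, out$marker, function(g, m) {
    r <- tryCatch(spearman_rho(expr[g, ], expr[m, ]),
                  sighub_degenerate_error = function(e) NA_real_)
    r
  })
  class(out) <- c("sighub_marker_cor", class(out))
  out
}

#' @export
autoplot.sighub_marker_cor <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$marker, y = .data$gene,
                                       fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", limits = c(-1, 1)) +
    ggplot2::labs(x = "Cell marker", y = NULL, fill = "Spearman rho") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Seed-vs-marker correlation contrast between strata
#'
#' Spearman rho of the seed gene against each marker, computed separately
#' in the low and high seed-expression strata. Markers constant within a
#' stratum yield `NA` for that stratum.
#'
#' @param expr Expression matrix.
#' @param low_ids,high_ids Sample IDs of the two strata (>= 3 each).
#' @param seed_gene Seed gene symbol.
#' @param panel Tibble `marker`, `cell_type`.
#' @return Tibble `marker`, `cell_type`, `rho_low`, `rho_high`.
#' @export
group_marker_contrast <- function(expr, low_ids, high_ids, seed_gene,
                                  panel = default_marker_panel()) {
  assert_expression_matrix(expr)
  assert_panel(panel)
  if (length(low_ids) < 3 || length(high_ids) < 3) {
    stop_param("each stratum needs at least 3 samples")
  }
  if (!seed_gene %in% rownames(expr)) {
    stop_key(sprintf("seed gene '%s' absent from expression matrix", seed_gene))
  }
  panel <- filter(panel, .data$marker %in% rownames(expr))
  if (nrow(panel) == 0) stop_coverage("no panel marker present")
  rho_in <- function(m, ids) {
    tryCatch(spearman_rho(expr[seed_gene, ids], expr[m, ids]),
             sighub_degenerate_error = function(e) NA_real_)
  }
  panel |>
    mutate(rho_low = map_dbl(.data$marker, rho_in, ids = low_ids),
           rho_high = map_dbl(.data$marker, rho_in, ids = high_ids))
}

ssgsea_one <- function(x, in_set, weight_exponent) {
  r <- midrank(x)                       # high expression -> high rank
  o <- order(r, decreasing = TRUE)
  ind <- in_set[o]
  w <- r[o]^weight_exponent
  # both cumulative distributions are rank-weighted; under random set
  # placement they have the same expected shape, so the score is centred
  p_in <- cumsum(w * ind) / sum(w * ind)
  p_out <- cumsum(w * !ind) / sum(w * !ind)
  sum(p_in - p_out)
}

#' Rank-based single-sample gene-set enrichment score
#'
#' For each sample, genes are ranked by expression (midranks for ties) and
#' the score is the sum over the ranking of the difference between the
#' weighted cumulative distribution of in-set genes (weights
#' `rank^weight_exponent`, normalized by the total in-set weight) and the
#' unweighted cumulative distribution of out-of-set genes. Because only
#' ranks enter, the score is invariant to any strictly monotone transform
#' of a sample's expression. The score scale is the package's own; only
#' comparisons between samples or groups are meaningful.
#'
#' @param expr Expression matrix.
#' @param gene_set Character vector of set genes (those absent from the
#'   matrix are ignored; at least one must be present).
#' @param weight_exponent Rank-weight exponent (default 0.25).
#' @return Tibble `sample_id`, `score`.
#' @export
ssgsea_score <- function(expr, gene_set, weight_exponent = 0.25) {
  assert_expression_matrix(expr)
  in_set <- rownames(expr) %in% gene_set
  if (!any(in_set)) stop_coverage("no gene of the set is present in the matrix")
  if (all(in_set)) stop_param("gene set covers the whole matrix; score undefined")
  scores <- apply(expr, 2, ssgsea_one, in_set = in_set,
                  weight_exponent = weight_exponent)
  tibble(sample_id = colnames(expr), score = unname(scores))
}

#' Immune/stromal/combined enrichment scores
#'
#' Convenience wrapper computing [ssgsea_score()] for an immune and a
#' stromal gene set and their sum as the combined score (the additive
#' convention of expression-based purity scores).
#'
#' @param expr Expression matrix.
#' @param gene_sets Named list with elements `immune` and `stromal` (e.g.
#'   from [read_gene_sets()]).
#' @param weight_exponent Rank-weight exponent (default 0.25).
#' @return Tibble `sample_id`, `immune`, `stromal`, `combined`.
#' @export
estimate_scores <- function(expr, gene_sets, weight_exponent = 0.25) {
  if (!all(c("immune", "stromal") %in% names(gene_sets))) {
    stop_param("gene_sets must contain 'immune' and 'stromal' sets")
  }
  imm <- ssgsea_score(expr, gene_sets$immune, weight_exponent)
  str <- ssgsea_score(expr, gene_sets$stromal, weight_exponent)
  tibble(sample_id = imm$sample_id, immune = imm$score,
         stromal = str$score, combined = imm$score + str$score)
}

#' Compare per-sample scores between strata
#'
#' Welch's t-test of a per-sample score between the low and high
#' seed-expression strata, with the direction of the difference.
#'
#' @param scores Tibble `sample_id`, `score` (or another score column
#'   named by `column`).
#' @param low_ids,high_ids Sample IDs of the strata.
#' @param column Score column name (default `"score"`).
#' @return A `sighub_test` with extra fields `mean_low`, `mean_high`,
#'   `direction` (`higher_in_high` / `higher_in_low`).
#' @export
score_group_comparison <- function(scores, low_ids, high_ids,
                                   column = "score") {
  lo <- scores[[column]][scores$sample_id %in% low_ids]
  hi <- scores[[column]][scores$sample_id %in% high_ids]
  if (length(lo) < 2 || length(hi) < 2) stop_param("each group needs n >= 2")
  w <- welch_t(hi, lo)
  w$mean_low <- mean(lo)
  w$mean_high <- mean(hi)
  w$direction <- if (mean(hi) >= mean(lo)) "higher_in_high" else "higher_in_low"
  w
}
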