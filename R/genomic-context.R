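# Auxiliary genomic screens: dependency-table filtering for essential
# signaling genes and mutation-status association with seed-gene expression.

#' Cell lines dependent on a gene
#'
#' Cell lines whose T-statistic for the given gene is `<= threshold`
#' (the "-0.5 or more negative" selection rule).
#'
#' @param dependencies Tibble `cell_line`, `gene`, `t_statistic`,
#'   `perturbation`.
#' @param gene Gene symbol (must appear in the table).
#' @param threshold Inclusive T-statistic ceiling (default -0.5).
#' @return Tibble of qualifying rows, sorted by `t_statistic` ascending.
#' @export
filter_dependent_lines <- function(dependencies, gene, threshold = -0.5) {
  if (!gene %in% dependencies$gene) {
    stop_key(sprintf("gene '%s' absent from dependency table", gene))
  }
  dependencies |>
    filter(.data$gene == !!gene, .data$t_statistic <= threshold) |>
    arrange(.data$t_statistic)
}

#' Coessential signaling genes
#'
#' Genes with any T-statistic strictly below `threshold` (the "below -3"
#' rule), intersected with the signaling annotation. One hit per gene,
#' carrying its most negative T-statistic and the cell line/perturbation
#' where it was observed; sorted by T ascending.
#'
#' @param dependencies Dependency tibble.
#' @param annotation Long tibble `gene`, `category`.
#' @param threshold Strict T-statistic bound (default -3).
#' @return Tibble `gene`, `cell_line`, `t_statistic`, `perturbation`,
#'   `is_signaling` (always TRUE for emitted hits).
#' @export
coessential_signaling <- function(dependencies, annotation, threshold = -3) {
  signaling <- unique(annotation$gene)
  dependencies |>
    filter(.data$t_statistic < threshold, .data$gene %in% signaling) |>
    group_by(.data$gene) |>
    dplyr::slice_min(.data$t_statistic, n = 1, with_ties = FALSE) |>
    ungroup() |>
    mutate(is_signaling = TRUE) |>
    arrange(.data$t_statistic) |>
    select("gene", "cell_line", "t_statistic", "perturbation", "is_signaling")
}

#' Per-gene alteration frequency by seed-expression group
#'
#' Percent of samples in each group with any status other than WT, per
#' gene; genes whose high-group frequency exceeds the low-group frequency
#' are flagged.
#'
#' @param mutations Tibble `sample_id`, `gene`, `status`.
#' @param low_ids,high_ids Disjoint, non-empty sample-ID groups.
#' @param genes Genes to tabulate (default: all genes in the table).
#' @return Tibble `gene`, `freq_low`, `freq_high` (percent), `flagged`.
#' @export
mutation_frequency_by_group <- function(mutations, low_ids, high_ids,
                                        genes = NULL) {
  if (length(low_ids) == 0 || length(high_ids) == 0) {
    stop_param("both groups must be non-empty")
  }
  if (length(intersect(low_ids, high_ids))) stop_param("groups must be disjoint")
  genes <- genes %||% sort(unique(mutations$gene))
  freq_in <- function(g, ids) {
    sub <- mutations[mutations$gene == g & mutations$sample_id %in% ids, ]
    if (nrow(sub) == 0) return(0)
    100 * mean(sub$status != "WT")
  }
  tibble(gene = genes) |>
    mutate(freq_low = map_dbl(.data$gene, freq_in, ids = low_ids),
           freq_high = map_dbl(.data$gene, freq_in, ids = high_ids),
           flagged = .data$freq_high > .data$freq_low)
}

#' Seed-gene expression compared across mutation-status groups
#'
#' Groups the cohort by the mutation status of `query_gene` and compares
#' the expression of `target_gene` across the status groups: Welch's t for
#' two groups, one-way ANOVA followed by pairwise Welch tests with Holm
#' adjustment for three or more.
#'
#' @param expr Expression matrix.
#' @param mutations Mutation tibble.
#' @param query_gene Gene whose mutation status defines the groups.
#' @param target_gene Gene whose expression is compared (e.g. the seed).
#' @param min_group_n Minimum samples per status group (default 2; smaller
#'   groups are dropped).
#' @return List with `omnibus` (`sighub_test`), `group_means` (tibble
#'   `status`, `n`, `mean`), and `pairwise` (tibble from
#'   [pairwise_welch()], or NULL for two groups).
#' @export
expression_by_mutation <- function(expr, mutations, query_gene, target_gene,
                                   min_group_n = 2) {
  assert_expression_matrix(expr)
  if (!target_gene %in% rownames(expr)) {
    stop_key(sprintf("gene '%s' absent from expression matrix", target_gene))
  }
  mut <- mutations |>
    filter(.data$gene == query_gene,
           .data$sample_id %in% colnames(expr))
  if (nrow(mut) == 0) {
    stop_key(sprintf("gene '%s' absent from mutation table (or no shared samples)",
                     query_gene))
  }
  groups <- split(expr[target_gene, mut$sample_id], mut$status)
  groups <- groups[lengths(groups) >= min_group_n]
  if (length(groups) < 2) {
    stop_degenerate("fewer than 2 mutation-status groups with enough samples")
  }
  means <- tibble(status = names(groups),
                  n = lengths(groups),
                  mean = map_dbl(groups, mean))
  if (length(groups) == 2) {
    omnibus <- welch_t(groups[[1]], groups[[2]])
    pairwise <- NULL
  } else {
    omnibus <- one_way_anova(groups)
    pairwise <- pairwise_welch(groups)
  }
  list(omnibus = omnibus, group_means = means, pairwise = pairwise)
}
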