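# Readers and writers for every external table the pipeline touches.
# Everything is plain tab-delimited text; validation is strict and format
# errors name the offending line. Gene symbols are case-sensitive and never
# remapped (users pre-harmonize aliases).

SIGNALING_CATEGORIES <- c("GPCR", "RTK", "STK", "DK", "TyrK",
                          "PPP", "PTP", "DSP", "agonist", "adaptor")
MUTATION_STATUSES <- c("WT", "MT", "AMP", "DEL")
PERTURBATION_TYPES <- c("crispr", "rnai", "compound")

check_rectangular <- function(path) {
  nf <- count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(nf) == 0) return(invisible(0L))
  bad <- which(nf != nf[1])
  if (length(bad)) {
    stop_format(sprintf("%s: line %d has %d fields, expected %d",
                        path, bad[1], nf[bad[1]], nf[1]))
  }
  invisible(length(nf))
}

read_tsv_strict <- function(path, required_cols) {
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  check_rectangular(path)
  df <- read.delim(path, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, quote = "",
                   comment.char = "")
  missing <- setdiff(required_cols, names(df))
  if (length(missing)) {
    stop_format(sprintf("%s: missing required column(s): %s",
                        path, paste(missing, collapse = ", ")))
  }
  as_tibble(df)
}

#' Read a gene x sample expression matrix
#'
#' Tab-delimited, first column gene symbols, header row of sample IDs,
#' non-negative finite values. Duplicated gene symbols, negative values and
#' ragged rows are rejected with the offending line named.
#'
#' @param path Path to a tab-delimited file.
#' @return Numeric matrix (genes x samples) with gene symbols as rownames
#'   and sample IDs as colnames.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  check_rectangular(path)
  df <- read.delim(path, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, quote = "", comment.char = "")
  genes <- as.character(df[[1]])
  dup <- which(duplicated(genes))
  if (length(dup)) {
    stop_format(sprintf("%s: line %d duplicates gene symbol '%s'",
                        path, dup[1] + 1L, genes[dup[1]]))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad_row <- which(apply(df[, -1, drop = FALSE], 1,
                           function(r) anyNA(suppressWarnings(as.numeric(r)))))
    stop_format(sprintf("%s: line %d contains a non-numeric value",
                        path, (if (length(bad_row)) bad_row[1] else 1) + 1L))
  }
  storage.mode(m) <- "double"
  if (anyNA(m) || any(!is.finite(m))) {
    bad <- which(apply(m, 1, function(r) any(!is.finite(r))))[1]
    stop_format(sprintf("%s: line %d contains a missing/non-finite value",
                        path, bad + 1L))
  }
  neg <- which(apply(m, 1, function(r) any(r < 0)))
  if (length(neg)) {
    stop_format(sprintf("%s: line %d contains a negative value", path, neg[1] + 1L))
  }
  rownames(m) <- genes
  if (anyDuplicated(colnames(m))) stop_format(sprintf("%s: duplicated sample IDs", path))
  assert_expression_matrix(m)
}

#' Write an expression matrix
#'
#' @param expr Genes x samples matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly. Round-trips through [read_expression()] at
#'   full precision.
#' @export
write_expression <- function(expr, path) {
  assert_expression_matrix(expr)
  df <- data.frame(gene_symbol = rownames(expr),
                   format(expr, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

parse_event_status <- function(status, path) {
  s <- trimws(as.character(status))
  out <- dplyr::case_when(
    s %in% c("1", "1:DECEASED", "DECEASED") ~ 1,
    s %in% c("0", "0:LIVING", "LIVING") ~ 0,
    .default = NA_real_
  )
  bad <- which(is.na(out))
  if (length(bad)) {
    stop_format(sprintf("%s: line %d has unknown status token '%s'",
                        path, bad[1] + 1L, s[bad[1]]))
  }
  out
}

#' Read a clinical overall-survival table
#'
#' Expects columns `sample_id`, `os_months`, `os_event` (alias column names
#' `OS_MONTHS`/`OS_STATUS` from cBioPortal-style exports are accepted). The
#' status dialects `1:DECEASED`/`0:LIVING` and bare `0`/`1` both map to a
#' 0/1 event indicator.
#'
#' @param path Tab-delimited file.
#' @return Tibble with `sample_id`, `os_months`, `os_event`.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  check_rectangular(path)
  df <- read.delim(path, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, quote = "", comment.char = "")
  alias <- c(sample_id = "SAMPLE_ID", os_months = "OS_MONTHS",
             os_event = "OS_STATUS")
  for (nm in names(alias)) {
    if (!nm %in% names(df) && alias[[nm]] %in% names(df)) {
      names(df)[names(df) == alias[[nm]]] <- nm
    }
  }
  missing <- setdiff(c("sample_id", "os_months", "os_event"), names(df))
  if (length(missing)) {
    stop_format(sprintf("%s: missing required column(s): %s",
                        path, paste(missing, collapse = ", ")))
  }
  months <- suppressWarnings(as.numeric(df$os_months))
  bad <- which(is.na(months) | months < 0)
  if (length(bad)) {
    stop_format(sprintf("%s: line %d has invalid os_months '%s'",
                        path, bad[1] + 1L, df$os_months[bad[1]]))
  }
  out <- tibble(sample_id = as.character(df$sample_id),
                os_months = months,
                os_event = parse_event_status(df$os_event, path))
  if (anyDuplicated(out$sample_id)) {
    stop_format(sprintf("%s: duplicated sample IDs", path))
  }
  out
}

#' Write a clinical table
#' @param clinical Tibble with `sample_id`, `os_months`, `os_event`.
#' @param path Output path.
#' @export
write_clinical <- function(clinical, path) {
  assert_clinical(clinical)
  write.table(clinical[, c("sample_id", "os_months", "os_event")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, `name<TAB>description<TAB>gene...`.
#' Genes are deduplicated within a set; set order is preserved.
#'
#' @param path GMT file.
#' @return Named list of character vectors.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(setNames(list(), character(0)))
  nf <- lengths(strsplit(lines, "\t", fixed = TRUE))
  bad <- which(nf < 3)
  if (length(bad)) {
    stop_format(sprintf("%s: line %d has %d field(s), GMT needs at least 3",
                        path, bad[1], nf[bad[1]]))
  }
  sets <- fgsea::gmtPathways(path)
  lapply(sets, unique)
}

#' Write gene sets in GMT format
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @export
write_gene_sets <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a signaling-category gene annotation
#'
#' Tab-delimited with columns `gene_symbol` and `categories`
#' (semicolon-separated labels from the controlled vocabulary:
#' `r paste(SIGNALING_CATEGORIES, collapse = ", ")`).
#'
#' @param path Tab-delimited file.
#' @param vocabulary Allowed category labels.
#' @return Long tibble `gene`, `category` (one row per gene-category pair).
#' @export
read_annotation <- function(path, vocabulary = SIGNALING_CATEGORIES) {
  df <- read_tsv_strict(path, c("gene_symbol", "categories"))
  out <- df |>
    mutate(gene = as.character(.data$gene_symbol),
           category = strsplit(as.character(.data$categories), ";", fixed = TRUE)) |>
    select("gene", "category") |>
    tidyr::unnest("category") |>
    mutate(category = trimws(.data$category)) |>
    dplyr::distinct()
  bad <- setdiff(unique(out$category), vocabulary)
  if (length(bad)) {
    stop_format(sprintf("%s: unknown annotation categor%s: %s", path,
                        if (length(bad) > 1) "ies" else "y",
                        paste(bad, collapse = ", ")))
  }
  out
}

#' Write a signaling annotation
#' @param annotation Long tibble `gene`, `category`.
#' @param path Output path.
#' @export
write_annotation <- function(annotation, path) {
  wide <- annotation |>
    group_by(.data$gene) |>
    summarise(categories = paste(.data$category, collapse = ";"),
              .groups = "drop") |>
    rename(gene_symbol = "gene")
  write.table(wide, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a kinase-substrate map
#'
#' Tab-delimited with columns `kinase` and `substrates`
#' (semicolon-separated). Empty substrate sets are allowed.
#'
#' @param path Tab-delimited file.
#' @return Named list: kinase gene symbol -> character vector of substrates.
#' @export
read_kinase_substrates <- function(path) {
  df <- read_tsv_strict(path, c("kinase", "substrates"))
  subs <- strsplit(as.character(df$substrates), ";", fixed = TRUE)
  subs <- lapply(subs, function(s) unique(trimws(s[nzchar(trimws(s))])))
  setNames(subs, as.character(df$kinase))
}

#' Write a kinase-substrate map
#' @param ks_map Named list kinase -> substrates.
#' @param path Output path.
#' @export
write_kinase_substrates <- function(ks_map, path) {
  df <- tibble(kinase = names(ks_map),
               substrates = vapply(ks_map, paste, character(1), collapse = ";"))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-sample mutation-status table
#'
#' Columns `sample_id`, `gene`, `status` with status in
#' `WT`, `MT`, `AMP`, `DEL`; one status per (sample, gene).
#'
#' @param path Tab-delimited file.
#' @return Tibble `sample_id`, `gene`, `status`.
#' @export
read_mutations <- function(path) {
  df <- read_tsv_strict(path, c("sample_id", "gene", "status"))
  bad <- which(!df$status %in% MUTATION_STATUSES)
  if (length(bad)) {
    stop_format(sprintf("%s: line %d has unknown mutation status '%s'",
                        path, bad[1] + 1L, df$status[bad[1]]))
  }
  if (anyDuplicated(df[, c("sample_id", "gene")])) {
    stop_format(sprintf("%s: duplicated (sample, gene) pair", path))
  }
  mutate(df, sample_id = as.character(.data$sample_id),
         gene = as.character(.data$gene))
}

#' Write a mutation table
#' @param mutations Tibble `sample_id`, `gene`, `status`.
#' @param path Output path.
#' @export
write_mutations <- function(mutations, path) {
  write.table(mutations, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a dependency-screen table
#'
#' Columns `cell_line`, `gene`, `t_statistic` (finite), `perturbation`
#' (one of `crispr`, `rnai`, `compound`).
#'
#' @param path Tab-delimited file.
#' @return Tibble `cell_line`, `gene`, `t_statistic`, `perturbation`.
#' @export
read_dependencies <- function(path) {
  df <- read_tsv_strict(path, c("cell_line", "gene", "t_statistic", "perturbation"))
  tval <- suppressWarnings(as.numeric(df$t_statistic))
  bad <- which(is.na(tval) | !is.finite(tval))
  if (length(bad)) {
    stop_format(sprintf("%s: line %d has non-finite t_statistic '%s'",
                        path, bad[1] + 1L, df$t_statistic[bad[1]]))
  }
  badp <- which(!df$perturbation %in% PERTURBATION_TYPES)
  if (length(badp)) {
    stop_format(sprintf("%s: line %d has unknown perturbation '%s'",
                        path, badp[1] + 1L, df$perturbation[badp[1]]))
  }
  tibble(cell_line = as.character(df$cell_line),
         gene = as.character(df$gene),
         t_statistic = tval,
         perturbation = as.character(df$perturbation))
}

#' Write a dependency table
#' @param dependencies Tibble as returned by [read_dependencies()].
#' @param path Output path.
#' @export
write_dependencies <- function(dependencies, path) {
  write.table(dependencies, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Report samples shared between expression and clinical tables
#'
#' Joins are by sample ID; samples present in one table but not the other
#' are reported, never silently dropped.
#'
#' @param expr Expression matrix.
#' @param clinical Clinical tibble.
#' @return List with `shared`, `expr_only`, `clinical_only` ID vectors.
#' @export
match_samples <- function(expr, clinical) {
  assert_expression_matrix(expr)
  assert_clinical(clinical)
  list(shared = intersect(colnames(expr), clinical$sample_id),
       expr_only = setdiff(colnames(expr), clinical$sample_id),
       clinical_only = setdiff(clinical$sample_id, colnames(expr)))
}
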