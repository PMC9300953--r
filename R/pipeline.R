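# End-to-end orchestration: a declarative config drives discovery ->
# validation -> microenvironment -> genomic context, with a reproducibility
# manifest recording input checksums, parameters and per-stage gene counts.
# make_fixture() writes complete small cohorts for tests and documentation.

FIXTURE_PRESETS <- c("null", "planted_hub", "planted_hub_with_validation")

fixture_params <- function(preset, rng_seed) {
  base <- list(n_samples = 200, n_genes = 800, n_partners = 10,
               rho_high = 0.5, rho_low = 0.05, beta = 1.0,
               baseline_scale = 60, weibull_shape = 1.2,
               censor_frac = 0.3, frac_signaling = 0.2,
               rng_seed = rng_seed)
  if (preset == "null") {
    base$n_partners <- 0
    base$beta <- 0
  }
  do.call(cohort_params, base)
}

write_cohort_files <- function(cohort, out_dir, prefix = "") {
  p <- function(name) file.path(out_dir, paste0(prefix, name))
  write_expression(cohort$expression, p("expression.tsv"))
  write_clinical(cohort$clinical, p("clinical.tsv"))
  write_annotation(cohort$annotation, p("annotation.tsv"))
  jsonlite::write_json(
    list(seed_gene = cohort$truth$seed_gene,
         partner_genes = cohort$truth$partner_genes),
    p("truth.json"), auto_unbox = TRUE)
  invisible(out_dir)
}

#' Write a complete fixture cohort to disk
#'
#' Presets: `null` (no planted hub, no survival effect), `planted_hub`
#' (10-partner hub, stratum-dependent coexpression, hazard driven by the
#' hub), and `planted_hub_with_validation` (adds a second independent
#' cohort sharing the planted hub structure, for cross-cohort validation).
#' All files are tab-delimited and round-trip through the package readers.
#'
#' @param out_dir Output directory (created if needed).
#' @param preset One of `r paste(FIXTURE_PRESETS, collapse = ", ")`.
#' @param rng_seed Integer RNG seed; identical seeds give identical files.
#' @return Invisibly, the list of files written.
#' @export
make_fixture <- function(out_dir, preset = "planted_hub", rng_seed = 1L) {
  if (!preset %in% FIXTURE_PRESETS) {
    stop_param(sprintf("unknown preset '%s' (choose from: %s)", preset,
                       paste(FIXTURE_PRESETS, collapse = ", ")))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- generate_cohort(fixture_params(preset, rng_seed))
  write_cohort_files(cohort, out_dir)
  if (preset == "planted_hub_with_validation") {
    params2 <- fixture_params("planted_hub", rng_seed + 1000L)
    write_cohort_files(generate_cohort(params2), out_dir, prefix = "validation_")
  }
  invisible(list.files(out_dir, full.names = TRUE))
}

default_config <- function() {
  list(
    expression = NULL, clinical = NULL, annotation = NULL,
    validation_expression = NULL, validation_clinical = NULL,
    kinase_substrates = NULL, markers = NULL, gene_sets = NULL,
    dependencies = NULL, mutations = NULL,
    seed_gene = NULL, percentile = 50, min_rho_high = 0.2, alpha = 0.05,
    score_method = "zscore", include_seed = TRUE,
    dependency_threshold = -0.5, coessential_threshold = -3,
    out_dir = "sighub_out"
  )
}

#' Assemble (or load) a pipeline configuration
#'
#' Either pass a YAML file path or named overrides. Defaults mirror the
#' reference analysis: 50:50 stratification, contrast threshold 0.2,
#' survival alpha 0.05, dependency thresholds -0.5 (inclusive) and -3
#' (strict).
#'
#' @param path Optional YAML configuration file.
#' @param ... Named overrides of configuration fields.
#' @return Named list of class `sighub_config`.
#' @export
sighub_config <- function(path = NULL, ...) {
  cfg <- default_config()
  if (!is.null(path)) {
    loaded <- yaml::read_yaml(path)
    unknown <- setdiff(names(loaded), names(cfg))
    if (length(unknown)) {
      stop_param(sprintf("unknown configuration field(s): %s",
                         paste(unknown, collapse = ", ")))
    }
    cfg[names(loaded)] <- loaded
  }
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown)) {
    stop_param(sprintf("unknown configuration field(s): %s",
                       paste(unknown, collapse = ", ")))
  }
  cfg[names(overrides)] <- overrides
  structure(cfg, class = c("sighub_config", "list"))
}

md5_of <- function(paths) {
  paths <- paths[!vapply(paths, is.null, logical(1))]
  paths <- unlist(paths)
  if (length(paths) == 0) return(list())
  as.list(tools::md5sum(paths))
}

run_stage <- function(manifest, name, fun) {
  res <- tryCatch(fun(), error = function(e) e)
  if (inherits(res, "error")) {
    manifest$status <- "failed"
    manifest$failed_stage <- name
    manifest$error <- conditionMessage(res)
    attr(manifest, "failed") <- TRUE
  } else {
    manifest$stages[[name]] <- res
  }
  manifest
}

#' Run the full pipeline from a configuration
#'
#' Stages run in order (discover, validate, microenvironment, context);
#' each stage's outputs are written before the next starts, so partial
#' outputs survive a failing stage. The manifest records input checksums,
#' parameters, per-stage gene counts and the package version.
#'
#' @param config A [sighub_config()] (or YAML path).
#' @return The manifest list, invisibly; `manifest$status` is `"ok"` or
#'   `"failed"` (with `failed_stage` naming the failing stage). The
#'   manifest is also written to `<out_dir>/manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- sighub_config(config)
  cfg <- config
  for (f in c("expression", "clinical", "annotation")) {
    if (is.null(cfg[[f]])) stop_param(sprintf("config field '%s' is required", f))
  }
  if (is.null(cfg$seed_gene)) stop_param("config field 'seed_gene' is required")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  input_paths <- cfg[c("expression", "clinical", "annotation",
                       "validation_expression", "validation_clinical",
                       "kinase_substrates", "markers", "gene_sets",
                       "dependencies", "mutations")]
  manifest <- list(
    package_version = as.character(packageVersion("sighub")),
    parameters = cfg[c("seed_gene", "percentile", "min_rho_high", "alpha",
                       "score_method", "include_seed",
                       "dependency_threshold", "coessential_threshold")],
    inputs = md5_of(input_paths),
    status = "ok", stages = list()
  )

  expr <- NULL; clinical <- NULL; annotation <- NULL; sig <- NULL
  strata <- NULL

  manifest <- run_stage(manifest, "load", function() {
    expr <<- read_expression(cfg$expression)
    clinical <<- read_clinical(cfg$clinical)
    annotation <<- read_annotation(cfg$annotation)
    sm <- match_samples(expr, clinical)
    list(n_genes = nrow(expr), n_samples = ncol(expr),
         n_clinical = nrow(clinical),
         n_shared = length(sm$shared),
         expr_only = sm$expr_only, clinical_only = sm$clinical_only)
  })

  if (is.null(attr(manifest, "failed"))) {
    manifest <- run_stage(manifest, "discover", function() {
      ks <- if (!is.null(cfg$kinase_substrates))
        read_kinase_substrates(cfg$kinase_substrates) else NULL
      sig <<- build_hub_signature(
        expr, clinical, annotation, cfg$seed_gene,
        min_rho_high = cfg$min_rho_high, alpha = cfg$alpha,
        percentile = cfg$percentile, ks_map = ks)
      strata <<- stratify_by_seed(expr, cfg$seed_gene, cfg$percentile)
      write_signature(sig, file.path(cfg$out_dir, "signature.tsv"))
      jsonlite::write_json(sig$provenance,
                           file.path(cfg$out_dir, "provenance.json"),
                           auto_unbox = TRUE)
      sig$provenance
    })
  }

  if (is.null(attr(manifest, "failed"))) {
    manifest <- run_stage(manifest, "validate", function() {
      v_expr <- if (!is.null(cfg$validation_expression))
        read_expression(cfg$validation_expression) else expr
      v_clin <- if (!is.null(cfg$validation_clinical))
        read_clinical(cfg$validation_clinical) else clinical
      if (nrow(sig$partners) == 0) {
        return(list(skipped = "empty signature"))
      }
      sc <- signature_score(v_expr, sig, include_seed = cfg$include_seed,
                            method = cfg$score_method)
      risk <- cox_risk_validation(sc, v_clin)
      write.table(risk$scores, file.path(cfg$out_dir, "risk_scores.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(tidy(risk$cox), file.path(cfg$out_dir, "cox_summary.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      km_df <- bind_rows(
        mutate(as_tibble(risk$km_low), risk_group = "low"),
        mutate(as_tibble(risk$km_high), risk_group = "high"))
      write.table(km_df, file.path(cfg$out_dir, "km_coordinates.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      as.list(glance(risk))
    })
  }

  if (is.null(attr(manifest, "failed")) &&
      (!is.null(cfg$markers) || !is.null(cfg$gene_sets))) {
    manifest <- run_stage(manifest, "microenvironment", function() {
      out <- list()
      if (!is.null(cfg$markers)) {
        panel <- read_tsv_strict(cfg$markers, c("marker", "cell_type"))
        genes <- c(cfg$seed_gene, sig$partners$gene)
        mc <- marker_correlation_matrix(expr, genes, panel)
        write.table(mc, file.path(cfg$out_dir, "marker_correlations.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        gc <- group_marker_contrast(expr, strata$low, strata$high,
                                    cfg$seed_gene, panel)
        write.table(gc, file.path(cfg$out_dir, "marker_contrast.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        out$n_markers <- nrow(gc)
      }
      if (!is.null(cfg$gene_sets)) {
        sets <- read_gene_sets(cfg$gene_sets)
        scores <- purrr::imap(sets, function(s, nm) {
          sc <- ssgsea_score(expr, s)
          names(sc)[2] <- nm
          sc
        }) |> purrr::reduce(left_join, by = "sample_id")
        write.table(scores, file.path(cfg$out_dir, "enrichment_scores.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        comps <- purrr::map(names(sets), function(nm) {
          ct <- score_group_comparison(scores, strata$low, strata$high,
                                       column = nm)
          tibble(set = nm, statistic = ct$statistic, p.value = ct$p_value,
                 direction = ct$direction)
        }) |> bind_rows()
        write.table(comps, file.path(cfg$out_dir, "enrichment_contrast.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        out$n_gene_sets <- length(sets)
      }
      out
    })
  }

  if (is.null(attr(manifest, "failed")) &&
      (!is.null(cfg$dependencies) || !is.null(cfg$mutations))) {
    manifest <- run_stage(manifest, "context", function() {
      out <- list()
      if (!is.null(cfg$dependencies)) {
        dep <- read_dependencies(cfg$dependencies)
        hits <- coessential_signaling(dep, annotation,
                                      cfg$coessential_threshold)
        write.table(hits, file.path(cfg$out_dir, "coessential_hits.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        out$n_coessential <- nrow(hits)
      }
      if (!is.null(cfg$mutations)) {
        mut <- read_mutations(cfg$mutations)
        freq <- mutation_frequency_by_group(mut, strata$low, strata$high)
        write.table(freq, file.path(cfg$out_dir, "mutation_frequencies.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        out$n_mutation_genes <- nrow(freq)
      }
      out
    })
  }

  attr(manifest, "failed") <- NULL
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
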