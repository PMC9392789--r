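# End-to-end orchestration: synthesise or ingest a cohort, filter, score,
# baseline-correct, classify quadrants, compare groups at the mutation, arm
# and expression/pathway level, and write one TSV per stage plus a
# machine-readable run report.

#' Build a pipeline run configuration
#'
#' Every threshold defaults to the convention used throughout the package:
#' minimum group size 10, quadrant cut 0.5, mutation/arm and DE FDR 5%,
#' enrichment FDR 10%, log2 fold-change cut 2, correlation reference 0.3.
#'
#' @param synthetic A [synthetic_config()] to generate the cohort from, or
#'   `NULL` to read inputs from `input_dir` (files as written by
#'   [write_cohort()]).
#' @param input_dir Directory of input files when `synthetic` is `NULL`.
#' @param group1,group2 Cancer-type codes of the comparison groups; defaults
#'   follow [group_assignment()].
#' @param min_group_size,quadrant_threshold,outlier_alpha,fdr_genomic,fdr_de,
#'   fdr_gsea,lfc,rho_ref,n_perm Analysis parameters.
#' @param covariate_gene Continuous covariate gene for the DE design
#'   (default `"ESR1"`; `NULL` to omit).
#' @param seed Integer seed governing every stochastic stage.
#' @return A list of class `bccs_run_config`.
#' @export
run_config <- function(synthetic = synthetic_config(),
                       input_dir = NULL,
                       group1 = c("HNSC", "KICH", "KIRP", "UCEC"),
                       group2 = c("CESC", "OV", "UCS"),
                       min_group_size = 10,
                       quadrant_threshold = 0.5,
                       outlier_alpha = 0.001,
                       fdr_genomic = 0.05,
                       fdr_de = 0.05,
                       fdr_gsea = 0.10,
                       lfc = 2,
                       rho_ref = 0.3,
                       n_perm = 1000,
                       covariate_gene = "ESR1",
                       seed = 17L) {
  if (is.null(synthetic) && is.null(input_dir)) {
    .stop("either a synthetic config or an input directory is required")
  }
  for (th in c(quadrant_threshold, outlier_alpha, fdr_genomic, fdr_de, fdr_gsea)) {
    .assert_scalar_number(th, "threshold", 1e-12, 1 - 1e-12)
  }
  if (lfc < 0) .stop("lfc must be >= 0")
  groups <- group_assignment(group1, group2)  # validates disjointness up front
  structure(
    list(synthetic = synthetic, input_dir = input_dir, groups = groups,
         min_group_size = min_group_size,
         quadrant_threshold = quadrant_threshold,
         outlier_alpha = outlier_alpha, fdr_genomic = fdr_genomic,
         fdr_de = fdr_de, fdr_gsea = fdr_gsea, lfc = lfc, rho_ref = rho_ref,
         n_perm = n_perm, covariate_gene = covariate_gene,
         seed = as.integer(seed)),
    class = "bccs_run_config"
  )
}

.read_cohort_dir <- function(dir) {
  expr_path <- if (file.exists(file.path(dir, "expression.tsv"))) {
    list(path = file.path(dir, "expression.tsv"), format = "tsv")
  } else {
    list(path = file.path(dir, "expression.mtx"), format = "mtx")
  }
  list(
    manifest = read_manifest(file.path(dir, "manifest.tsv")),
    expression = read_expression(expr_path$path, expr_path$format),
    purity = read_purity(file.path(dir, "purity.tsv")),
    mutations = read_mutations(file.path(dir, "mutations.tsv")),
    arm_calls = read_arm_calls(file.path(dir, "arm_calls.tsv")),
    gene_sets = read_gmt(file.path(dir, "gene_sets.gmt")),
    truth = NULL
  )
}

#' Run the full pipeline
#'
#' Executes the stages in cohort order — filter, score, baseline-correct,
#' purity-adjust, quadrant-classify, compare mutations and arm calls,
#' differential expression, preranked enrichment, score-correlation — and
#' writes one TSV per stage plus `report.json` under `outdir`. Reruns with
#' the same config are identical for every deterministic stage.
#'
#' @param config A [run_config()].
#' @param outdir Output directory (created if needed). `NULL` skips writing.
#' @return A list of class `bccs_run` with all stage results and a `report`
#'   element (stage log, counts, thresholds, seed).
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (!inherits(config, "bccs_run_config")) .stop("config must come from run_config()")
  log <- list()
  note <- function(stage, ...) {
    log[[length(log) + 1L]] <<- c(list(stage = stage), list(...))
  }

  cohort <- if (!is.null(config$synthetic)) {
    generate_cohort(config$synthetic)
  } else {
    .read_cohort_dir(config$input_dir)
  }
  note("input", n_samples = nrow(cohort$manifest), n_genes = nrow(cohort$expression))

  # groups restricted to what the cohort actually contains
  present <- unique(cohort$manifest$cancer_type[cohort$manifest$study == "TCGA_TUMOR"])
  groups <- group_assignment(intersect(config$groups$group1, present),
                             intersect(config$groups$group2, present))

  filtered <- apply_consort_filters(cohort$manifest)
  manifest <- apply_small_group_rule(filtered$manifest, config$min_group_size)
  note("filter", n_remaining = nrow(manifest))
  manifest <- manifest[manifest$sample_id %in% colnames(cohort$expression), ,
                       drop = FALSE]
  expr <- cohort$expression[, manifest$sample_id, drop = FALSE]

  signature <- cohort$gene_sets$CCS
  scores <- compute_signature_score(expr, signature, name = "CCS") |>
    minmax_rescale()
  note("score", n_genes_used = attr(scores, "n_genes_used"))

  baselines <- compute_baselines(scores, manifest)
  bc <- compute_bc_ccs(scores, baselines, manifest) |>
    adjust_for_purity(cohort$purity) |>
    minmax_rescale(from = "bc_purity_adjusted", to = "bc_scaled")
  quadrants <- classify_quadrants(scores, scores, manifest,
                                  config$quadrant_threshold)
  note("baseline_correction", n_tumors = nrow(bc), n_tissues = nrow(quadrants))

  mut_res <- compare_mutations(cohort$mutations, manifest, groups)
  arm_res <- compare_arm_calls(cohort$arm_calls, manifest, groups)
  note("genomic_comparison",
       n_mut_enriched = nrow(higher_in_g2(mut_res, config$fdr_genomic)),
       n_arm_enriched = nrow(higher_in_g2(arm_res, config$fdr_genomic)))

  de <- fit_moderated_de(expr, manifest, groups,
                         covariate_gene = config$covariate_gene,
                         lfc = config$lfc, fdr = config$fdr_de)
  parts <- volcano_partition(de)
  ranks <- rank_statistic(de)
  gsea <- preranked_gsea(ranks, cohort$gene_sets, n_perm = config$n_perm,
                         seed = config$seed)
  note("de_enrichment", n_up = length(parts$up), n_down = length(parts$down),
       n_sets_tested = nrow(gsea))

  de_genes <- unique(c(parts$up, parts$down))
  correlations <- if (length(de_genes) >= 1) {
    correlate_genes_to_bccs(expr, bc, de_genes, rho_ref = config$rho_ref)
  } else {
    tibble(gene_id = character(), rho = double(), p = double(),
           passes_reference_line = logical())
  }

  report <- list(
    seed = config$seed,
    thresholds = config[c("min_group_size", "quadrant_threshold", "fdr_genomic",
                          "fdr_de", "fdr_gsea", "lfc", "rho_ref")],
    groups = unclass(groups),
    filter_report = filtered$report,
    stages = log
  )
  run <- structure(
    list(manifest = manifest, scores = scores, baselines = baselines, bc = bc,
         quadrants = quadrants, mutations = mut_res, arms = arm_res, de = de,
         gsea = gsea, correlations = correlations, report = report,
         truth = cohort$truth),
    class = "bccs_run"
  )

  if (!is.null(outdir)) .write_run(run, outdir)
  run
}

.write_run <- function(run, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  readr::write_tsv(run$manifest, file.path(outdir, "manifest_filtered.tsv"))
  readr::write_tsv(as_tibble(run$scores), file.path(outdir, "scores.tsv"))
  readr::write_tsv(run$baselines, file.path(outdir, "baselines.tsv"))
  readr::write_tsv(run$bc, file.path(outdir, "bc_scores.tsv"))
  readr::write_tsv(as_tibble(run$quadrants), file.path(outdir, "quadrants.tsv"))
  readr::write_tsv(run$mutations, file.path(outdir, "mutation_comparison.tsv"))
  readr::write_tsv(run$arms, file.path(outdir, "arm_comparison.tsv"))
  readr::write_tsv(run$de$results, file.path(outdir, "de_results.tsv"))
  gsea_flat <- run$gsea |>
    mutate(leading_edge = vapply(.data$leading_edge, paste, character(1),
                                 collapse = ",")) |>
    as_tibble()
  readr::write_tsv(gsea_flat, file.path(outdir, "gsea_results.tsv"))
  readr::write_tsv(run$correlations, file.path(outdir, "bccs_correlations.tsv"))
  report <- run$report
  report$filter_report <- as_tibble(report$filter_report)
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(outdir)
}

#' @export
print.bccs_run <- function(x, ...) {
  cat("bccs pipeline run\n")
  cat(sprintf("  samples: %d (%d tumours)\n", nrow(x$manifest),
              sum(x$manifest$study == "TCGA_TUMOR")))
  cat(sprintf("  tissues in quadrant plot: %d\n", nrow(x$quadrants)))
  cat(sprintf("  DE: %d significant genes; GSEA: %d sets tested\n",
              sum(x$de$results$significant), nrow(x$gsea)))
  invisible(x)
}
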