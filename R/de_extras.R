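# Group t-tests on module scores and per-gene Spearman correlation of
# expression to the corrected score.

# q value -> conventional significance stars
.stars <- function(q) {
  cut(q, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 0.05, Inf),
      labels = c("****", "***", "**", "*", "ns"))
}

#' Two-sample t-tests on module scores between groups
#'
#' For each module, a two-sided two-sample Student's t-test of the module
#' score between Group 1 and Group 2 tumours, with BH-FDR across the tested
#' modules and conventional significance stars mapped from q.
#'
#' @param module_scores Named list of `bccs_scores` tibbles (one per
#'   module), or a single `bccs_scores` tibble.
#' @param manifest A manifest tibble.
#' @param groups A [group_assignment()].
#' @param var_equal Assume equal variances (classic Student test, default
#'   `TRUE`).
#' @return Tibble with one row per module: `module`, `mean_g1`, `mean_g2`,
#'   `t`, `p`, `q`, `stars`.
#' @export
module_ttests <- function(module_scores, manifest, groups, var_equal = TRUE) {
  validate_manifest(manifest)
  if (inherits(module_scores, "bccs_scores") || is.data.frame(module_scores)) {
    nm <- attr(module_scores, "signature_name") %||% "module"
    module_scores <- setNames(list(module_scores), nm)
  }
  g1_ids <- manifest$sample_id[manifest$study == "TCGA_TUMOR" &
                                 manifest$cancer_type %in% groups$group1]
  g2_ids <- manifest$sample_id[manifest$study == "TCGA_TUMOR" &
                                 manifest$cancer_type %in% groups$group2]
  res <- purrr::map_dfr(names(module_scores), function(nm) {
    sc <- as_tibble(module_scores[[nm]])
    x1 <- sc$raw_score[sc$sample_id %in% g1_ids]
    x2 <- sc$raw_score[sc$sample_id %in% g2_ids]
    if (length(x1) < 2 || length(x2) < 2) .stop("each group needs >= 2 scored samples")
    if (sd(x1) == 0 && sd(x2) == 0) {
      if (mean(x1) == mean(x2)) {
        return(tibble(module = nm, mean_g1 = mean(x1), mean_g2 = mean(x2),
                      t = 0, p = 1))
      }
      .stop("zero within-group variance in both groups")
    }
    tt <- t.test(x2, x1, var.equal = var_equal)
    tibble(module = nm, mean_g1 = mean(x1), mean_g2 = mean(x2),
           t = unname(tt$statistic), p = tt$p.value)
  })
  res$q <- benjamini_hochberg(res$p)
  res$stars <- .stars(res$q)
  res
}

#' Correlate gene expression to the corrected score
#'
#' Spearman rank correlation of each gene's expression with the
#' baseline-corrected score over the shared samples, flagging genes above
#' the conventional reference line of rho > 0.3. Constant genes have no
#' defined rank correlation and are reported with `rho = NA` and a warning.
#'
#' @param expr Genes x samples expression matrix.
#' @param bc Output of [compute_bc_ccs()] or [adjust_for_purity()]; the
#'   column named by `score_col` is used.
#' @param genes Gene ids to correlate (default: all genes in `expr`).
#' @param score_col Score column in `bc` (default `"bc_raw"`).
#' @param rho_ref Reference line (default 0.3).
#' @return Tibble with `gene_id`, `rho`, `p`, `passes_reference_line`,
#'   ordered by decreasing rho (NA last).
#' @export
correlate_genes_to_bccs <- function(expr, bc, genes = rownames(expr),
                                    score_col = "bc_raw", rho_ref = 0.3) {
  .validate_expression(expr)
  if (!score_col %in% names(bc)) .stop(sprintf("no column '%s' in bc", score_col))
  shared <- intersect(colnames(expr), bc$sample_id)
  if (length(shared) < 10) .stop("fewer than 10 shared samples")
  score <- bc[[score_col]][match(shared, bc$sample_id)]
  missing_genes <- setdiff(genes, rownames(expr))
  if (length(missing_genes) > 0) {
    .stop(paste0("genes not in matrix: ", paste(head(missing_genes, 5), collapse = ", ")))
  }
  x <- expr[genes, shared, drop = FALSE]
  res <- purrr::map_dfr(genes, function(g) {
    v <- x[g, ]
    if (sd(v) == 0) return(tibble(gene_id = g, rho = NA_real_, p = NA_real_))
    ct <- suppressWarnings(cor.test(v, score, method = "spearman", exact = FALSE))
    tibble(gene_id = g, rho = unname(ct$estimate), p = ct$p.value)
  })
  n_const <- sum(is.na(res$rho))
  if (n_const > 0) {
    warn(sprintf("%d constant gene(s): rho undefined, reported as NA", n_const))
  }
  res |>
    mutate(passes_reference_line = !is.na(.data$rho) & .data$rho > rho_ref) |>
    arrange(desc(.data$rho))
}
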