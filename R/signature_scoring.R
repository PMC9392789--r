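# Per-sample signature and module scores. The cell-cycle score (CCS) of a
# sample is the plain sum of its log-expression values over the signature
# genes present in the matrix; module scores are means of per-gene z-scores
# so modules of unequal size stay comparable.

.new_scores <- function(tab, signature_name, n_used, n_missing) {
  structure(tab,
            signature_name = signature_name,
            n_genes_used = as.integer(n_used),
            n_genes_missing = as.integer(n_missing),
            class = c("bccs_scores", class(tibble())))
}

#' Sum-based signature score per sample
#'
#' Computes, for every sample, the sum of log-expression values over the
#' signature genes found in the matrix. Signature genes missing from the
#' matrix are dropped (never imputed) and counted; scoring aborts if the
#' missing fraction exceeds `max_missing`.
#'
#' @param expr Genes x samples expression matrix.
#' @param signature Character vector of signature gene ids.
#' @param name Signature name recorded on the result.
#' @param max_missing Maximum tolerated fraction of signature genes absent
#'   from the matrix (default 0.2).
#' @return A `bccs_scores` tibble (`sample_id`, `raw_score`) with attributes
#'   `signature_name`, `n_genes_used`, `n_genes_missing`.
#' @export
compute_signature_score <- function(expr, signature, name = "CCS",
                                    max_missing = 0.2) {
  .validate_expression(expr)
  signature <- unique(signature)
  present <- intersect(signature, rownames(expr))
  n_missing <- length(signature) - length(present)
  if (length(present) == 0) {
    .stop(sprintf("signature '%s' has no genes in the expression matrix", name))
  }
  if (n_missing / length(signature) > max_missing) {
    .stop(sprintf(
      "signature '%s': %d of %d genes missing from the matrix (> %.0f%% ceiling)",
      name, n_missing, length(signature), 100 * max_missing
    ))
  }
  if (n_missing > 0) {
    warn(sprintf("signature '%s': %d of %d genes absent from the matrix and dropped",
                 name, n_missing, length(signature)))
  }
  raw <- colSums(expr[present, , drop = FALSE])
  .new_scores(tibble(sample_id = colnames(expr), raw_score = unname(raw)),
              name, length(present), n_missing)
}

#' Min-max rescale scores to the unit interval
#'
#' Affine rescaling `(x - min) / (max - min)` of the raw scores, mapping the
#' minimum to 0 and the maximum to 1. Rank order is preserved exactly.
#'
#' @param scores A `bccs_scores` tibble with a `raw_score` column, or any
#'   tibble with the columns named by `from`.
#' @param from Column to rescale (default `raw_score`).
#' @param to Name of the rescaled column added (default `scaled_score`).
#' @return The input with the rescaled column added.
#' @export
minmax_rescale <- function(scores, from = "raw_score", to = "scaled_score") {
  x <- scores[[from]]
  if (is.null(x)) .stop(sprintf("no column '%s' to rescale", from))
  if (length(x) < 2) .stop("rescaling requires at least 2 samples")
  rng <- range(x)
  if (rng[1] == rng[2]) .stop("degenerate range: all scores equal")
  scores[[to]] <- (x - rng[1]) / (rng[2] - rng[1])
  scores
}

#' Mean-of-z-scores module score per sample
#'
#' Each module gene is z-scored across samples; the module score of a sample
#' is the mean z over the module genes. Genes with zero variance are
#' excluded with a warning (a z-score is undefined for them).
#'
#' @inheritParams compute_signature_score
#' @param module Character vector of module gene ids.
#' @return A `bccs_scores` tibble (`sample_id`, `raw_score`).
#' @export
compute_module_score <- function(expr, module, name = "module") {
  .validate_expression(expr)
  module <- unique(module)
  present <- intersect(module, rownames(expr))
  if (length(present) == 0) {
    .stop(sprintf("module '%s' has no genes in the expression matrix", name))
  }
  x <- expr[present, , drop = FALSE]
  sds <- apply(x, 1, sd)
  if (any(sds == 0)) {
    warn(sprintf("module '%s': %d zero-variance gene(s) excluded", name, sum(sds == 0)))
    x <- x[sds > 0, , drop = FALSE]
    if (nrow(x) == 0) .stop(sprintf("module '%s': all genes have zero variance", name))
    sds <- sds[sds > 0]
  }
  z <- (x - rowMeans(x)) / sds
  .new_scores(tibble(sample_id = colnames(expr), raw_score = unname(colMeans(z))),
              name, nrow(x), length(module) - nrow(x))
}

#' Correlate two score tables
#'
#' Pearson or Spearman correlation over the samples shared by two score
#' tables, with a two-sided p value.
#'
#' @param a,b `bccs_scores` tibbles (or any tibble with `sample_id` and
#'   `raw_score`).
#' @param method `"pearson"` or `"spearman"`.
#' @return A one-row tibble with `method`, `estimate`, `p_value`,
#'   `n_samples`.
#' @export
correlate_scores <- function(a, b, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  shared <- inner_join(
    select(as_tibble(a), "sample_id", a_score = "raw_score"),
    select(as_tibble(b), "sample_id", b_score = "raw_score"),
    by = "sample_id"
  )
  if (nrow(shared) < 3) .stop("fewer than 3 shared samples")
  ct <- suppressWarnings(
    cor.test(shared$a_score, shared$b_score, method = method, exact = FALSE)
  )
  tibble(method = method, estimate = unname(ct$estimate),
         p_value = ct$p.value, n_samples = nrow(shared))
}
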