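# Variable-gene selection, PCA and UMAP embeddings for batch-effect
# assessment, and an automated robust-Mahalanobis outlier rule formalising
# what is otherwise done by eye on a PCA plot.

#' Select the most variable genes
#'
#' @param expr Genes x samples expression matrix.
#' @param n_top Number of genes to return.
#' @return Character vector of the `n_top` gene ids with the largest
#'   variance across samples; ties broken by lexicographic gene id, so the
#'   selection is deterministic.
#' @export
select_variable_genes <- function(expr, n_top) {
  .validate_expression(expr)
  if (n_top < 1) .stop("n_top must be >= 1")
  if (n_top > nrow(expr)) .stop("n_top exceeds the number of genes")
  v <- apply(expr, 1, var)
  ord <- order(-v, rownames(expr), method = "radix")
  rownames(expr)[ord][seq_len(n_top)]
}

.new_embedding <- function(sample_ids, coords, method, gene_subset_name,
                           explained_variance = NULL) {
  colnames(coords) <- paste0("dim", seq_len(ncol(coords)))
  emb <- as_tibble(coords)
  emb <- mutate(emb, sample_id = sample_ids, .before = 1)
  structure(emb,
            method = method,
            gene_subset_name = gene_subset_name,
            explained_variance = explained_variance,
            class = c("bccs_embedding", class(tibble())))
}

#' Principal component analysis of samples
#'
#' Samples are embedded over a chosen gene subset; each gene is centred
#' before decomposition. Component signs are fixed by convention (the
#' largest-magnitude loading of each component is made positive) so repeat
#' runs give identical coordinates.
#'
#' @param expr Genes x samples expression matrix.
#' @param genes Gene ids to embed over (subset of `rownames(expr)`).
#' @param k Number of components.
#' @param gene_subset_name Label recorded on the embedding (e.g. `"top"` or
#'   `"signature"`).
#' @return A `bccs_embedding` tibble (`sample_id`, `dim1` ... `dimk`) with
#'   attributes `method = "PCA"`, `gene_subset_name` and
#'   `explained_variance` (per-component fractions of total variance).
#' @export
run_pca <- function(expr, genes, k = 2, gene_subset_name = "custom") {
  .validate_expression(expr)
  missing_genes <- setdiff(genes, rownames(expr))
  if (length(missing_genes) > 0) {
    .stop(paste0("genes not in matrix: ", paste(head(missing_genes, 5), collapse = ", ")))
  }
  x <- t(expr[genes, , drop = FALSE])  # samples x genes
  total_var <- sum(apply(x, 2, var))
  if (total_var == 0) .stop("zero total variance: PCA undefined on a constant matrix")
  if (k > min(dim(x))) .stop("k exceeds min(n_samples, n_genes)")
  pc <- prcomp(x, center = TRUE, scale. = FALSE, rank. = k)
  # sign convention: largest-|loading| entry of each rotation vector positive
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  .new_embedding(colnames(expr), pc$x[, seq_len(k), drop = FALSE], "PCA",
                 gene_subset_name,
                 explained_variance = (pc$sdev[seq_len(k)]^2) / total_var)
}

#' UMAP embedding of samples
#'
#' Two-dimensional uniform manifold approximation over a chosen gene subset.
#' Coordinates are reproducible for a fixed seed on a given platform; only
#' neighbourhood structure, not exact coordinates, is meaningful.
#'
#' @inheritParams run_pca
#' @param seed Integer seed.
#' @param n_neighbors UMAP neighbourhood size (default 15, reduced
#'   automatically with a warning when the cohort is small).
#' @return A `bccs_embedding` tibble with `method = "UMAP"`.
#' @export
run_umap <- function(expr, genes, seed = 17L, n_neighbors = 15,
                     gene_subset_name = "custom") {
  .validate_expression(expr)
  x <- t(expr[genes, , drop = FALSE])
  if (nrow(x) < 10) .stop("UMAP requires at least 10 samples")
  if (n_neighbors >= nrow(x)) {
    .stop(sprintf(
      "n_neighbors (%d) must be smaller than the sample count (%d); lower n_neighbors",
      n_neighbors, nrow(x)
    ))
  }
  set.seed(seed)
  coords <- uwot::umap(x, n_neighbors = n_neighbors, n_components = 2,
                       n_threads = 1, n_sgd_threads = 1)
  .new_embedding(colnames(expr), coords, "UMAP", gene_subset_name)
}

#' Flag embedding outliers by robust Mahalanobis distance
#'
#' Replaces manual inspection of PCA plots with an explicit rule: on the
#' first two components, samples whose squared Mahalanobis distance from a
#' high-breakdown (MCD) robust location/scatter estimate exceeds the
#' chi-square(2) quantile at `1 - alpha` are flagged.
#'
#' @param emb A PCA `bccs_embedding` with at least 2 dimensions.
#' @param alpha Flagging rate under multivariate normality (default 0.001).
#' @return Character vector of flagged sample ids (possibly empty).
#' @export
flag_embedding_outliers <- function(emb, alpha = 0.001) {
  if (!inherits(emb, "bccs_embedding")) .stop("emb must be a bccs_embedding")
  if (alpha <= 0 || alpha >= 1) .stop("alpha must be in (0, 1)")
  if (!all(c("dim1", "dim2") %in% names(emb))) .stop("embedding must have >= 2 dimensions")
  x <- cbind(emb$dim1, emb$dim2)
  if (nrow(x) < 5) .stop("outlier flagging requires at least 5 samples")
  # the MCD subset search is randomised; pin it so flagging is a pure
  # function of the embedding, without disturbing the caller's RNG stream
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(2090L)
  rob <- MASS::cov.rob(x, method = "mcd")
  d2 <- mahalanobis(x, rob$center, rob$cov)
  emb$sample_id[d2 > qchisq(1 - alpha, df = 2)]
}
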