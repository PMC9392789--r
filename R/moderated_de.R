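# Covariate-adjusted differential expression with an empirical-Bayes
# moderated t-statistic. Per gene, an ordinary least squares fit on the
# design [intercept, group indicator, cancer-type dummies, covariate gene];
# residual variances are then shrunk toward a common prior estimated by
# moment matching of the log residual variances (the scaled-F model:
# s^2 ~ s0^2 * F(df_resid, d0)), and the group coefficient is tested with
# t = beta / se_shrunk on d0 + df_resid degrees of freedom.

# Inverse of trigamma by Newton iteration (monotone decreasing, convex).
.trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif) / y < 1e-8) break
  }
  y
}

# Moment-matching estimate of the variance prior (d0, s0^2) from per-gene
# residual variances s2 on df degrees of freedom. Returns d0 = Inf when the
# observed spread of log variances is no larger than expected under a
# common variance.
.estimate_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 >= 0
  s2 <- s2[ok]
  m <- median(s2)
  if (m == 0) {
    .stop("more than half of the residual variances are exactly zero")
  }
  # genes fitted (near-)exactly by the design would send log(s2) to -Inf and
  # destroy the moment estimates; floor them away from zero
  floor_at <- 1e-5 * m
  if (any(s2 < floor_at)) {
    warn(sprintf("%d near-zero residual variance(s) floored at 1e-5 * median",
                 sum(s2 < floor_at)))
    s2 <- pmax(s2, floor_at)
  }
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  e_var <- mean((e - mean(e))^2) * length(e) / (length(e) - 1)
  excess <- e_var - trigamma(df / 2)
  if (excess <= 0) {
    return(list(d0 = Inf, s0_2 = exp(mean(e))))
  }
  d0 <- 2 * .trigamma_inverse(excess)
  s0_2 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_2 = s0_2)
}

# Posterior (shrunken) variances given the prior.
.shrink_variances <- function(s2, df, d0, s0_2) {
  if (is.infinite(d0)) return(rep(s0_2, length(s2)))
  (d0 * s0_2 + df * s2) / (d0 + df)
}

#' Moderated differential expression between two tumour groups
#'
#' Fits, for every gene, a linear model of log expression on a Group 2
#' indicator with cancer-type dummies and (optionally) the expression of a
#' covariate gene such as ESR1 as adjustments, then moderates the per-gene
#' residual variances by empirical Bayes before testing the group
#' coefficient. `prior_df` can be forced to 0 (no shrinkage: ordinary OLS t)
#' or `Inf` (complete pooling to the common prior variance); by default it
#' is estimated from the data.
#'
#' @param expr Genes x samples expression matrix.
#' @param manifest A manifest tibble.
#' @param groups A [group_assignment()]; the reported `log2_fc` is the
#'   Group 2 minus Group 1 coefficient.
#' @param covariate_gene Gene id whose expression row enters the design as a
#'   continuous adjustment (default `"ESR1"`); `NULL` to omit. A missing
#'   covariate gene is a hard error, so silent non-adjustment cannot occur.
#' @param adjust_cancer_type Include cancer-type dummy variables
#'   (default `TRUE`).
#' @param prior_df Force the prior degrees of freedom `d0` (0, a positive
#'   number, or `Inf`); `NULL` (default) estimates it by moment matching.
#' @param lfc,fdr Significance thresholds: a gene is `significant` when
#'   `|log2_fc| > lfc` (strict) and `q < fdr`. Defaults 2 and 0.05.
#' @return An object of class `bccs_de`: a list with `results` (tibble:
#'   `gene_id`, `log2_fc`, `t_moderated`, `p`, `q`, `significant`),
#'   `prior_df`, `prior_var`, `df_residual`, `n_g1`, `n_g2`, and the
#'   thresholds. Use [tidy()] for the per-gene table.
#' @export
fit_moderated_de <- function(expr, manifest, groups,
                             covariate_gene = "ESR1",
                             adjust_cancer_type = TRUE,
                             prior_df = NULL, lfc = 2, fdr = 0.05) {
  .validate_expression(expr)
  validate_manifest(manifest)
  tumors <- manifest |>
    filter(.data$study == "TCGA_TUMOR",
           .data$cancer_type %in% c(groups$group1, groups$group2),
           .data$sample_id %in% colnames(expr))
  if (nrow(tumors) < 4) .stop("too few samples in the two groups")
  x <- expr[, tumors$sample_id, drop = FALSE]

  group2_ind <- as.numeric(tumors$cancer_type %in% groups$group2)
  design <- cbind(`(Intercept)` = 1, group2 = group2_ind)
  if (adjust_cancer_type) {
    # cancer-type dummies nested within group: one reference type per group
    # is dropped, otherwise the group indicator is the sum of its type
    # dummies and the design is aliased by construction
    refs <- c(sort(intersect(groups$group1, tumors$cancer_type))[1],
              sort(intersect(groups$group2, tumors$cancer_type))[1])
    dummy_types <- setdiff(sort(unique(tumors$cancer_type)), refs)
    for (ctype in dummy_types) {
      design <- cbind(design, as.numeric(tumors$cancer_type == ctype))
      colnames(design)[ncol(design)] <- paste0("cancer_type", ctype)
    }
  }
  if (!is.null(covariate_gene)) {
    if (!covariate_gene %in% rownames(x)) {
      .stop(sprintf("covariate gene '%s' not in the expression matrix", covariate_gene))
    }
    design <- cbind(design, covariate = x[covariate_gene, ])
  }
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    aliased <- colnames(design)[qr_d$pivot[(qr_d$rank + 1):ncol(design)]]
    .stop(paste0("rank-deficient design; aliased column(s): ",
                 paste(aliased, collapse = ", ")))
  }
  df_resid <- ncol(x) - ncol(design)
  if (df_resid < 2) .stop("fewer than 2 residual degrees of freedom")

  # one multi-response OLS fit for all genes
  fit <- stats::lm.fit(design, t(x))
  coefs <- t(fit$coefficients)  # genes x terms
  res <- t(fit$residuals)
  s2 <- rowSums(res^2) / df_resid

  if (is.null(prior_df)) {
    prior <- .estimate_variance_prior(s2, df_resid)
  } else {
    if (prior_df < 0) .stop("prior_df must be >= 0 (possibly Inf)")
    s0_2 <- exp(mean(log(pmax(s2, .Machine$double.xmin))))
    prior <- list(d0 = prior_df,
                  s0_2 = if (prior_df == 0) NA_real_ else s0_2)
    if (is.infinite(prior_df)) prior$s0_2 <- mean(s2)
  }
  s2_post <- if (prior$d0 == 0) s2 else .shrink_variances(s2, df_resid, prior$d0, prior$s0_2)

  # unscaled variance of the group coefficient
  xtxi <- chol2inv(qr.R(qr_d))
  j <- match("group2", colnames(design))
  v_j <- xtxi[j, j]
  beta <- coefs[, j]
  t_mod <- beta / sqrt(s2_post * v_j)
  df_total <- prior$d0 + df_resid
  p <- 2 * pt(abs(t_mod), df = df_total, lower.tail = FALSE)
  q <- benjamini_hochberg(p)

  results <- tibble(
    gene_id = rownames(x),
    log2_fc = unname(beta),
    t_moderated = unname(t_mod),
    p = unname(p),
    q = unname(q),
    significant = abs(beta) > lfc & q < fdr
  )
  structure(
    list(results = results, prior_df = prior$d0, prior_var = prior$s0_2,
         df_residual = df_resid,
         n_g1 = sum(group2_ind == 0), n_g2 = sum(group2_ind == 1),
         lfc = lfc, fdr = fdr, covariate_gene = covariate_gene),
    class = "bccs_de"
  )
}

#' @export
print.bccs_de <- function(x, ...) {
  cat(sprintf(
    "Moderated DE fit: %d genes, %d vs %d samples, df_resid = %d, prior df = %s\n",
    nrow(x$results), x$n_g1, x$n_g2, x$df_residual, format(x$prior_df, digits = 4)
  ))
  cat(sprintf("Significant (|log2FC| > %g & FDR < %g): %d up, %d down\n",
              x$lfc, x$fdr,
              sum(x$results$significant & x$results$log2_fc > 0),
              sum(x$results$significant & x$results$log2_fc < 0)))
  invisible(x)
}

#' Partition DE results into up- and downregulated gene lists
#'
#' Genes significant with `log2_fc` strictly above `lfc` are "up" (higher in
#' Group 2), strictly below `-lfc` "down". A gene at exactly the threshold
#' is excluded.
#'
#' @param de A `bccs_de` object or its `results` tibble.
#' @param lfc,fdr Thresholds; default to those stored on the fit (2, 0.05
#'   for a bare tibble).
#' @return List with character vectors `up` and `down`.
#' @export
volcano_partition <- function(de, lfc = NULL, fdr = NULL) {
  results <- if (inherits(de, "bccs_de")) de$results else as_tibble(de)
  lfc <- lfc %||% (if (inherits(de, "bccs_de")) de$lfc else 2)
  fdr <- fdr %||% (if (inherits(de, "bccs_de")) de$fdr else 0.05)
  sig <- results$q < fdr
  list(
    up = results$gene_id[sig & results$log2_fc > lfc],
    down = results$gene_id[sig & results$log2_fc < -lfc]
  )
}
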