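# Group 1 vs Group 2 comparisons of binary genomic features (driver-gene
# mutations; arm-level gains and losses, tested separately per direction).
# Displayed frequencies are macro-averaged over cancer types so unequal type
# sizes cannot dominate; the test itself is a two-sided Fisher exact test on
# pooled per-group counts (a stratified Cochran-Mantel-Haenszel alternative
# is available), with Benjamini-Hochberg FDR across features.

#' Define the two comparison groups
#'
#' @param group1,group2 Character vectors of cancer-type codes. Defaults are
#'   the lowest and highest corrected-activity groups used throughout:
#'   Group 1 = HNSC, KICH, KIRP, UCEC; Group 2 = CESC, OV, UCS.
#' @param manifest Optional manifest; when given, every code must occur in it.
#' @return A list of class `bccs_groups` with elements `group1`, `group2`.
#' @export
group_assignment <- function(group1 = c("HNSC", "KICH", "KIRP", "UCEC"),
                             group2 = c("CESC", "OV", "UCS"),
                             manifest = NULL) {
  group1 <- unique(as.character(group1))
  group2 <- unique(as.character(group2))
  if (length(group1) == 0 || length(group2) == 0) .stop("both groups must be non-empty")
  overlap <- intersect(group1, group2)
  if (length(overlap) > 0) {
    .stop(paste0("groups must be disjoint; shared: ", paste(overlap, collapse = ", ")))
  }
  if (!is.null(manifest)) {
    known <- unique(manifest$cancer_type[manifest$study == "TCGA_TUMOR"])
    unknown <- setdiff(c(group1, group2), known)
    if (length(unknown) > 0) {
      .stop(paste0("cancer type(s) not in manifest: ", paste(unknown, collapse = ", ")))
    }
  }
  structure(list(group1 = group1, group2 = group2), class = "bccs_groups")
}

#' Macro-averaged feature frequency within a group
#'
#' The frequency of a binary feature in a group of cancer types, adjusted
#' for sample number within each cancer type: the unweighted mean over the
#' group's cancer types of the within-type frequency, expressed as a
#' percentage. Duplicating every sample of one type leaves it unchanged.
#'
#' @param feature Named 0/1 vector (names are sample ids).
#' @param manifest A manifest tibble.
#' @param group Character vector of cancer-type codes.
#' @return Percentage in \[0, 100\].
#' @export
adjusted_frequency <- function(feature, manifest, group) {
  if (length(group) == 0) .stop("group must be non-empty")
  samples <- manifest |>
    filter(.data$study == "TCGA_TUMOR", .data$cancer_type %in% group,
           .data$sample_id %in% names(feature))
  if (nrow(samples) == 0) .stop("no samples with feature data in the group")
  per_type <- samples |>
    mutate(value = feature[.data$sample_id]) |>
    group_by(.data$cancer_type) |>
    summarise(freq = mean(.data$value), .groups = "drop")
  100 * mean(per_type$freq)
}

# Two-sided Fisher exact p for a 2x2 table by direct hypergeometric
# enumeration: the sum of all conditional table probabilities not exceeding
# the observed one (with the conventional 1 + 1e-7 relative slack for ties).
.fisher_p <- function(k1, n1, k2, n2) {
  m <- k1 + k2
  lo <- max(0L, m - n2)
  hi <- min(n1, m)
  probs <- dhyper(lo:hi, n1, n2, m)
  sum(probs[probs <= probs[k1 - lo + 1L] * (1 + 1e-7)])
}

#' Two-sided Fisher exact test for one binary feature
#'
#' Tests the 2x2 table \[\[k1, n1-k1\], \[k2, n2-k2\]\] of feature-positive
#' counts in two groups. The p value is the exact conditional two-sided p
#' (hypergeometric enumeration); the odds ratio is the conditional maximum
#' likelihood estimate.
#'
#' @param k1,n1 Positives and total in group 1 (vectorised; vectors are
#'   recycled to a common length).
#' @param k2,n2 Positives and total in group 2.
#' @param odds_ratio Set `FALSE` to skip the conditional-MLE odds ratio
#'   (returned as `NA`) when only p values are needed in bulk.
#' @return A tibble with one row per table (`k1`, `n1`, `k2`, `n2`,
#'   `odds_ratio`, `p`).
#' @export
fisher_feature_test <- function(k1, n1, k2, n2, odds_ratio = TRUE) {
  tab <- tibble(k1 = k1, n1 = n1, k2 = k2, n2 = n2)  # recycles scalars
  counts <- c(tab$k1, tab$n1, tab$k2, tab$n2)
  if (any(counts < 0) || any(counts != round(counts))) {
    .stop("counts must be non-negative integers")
  }
  if (any(tab$n1 < 1) || any(tab$n2 < 1)) {
    .stop("each group must have at least one sample")
  }
  if (any(tab$k1 > tab$n1) || any(tab$k2 > tab$n2)) {
    .stop("positives cannot exceed group size")
  }
  p <- pmin(mapply(.fisher_p, tab$k1, tab$n1, tab$k2, tab$n2), 1)
  or <- rep(NA_real_, nrow(tab))
  if (odds_ratio) {
    or <- mapply(function(a, b, c, d) {
      unname(stats::fisher.test(matrix(c(a, b - a, c, d - c), nrow = 2,
                                       byrow = TRUE))$estimate)
    }, tab$k1, tab$n1, tab$k2, tab$n2)
  }
  mutate(tab, odds_ratio = or, p = p)
}

#' Benjamini-Hochberg adjusted q values
#'
#' Standard step-up false discovery rate adjustment.
#'
#' @param p_values Numeric vector of p values in \[0, 1\].
#' @return Vector of q values, same order as the input.
#' @export
benjamini_hochberg <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    .stop("p values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

# Shared engine: one row per feature of a binary samples-in-columns matrix.
.compare_binary_features <- function(feature_matrix, manifest, groups,
                                     stratified = FALSE) {
  g1_ids <- manifest$sample_id[manifest$study == "TCGA_TUMOR" &
                                 manifest$cancer_type %in% groups$group1]
  g2_ids <- manifest$sample_id[manifest$study == "TCGA_TUMOR" &
                                 manifest$cancer_type %in% groups$group2]
  g1_ids <- intersect(g1_ids, colnames(feature_matrix))
  g2_ids <- intersect(g2_ids, colnames(feature_matrix))
  if (length(g1_ids) == 0 || length(g2_ids) == 0) {
    .stop("both groups need samples with feature data")
  }
  ct <- setNames(manifest$cancer_type, manifest$sample_id)
  res <- purrr::map_dfr(rownames(feature_matrix), function(f) {
    x <- feature_matrix[f, ]
    k1 <- sum(x[g1_ids]); k2 <- sum(x[g2_ids])
    if (stratified) {
      p <- .cmh_p(x, c(g1_ids, g2_ids), ct,
                  rep(c(1L, 2L), c(length(g1_ids), length(g2_ids))))
      or <- NA_real_
    } else {
      ft <- fisher_feature_test(k1, length(g1_ids), k2, length(g2_ids))
      p <- ft$p; or <- ft$odds_ratio
    }
    tibble(
      feature_id = f,
      adj_freq_g1 = adjusted_frequency(x, manifest, groups$group1),
      adj_freq_g2 = adjusted_frequency(x, manifest, groups$group2),
      k1 = k1, n1 = length(g1_ids), k2 = k2, n2 = length(g2_ids),
      odds_ratio = or, p = p
    )
  })
  res$q <- benjamini_hochberg(res$p)
  res
}

# Cochran-Mantel-Haenszel p stratified by cancer type (config alternative).
.cmh_p <- function(x, ids, cancer_type_of, group_code) {
  strata <- factor(cancer_type_of[ids])
  tab <- table(factor(x[ids], levels = c(0, 1)),
               factor(group_code, levels = c(1, 2)), strata)
  ok <- apply(tab, 3, function(t2) all(rowSums(t2) > 0) && all(colSums(t2) > 0))
  tab <- tab[, , ok, drop = FALSE]
  if (dim(tab)[3] == 0) return(1)
  tryCatch(stats::mantelhaen.test(tab, exact = FALSE, correct = TRUE)$p.value,
           error = function(e) 1)
}

#' Compare driver-gene mutation frequencies between groups
#'
#' Per driver gene: macro-averaged mutation percentages in each group, a
#' two-sided Fisher exact test on pooled per-group counts, and BH-FDR across
#' genes. Sort by `adj_freq_g1`/`adj_freq_g2` for top-mutated views, or
#' filter with `higher_in_g2()` for group-2-enriched genes.
#'
#' @param mutations Binary genes x samples matrix (see [read_mutations()]).
#' @param manifest A manifest tibble.
#' @param groups A [group_assignment()].
#' @param stratified Use a cancer-type-stratified Cochran-Mantel-Haenszel
#'   test instead of the pooled Fisher test (default `FALSE`).
#' @return Tibble with one row per gene: `feature_id`, `adj_freq_g1`,
#'   `adj_freq_g2`, counts, `odds_ratio`, `p`, `q`.
#' @export
compare_mutations <- function(mutations, manifest, groups, stratified = FALSE) {
  validate_manifest(manifest)
  if (!all(mutations %in% c(0, 1))) .stop("mutation matrix must be binary")
  .compare_binary_features(mutations, manifest, groups, stratified)
}

#' Compare arm-level alteration frequencies between groups
#'
#' Gains (+1 vs not) and losses (-1 vs not) are tested separately for every
#' arm; BH-FDR is applied within each direction. Feature ids are suffixed
#' `_gain` / `_loss`.
#'
#' @param arm_calls Arms x samples matrix with values in \{-1, 0, 1\}.
#' @inheritParams compare_mutations
#' @return Tibble as in [compare_mutations()] plus a `direction` column.
#' @export
compare_arm_calls <- function(arm_calls, manifest, groups, stratified = FALSE) {
  validate_manifest(manifest)
  if (!all(arm_calls %in% c(-1, 0, 1))) {
    .stop("arm calls must be -1, 0 or +1")
  }
  res <- purrr::map_dfr(c(gain = 1, loss = -1), function(code) {
    bin <- (arm_calls == code) * 1L
    rownames(bin) <- rownames(arm_calls)
    out <- .compare_binary_features(bin, manifest, groups, stratified)
    out$q <- benjamini_hochberg(out$p)  # FDR within direction
    out
  }, .id = "direction")
  res |>
    mutate(feature_id = paste0(.data$feature_id, "_", .data$direction)) |>
    select("feature_id", "direction", dplyr::everything())
}

#' Features enriched in Group 2
#'
#' Post-hoc direction filter on two-sided results: keeps features whose
#' macro-averaged frequency is higher in Group 2 and whose q value passes
#' the FDR threshold.
#'
#' @param results Output of [compare_mutations()] or [compare_arm_calls()].
#' @param fdr FDR threshold (default 0.05).
#' @return The filtered tibble, ordered by increasing q.
#' @export
higher_in_g2 <- function(results, fdr = 0.05) {
  results |>
    filter(.data$adj_freq_g2 > .data$adj_freq_g1, .data$q < fdr) |>
    arrange(.data$q)
}
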