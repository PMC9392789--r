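# Preranked gene-set enrichment: weighted Kolmogorov-Smirnov running-sum
# enrichment score (weight = |rank statistic|, exponent 1), significance by
# gene-label permutation, NES by sign-matched null normalisation, BH-FDR
# across sets.

# ES of positions `hits` (indices into the ranking) given |stat| weights.
# Single O(n) pass: the running sum increments by the normalised weight at
# hits and decrements by 1/(n - n_hits) otherwise; ES is the signed maximum
# deviation from zero.
.gsea_es <- function(abs_stat, hits, n) {
  n_hits <- length(hits)
  w <- abs_stat[hits]
  total_w <- sum(w)
  if (total_w == 0) total_w <- 1  # all-zero stats: hits contribute nothing
  step <- rep(-1 / (n - n_hits), n)
  step[hits] <- w / total_w
  running <- cumsum(step)
  hi <- max(running)
  lo <- min(running)
  # positive extremum wins ties, with a float tolerance so genuinely tied
  # deviations (possible on small rankings) resolve deterministically
  if (abs(hi) >= abs(lo) - 1e-12) hi else lo
}

#' Rank genes for enrichment analysis
#'
#' Builds the ordered ranking a preranked enrichment run consumes.
#' The default statistic combines effect size and significance as
#' `sign(log2_fc) * (-log10 p)`; ties are broken by `|log2_fc|` then gene
#' id, so the ranking is deterministic.
#'
#' @param de A `bccs_de` object or its `results` tibble (needs `gene_id`,
#'   `log2_fc`, `p`; `t_moderated` for `mode = "t_stat"`).
#' @param mode `"signed_logp"` (default), `"t_stat"` or `"log2fc"`.
#' @return A named numeric vector of rank statistics, sorted decreasing;
#'   names are gene ids. Zero p values are replaced by the smallest positive
#'   double with a warning.
#' @export
rank_statistic <- function(de, mode = c("signed_logp", "t_stat", "log2fc")) {
  mode <- match.arg(mode)
  results <- if (inherits(de, "bccs_de")) de$results else as_tibble(de)
  if (any(is.na(results$p))) .stop("NaN p values in DE results")
  p <- results$p
  if (any(p == 0)) {
    warn(sprintf("%d zero p value(s) replaced by the smallest positive double",
                 sum(p == 0)))
    p[p == 0] <- .Machine$double.xmin
  }
  stat <- switch(mode,
    signed_logp = sign(results$log2_fc) * (-log10(p)),
    t_stat = results$t_moderated,
    log2fc = results$log2_fc
  )
  ord <- order(-stat, -abs(results$log2_fc), results$gene_id, method = "radix")
  setNames(stat[ord], results$gene_id[ord])
}

#' Preranked gene-set enrichment analysis
#'
#' For each gene set, computes the weighted running-sum enrichment score
#' over the supplied ranking and assesses it against a null of random
#' gene-label draws of the same size (`n_perm` permutations, seeded). The
#' normalised score divides the ES by the mean |null ES| of matching sign;
#' p values are empirical with the +1 correction; q is BH across sets.
#'
#' @param ranked_stats Named numeric vector from [rank_statistic()] (names =
#'   gene ids, values = rank statistic, sorted decreasing).
#' @param gene_sets Named list of character vectors (see [read_gmt()]).
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed for the permutation null.
#' @param min_size Sets with fewer than this many genes in the ranking are
#'   skipped with a warning (default 5).
#' @return A tibble of class `bccs_gsea`: `set_name`, `size`, `es`, `nes`,
#'   `p`, `q`, `leading_edge` (list column of gene ids contributing to the
#'   ES peak).
#' @export
preranked_gsea <- function(ranked_stats, gene_sets, n_perm = 1000, seed = 17L,
                           min_size = 5) {
  if (any(!is.finite(ranked_stats))) .stop("rank statistics must be finite")
  if (is.unsorted(rev(ranked_stats))) {
    ranked_stats <- sort(ranked_stats, decreasing = TRUE)
  }
  if (n_perm < 100) .stop("n_perm must be >= 100")
  n <- length(ranked_stats)
  genes <- names(ranked_stats)
  abs_stat <- abs(ranked_stats)

  keep <- vapply(gene_sets, function(s) length(intersect(s, genes)), integer(1))
  if (any(keep == 0)) {
    warn(sprintf("%d set(s) with zero overlap skipped", sum(keep == 0)))
  }
  small <- keep > 0 & keep < min_size
  if (any(small)) {
    warn(sprintf("%d set(s) below min_size = %d skipped", sum(small), min_size))
  }
  gene_sets <- gene_sets[keep >= min_size]
  if (length(gene_sets) == 0) .stop("no gene set passes the size filter")

  set.seed(seed)
  sizes <- sort(unique(vapply(gene_sets, function(s) length(intersect(s, genes)),
                              integer(1))))
  # shared null per set size
  null_es <- lapply(sizes, function(k) {
    vapply(seq_len(n_perm),
           function(i) .gsea_es(abs_stat, sort(sample.int(n, k)), n),
           numeric(1))
  })
  names(null_es) <- as.character(sizes)

  res <- purrr::map_dfr(names(gene_sets), function(nm) {
    hits <- sort(match(intersect(gene_sets[[nm]], genes), genes))
    es <- .gsea_es(abs_stat, hits, n)
    null <- null_es[[as.character(length(hits))]]
    same_sign <- if (es >= 0) null[null >= 0] else null[null < 0]
    nes <- if (length(same_sign) > 0) es / mean(abs(same_sign)) else NA_real_
    p <- (1 + sum(abs(same_sign) >= abs(es))) / (1 + length(same_sign))
    # leading edge: set genes at or before the ES extremum
    step <- rep(-1 / (n - length(hits)), n)
    w <- abs_stat[hits]; tw <- sum(w); if (tw == 0) tw <- 1
    step[hits] <- w / tw
    running <- cumsum(step)
    peak <- if (es >= 0) which.max(running) else which.min(running)
    le <- if (es >= 0) genes[intersect(hits, seq_len(peak))] else genes[hits[hits >= peak]]
    tibble(set_name = nm, size = length(hits), es = es, nes = nes, p = p,
           leading_edge = list(le))
  })
  res$q <- benjamini_hochberg(res$p)
  res <- select(res, "set_name", "size", "es", "nes", "p", "q", "leading_edge")
  structure(res, n_perm = n_perm, seed = seed,
            class = c("bccs_gsea", class(tibble())))
}
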