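# Shared fixtures and independent oracles used across the suite.

# A small, fast cohort: 4 tissues, 2 low / 2 high, modest gene counts.
tiny_config <- function(seed = 1L, n_normal = 15L, n_tumor = 40L,
                        n_driver_genes = 20L, ...) {
  synthetic_config(
    tissues = tibble::tibble(
      tissue = c("HeadNeck", "KidneyPapillary", "Cervix", "Ovary"),
      cancer_type = c("HNSC", "KIRP", "CESC", "OV"),
      n_normal = n_normal, n_tumor = n_tumor,
      baseline = c(8, 4, 2, 1.5),
      uplift = c(0.6, 1.0, 3.0, 3.5),
      group = c("low", "low", "high", "high")
    ),
    n_signature_genes = 20, n_background_genes = 60, n_metagene_genes = 10,
    n_de_genes = 10, n_driver_genes = n_driver_genes, seed = seed, ...
  )
}

# Manifest with explicit per-sample rows, for filter tests.
manual_manifest <- function(...) {
  rows <- list(...)
  tibble::as_tibble(do.call(rbind, lapply(rows, function(r) {
    data.frame(sample_id = r[[1]], study = r[[2]], tissue = r[[3]],
               cancer_type = r[[4]], exclusion_class = r[[5]])
  })))
}

# Independent O(n^2) brute-force GSEA running-sum: recomputes the prefix
# sums from scratch at every position.
brute_force_es <- function(stats_sorted, set_genes) {
  genes <- names(stats_sorted)
  n <- length(genes)
  in_set <- genes %in% set_genes
  nr <- sum(abs(stats_sorted[in_set]))
  if (nr == 0) nr <- 1
  n_miss <- n - sum(in_set)
  devs <- numeric(n)
  for (i in seq_len(n)) {
    p_hit <- sum(abs(stats_sorted[seq_len(i)][in_set[seq_len(i)]])) / nr
    p_miss <- sum(!in_set[seq_len(i)]) / n_miss
    devs[i] <- p_hit - p_miss
  }
  hi <- max(devs)
  lo <- min(devs)
  if (abs(hi) >= abs(lo) - 1e-12) hi else lo  # positive wins ties
}

# Independent Fisher two-sided p by direct enumeration with choose(), no
# dhyper: sum of conditional table probabilities <= observed (with the same
# conventional tie slack).
enumerate_fisher_p <- function(k1, n1, k2, n2) {
  m <- k1 + k2
  ks <- max(0, m - n2):min(n1, m)
  probs <- choose(n1, ks) * choose(n2, m - ks) / choose(n1 + n2, m)
  obs <- probs[ks == k1]
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

# Hand-rolled BH step-up, independent of p.adjust.
stepup_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  pmin(q, 1)[order(o)]
}
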