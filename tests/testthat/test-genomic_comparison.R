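# Macro-averaged frequencies, Fisher exact tests, BH-FDR, group comparisons.

test_that("adjusted frequency is a macro average over cancer types", {
  m <- dplyr::bind_rows(
    tibble::tibble(sample_id = sprintf("A%02d", 1:3), study = "TCGA_TUMOR",
                   tissue = "ta", cancer_type = "AAA", exclusion_class = "NONE"),
    tibble::tibble(sample_id = sprintf("B%02d", 1:17), study = "TCGA_TUMOR",
                   tissue = "tb", cancer_type = "BBB", exclusion_class = "NONE")
  )
  # 0% in the 3-sample type, 100% in the 17-sample type: macro average 50
  feat <- setNames(c(rep(0, 3), rep(1, 17)), m$sample_id)
  expect_equal(adjusted_frequency(feat, m, c("AAA", "BBB")), 50)
  # single type equals the plain frequency
  expect_equal(adjusted_frequency(feat, m, "BBB"), 100)
  expect_error(adjusted_frequency(feat, m, character()), "non-empty")

  # invariant to duplicating all samples of one type
  m_dup <- dplyr::bind_rows(m, dplyr::mutate(m[m$cancer_type == "AAA", ],
                                             sample_id = paste0(sample_id, "dup")))
  feat_dup <- c(feat, setNames(rep(0, 3), paste0(sprintf("A%02d", 1:3), "dup")))
  expect_equal(adjusted_frequency(feat_dup, m_dup, c("AAA", "BBB")), 50)

  # brute-force two-level loop oracle on random data
  set.seed(41)
  m_r <- tibble::tibble(
    sample_id = sprintf("S%03d", 1:120), study = "TCGA_TUMOR", tissue = "t",
    cancer_type = sample(c("X", "Y", "Z"), 120, TRUE), exclusion_class = "NONE")
  feat_r <- setNames(rbinom(120, 1, 0.3), m_r$sample_id)
  manual <- mean(vapply(c("X", "Y", "Z"), function(ct) {
    ids <- m_r$sample_id[m_r$cancer_type == ct]
    mean(feat_r[ids])
  }, numeric(1))) * 100
  expect_equal(adjusted_frequency(feat_r, m_r, c("X", "Y", "Z")), manual)
})

test_that("Fisher exact p matches enumeration and the reference routine", {
  expect_equal(fisher_feature_test(0, 10, 0, 10)$p, 1)
  # fully separated 10/10 table: p = 2 / choose(20, 10)
  expect_equal(fisher_feature_test(10, 10, 0, 10)$p, 2 / choose(20, 10),
               tolerance = 1e-12)

  # random tables against stats::fisher.test (independent oracle) for both
  # the p value and the conditional MLE odds ratio
  set.seed(7)
  for (i in 1:50) {
    n1 <- sample(2:40, 1); n2 <- sample(2:40, 1)
    k1 <- sample(0:n1, 1); k2 <- sample(0:n2, 1)
    res <- fisher_feature_test(k1, n1, k2, n2)
    ref <- stats::fisher.test(matrix(c(k1, n1 - k1, k2, n2 - k2), 2, byrow = TRUE))
    expect_equal(res$p, ref$p.value, tolerance = 1e-9)
    expect_equal(res$odds_ratio, unname(ref$estimate), tolerance = 1e-6)
  }

  expect_error(fisher_feature_test(-1, 5, 0, 5), "non-negative")
  expect_error(fisher_feature_test(6, 5, 0, 5), "exceed")
  expect_error(fisher_feature_test(0, 0, 0, 5), "at least one")
})

test_that("BH adjustment reproduces the hand-computed step-up", {
  expect_equal(benjamini_hochberg(0.03), 0.03)
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(benjamini_hochberg(rep(1, 5)), rep(1, 5))
  set.seed(12)
  p <- runif(200)^2
  expect_equal(benjamini_hochberg(p), stepup_bh(p))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("mutation comparison recovers a planted enrichment as the top hit", {
  cfg <- tiny_config(seed = 33, n_normal = 2L, n_tumor = 150L,
                     mutation_rates = c(TP53 = 0.4, FBXW7 = 0.1),
                     mutation_enrichment = c(FBXW7 = 5))
  co <- generate_cohort(cfg)
  g <- group_assignment(co$truth$groups$group1, co$truth$groups$group2)
  res <- compare_mutations(co$mutations, co$manifest, g)
  expect_equal(res$feature_id[which.min(res$q)], "FBXW7")
  expect_lt(res$q[res$feature_id == "FBXW7"], 0.05)
  expect_true(all(res$q >= res$p))
  # q is monotone in p across features
  ord <- order(res$p)
  expect_true(all(diff(res$q[ord]) >= -1e-15))

  # a gene mutated in nobody is uninformative
  mut0 <- co$mutations
  mut0["DRV001", ] <- 0L
  res0 <- compare_mutations(mut0, co$manifest, g)
  expect_equal(res0$p[res0$feature_id == "DRV001"], 1)
})

test_that("permuted group labels give calibrated, conservative p values", {
  cfg <- tiny_config(seed = 51, n_normal = 2L, n_tumor = 120L,
                     mutation_rates = c(TP53 = 0.3), mutation_enrichment = c(),
                     n_driver_genes = 200L)
  co <- generate_cohort(cfg)
  set.seed(4)
  m_perm <- co$manifest
  tum <- m_perm$study == "TCGA_TUMOR"
  m_perm$cancer_type[tum] <- sample(m_perm$cancer_type[tum])
  g <- group_assignment(co$truth$groups$group1, co$truth$groups$group2)
  res <- compare_mutations(co$mutations, m_perm, g)
  # an exact conditional test on discrete data is conservative, never
  # anti-conservative: P(p <= a) <= a up to Monte-Carlo error, at every a
  for (a in c(0.01, 0.05, 0.1, 0.25)) {
    mc <- 3 * sqrt(a * (1 - a) / nrow(res))
    expect_lte(mean(res$p <= a), a + mc)
  }
  expect_lte(mean(res$q < 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / nrow(res)))
})

test_that("arm comparison tests directions separately and flags extremes", {
  m <- tibble::tibble(
    sample_id = sprintf("S%03d", 1:40), study = "TCGA_TUMOR", tissue = "t",
    cancer_type = rep(c("G1C", "G2C"), each = 20), exclusion_class = "NONE")
  arms <- matrix(0L, nrow = 3, ncol = 40,
                 dimnames = list(c("16q", "8p", "1q"), m$sample_id))
  arms["16q", 21:40] <- -1L  # deleted in all of group 2, never group 1
  g <- group_assignment("G1C", "G2C")
  res <- compare_arm_calls(arms, m, g)
  loss16 <- res[res$feature_id == "16q_loss", ]
  expect_lt(loss16$q, 0.05)
  expect_equal(loss16$adj_freq_g2, 100)
  expect_equal(loss16$adj_freq_g1, 0)
  # the same arm's gain direction carries no signal
  expect_equal(res$p[res$feature_id == "16q_gain"], 1)

  # identical call distributions: nothing significant
  arms_same <- arms
  arms_same["16q", ] <- rep(c(-1L, 0L), 20)
  res_same <- compare_arm_calls(arms_same, m, g)
  expect_true(all(res_same$q > 0.05))

  arms_bad <- arms
  arms_bad[1, 1] <- 3L
  expect_error(compare_arm_calls(arms_bad, m, g), "-1, 0 or \\+1")
})

test_that("group assignment validates disjointness and membership", {
  expect_error(group_assignment(c("A", "B"), c("B", "C")), "disjoint")
  expect_error(group_assignment(character(), "A"), "non-empty")
  m <- generate_cohort(tiny_config())$manifest
  expect_error(group_assignment("HNSC", "NOPE", manifest = m), "NOPE")
  g <- group_assignment(c("HNSC", "KIRP"), c("CESC", "OV"), manifest = m)
  expect_s3_class(g, "bccs_groups")
})

test_that("stratified testing controls cancer-type confounding", {
  # feature frequency differs by cancer type but not by group within type
  set.seed(8)
  m <- tibble::tibble(
    sample_id = sprintf("S%03d", 1:200), study = "TCGA_TUMOR", tissue = "t",
    cancer_type = rep(c("A1", "A2", "B1", "B2"), each = 50),
    exclusion_class = "NONE")
  rate <- c(A1 = 0.05, A2 = 0.6, B1 = 0.05, B2 = 0.6)
  feat <- matrix(rbinom(200, 1, rate[m$cancer_type]), nrow = 1,
                 dimnames = list("f1", m$sample_id))
  g <- group_assignment(c("A1", "A2"), c("B1", "B2"))
  res <- compare_mutations(feat, m, g, stratified = TRUE)
  expect_gt(res$p, 0.05)
})
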