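# Moderated t: analytic limits, agreement with the reference empirical-Bayes
# implementation, null calibration, planted-signal recovery.

de_cohort <- function(seed = 1, ...) {
  co <- generate_cohort(tiny_config(seed = seed, ...))
  g <- group_assignment(co$truth$groups$group1, co$truth$groups$group2)
  list(co = co, g = g)
}

test_that("prior df 0 reproduces the ordinary least squares t exactly", {
  d <- de_cohort(seed = 3)
  de <- suppressWarnings(
    fit_moderated_de(d$co$expression, d$co$manifest, d$g, prior_df = 0))
  # independent per-gene lm() fits on a subsample of genes
  tum <- d$co$manifest[d$co$manifest$study == "TCGA_TUMOR" &
                         d$co$manifest$cancer_type %in% c(d$g$group1, d$g$group2), ]
  x <- d$co$expression[, tum$sample_id]
  grp <- as.numeric(tum$cancer_type %in% d$g$group2)
  # same nested-dummy design, but fitted per gene through stats::lm
  refs <- c(sort(d$g$group1)[1], sort(d$g$group2)[1])
  dummies <- sapply(setdiff(sort(unique(tum$cancer_type)), refs),
                    function(ct) as.numeric(tum$cancer_type == ct))
  dm <- cbind(intercept = 1, grp = grp, dummies, esr1 = x["ESR1", ])
  set.seed(1)
  for (gene in sample(setdiff(rownames(x), "ESR1"), 12)) {
    fit <- stats::lm(x[gene, ] ~ 0 + dm)
    ref_t <- summary(fit)$coefficients["dmgrp", "t value"]
    expect_equal(de$results$t_moderated[de$results$gene_id == gene],
                 unname(ref_t), tolerance = 1e-8)
  }
})

test_that("infinite prior df pools every gene to the common prior variance", {
  d <- de_cohort(seed = 5)
  # no covariate gene, so no degenerate self-regressed row
  de0 <- fit_moderated_de(d$co$expression, d$co$manifest, d$g,
                          covariate_gene = NULL, prior_df = 0)
  deI <- fit_moderated_de(d$co$expression, d$co$manifest, d$g,
                          covariate_gene = NULL, prior_df = Inf)
  # with d0 -> Inf all genes share one variance, so t ratios across genes
  # equal coefficient ratios
  r <- deI$results
  expect_equal(r$t_moderated / r$log2_fc,
               rep((r$t_moderated / r$log2_fc)[1], nrow(r)),
               tolerance = 1e-9)
  # and the common variance is the pooled mean of the OLS residual variances
  v0 <- (de0$results$log2_fc / de0$results$t_moderated)^2
  vI <- (r$log2_fc / r$t_moderated)^2
  expect_equal(mean(vI), mean(v0), tolerance = 1e-9)
  expect_equal(sd(vI), 0, tolerance = 1e-12)
})

test_that("the fit agrees with the reference empirical-Bayes implementation", {
  skip_if_not_installed("limma")
  d <- de_cohort(seed = 7)
  de <- suppressWarnings(fit_moderated_de(d$co$expression, d$co$manifest, d$g))
  tum <- d$co$manifest[d$co$manifest$study == "TCGA_TUMOR" &
                         d$co$manifest$cancer_type %in% c(d$g$group1, d$g$group2), ]
  x <- d$co$expression[, tum$sample_id]
  grp <- as.numeric(tum$cancer_type %in% d$g$group2)
  refs <- c(sort(d$g$group1)[1], sort(d$g$group2)[1])
  dummies <- sapply(setdiff(sort(unique(tum$cancer_type)), refs),
                    function(ct) as.numeric(tum$cancer_type == ct))
  dm <- cbind(1, grp, dummies, esr1 = x["ESR1", ])
  fit <- suppressWarnings(limma::eBayes(limma::lmFit(x, dm)))
  expect_equal(de$prior_df, fit$df.prior, tolerance = 1e-6)
  expect_equal(de$results$t_moderated, unname(fit$t[, "grp"]), tolerance = 1e-9)
  expect_equal(de$results$p, unname(fit$p.value[, "grp"]), tolerance = 1e-9)
})

test_that("null p values are uniform under no group effect", {
  # pure-noise cohort: no DE genes, no uplift difference between the groups'
  # expression beyond what cancer-type dummies absorb
  set.seed(71)
  n <- 120
  expr <- matrix(rnorm(2000 * n), nrow = 2000,
                 dimnames = list(sprintf("g%04d", 1:2000), sprintf("s%03d", 1:n)))
  m <- tibble::tibble(
    sample_id = colnames(expr), study = "TCGA_TUMOR", tissue = "t",
    cancer_type = rep(c("AAA", "BBB"), each = n / 2), exclusion_class = "NONE")
  g <- group_assignment("AAA", "BBB")
  de <- fit_moderated_de(expr, m, g, covariate_gene = NULL,
                         adjust_cancer_type = FALSE)
  ks <- stats::ks.test(de$results$p, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("planted DE genes are recovered with few false positives", {
  d <- de_cohort(seed = 9, n_tumor = 100L)
  de <- suppressWarnings(fit_moderated_de(d$co$expression, d$co$manifest, d$g))
  parts <- volcano_partition(de)
  planted <- d$co$truth$de_genes$gene_id
  expect_gte(sum(planted %in% parts$up) / length(planted), 0.9)
  nulls <- grep("^BG", de$results$gene_id, value = TRUE)
  fp <- sum(de$results$significant[de$results$gene_id %in% nulls])
  expect_lte(fp / length(nulls), 0.05)
})

test_that("a missing covariate gene aborts instead of silently unadjusting", {
  d <- de_cohort(seed = 2)
  expect_error(fit_moderated_de(d$co$expression, d$co$manifest, d$g,
                                covariate_gene = "NOT_A_GENE"),
               "NOT_A_GENE")
})

test_that("aliased designs are rejected with the offending column named", {
  set.seed(10)
  expr <- matrix(rnorm(50 * 20), nrow = 50,
                 dimnames = list(sprintf("g%02d", 1:50), sprintf("s%02d", 1:20)))
  m <- tibble::tibble(
    sample_id = colnames(expr), study = "TCGA_TUMOR", tissue = "t",
    cancer_type = rep(c("AAA", "BBB"), each = 10), exclusion_class = "NONE")
  g <- group_assignment("AAA", "BBB")
  # constant covariate gene duplicates the intercept
  expr["g01", ] <- 1
  expect_error(fit_moderated_de(expr, m, g, covariate_gene = "g01"),
               "rank-deficient")
})

test_that("volcano partition applies strict thresholds", {
  res <- tibble::tibble(
    gene_id = c("a", "b", "c", "d"),
    log2_fc = c(2.0, 2.5, -2.5, -1.0),
    t_moderated = 0, p = c(1e-6, 1e-6, 1e-6, 1e-6),
    q = c(1e-5, 1e-5, 1e-5, 1e-5),
    significant = NA
  )
  parts <- volcano_partition(res, lfc = 2, fdr = 0.05)
  expect_identical(parts$up, "b")     # exactly 2.0 is excluded
  expect_identical(parts$down, "c")
  expect_identical(volcano_partition(res[0, ], lfc = 2, fdr = 0.05),
                   list(up = character(), down = character()))

  # brute-force filter oracle on random results
  set.seed(6)
  rr <- tibble::tibble(gene_id = sprintf("g%03d", 1:200),
                       log2_fc = rnorm(200, sd = 2), t_moderated = 0,
                       p = runif(200), q = runif(200), significant = NA)
  parts <- volcano_partition(rr, lfc = 1, fdr = 0.2)
  expect_setequal(parts$up, rr$gene_id[rr$q < 0.2 & rr$log2_fc > 1])
  expect_setequal(parts$down, rr$gene_id[rr$q < 0.2 & rr$log2_fc < -1])
})

test_that("rank statistic orders by signed significance with stable ties", {
  res <- tibble::tibble(
    gene_id = c("up", "down"), log2_fc = c(1, -1), t_moderated = c(2, -2),
    p = c(0.01, 0.01), q = 0.05, significant = TRUE)
  rk <- rank_statistic(res)
  expect_equal(names(rk), c("up", "down"))
  expect_equal(unname(rk), c(2, -2))  # sign * -log10(0.01)

  set.seed(13)
  rr <- tibble::tibble(gene_id = sprintf("g%03d", 1:100),
                       log2_fc = rnorm(100), t_moderated = rnorm(100),
                       p = runif(100), q = runif(100), significant = FALSE)
  rk <- rank_statistic(rr, "log2fc")
  expect_equal(names(rk), rr$gene_id[order(-rr$log2_fc, -abs(rr$log2_fc), rr$gene_id)])

  # signed_logp oracle
  rk2 <- rank_statistic(rr)
  manual <- sign(rr$log2_fc) * -log10(rr$p)
  expect_equal(unname(rk2), sort(manual, decreasing = TRUE))

  rr$p[1] <- 0
  expect_warning(rank_statistic(rr), "zero p")
  rr$p[1] <- NaN
  expect_error(rank_statistic(rr), "NaN")
})

test_that("tidy and glance expose the fit like any model object", {
  d <- de_cohort(seed = 4)
  de <- suppressWarnings(fit_moderated_de(d$co$expression, d$co$manifest, d$g))
  td <- tidy(de)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("gene_id", "log2_fc", "t_moderated", "p", "q", "significant"))
  gl <- glance(de)
  expect_equal(gl$n_genes, nrow(td))
  expect_equal(gl$n_up + gl$n_down, sum(td$significant))
})
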