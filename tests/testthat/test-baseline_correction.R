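# Baseline subtraction, purity adjustment, quadrant classification.

scores_for <- function(ids, values) {
  tibble::tibble(sample_id = ids, raw_score = values)
}

small_cohort_manifest <- function() {
  manual_manifest(
    list("N1", "GTEX", "Bladder", "", "NONE"),
    list("N2", "GTEX", "Bladder", "", "NONE"),
    list("N3", "GTEX", "Bladder", "", "NONE"),
    list("N4", "GTEX", "Bladder", "", "NONE"),
    list("M1", "GTEX", "Brain", "", "NONE"),
    list("M2", "GTEX", "Brain", "", "NONE"),
    list("M3", "GTEX", "Brain", "", "NONE"),
    list("T1", "TCGA_TUMOR", "Bladder", "BLCA", "NONE"),
    list("T2", "TCGA_TUMOR", "Brain", "GBM", "NONE")
  )
}

test_that("baselines are per-tissue medians over GTEX normals only", {
  m <- small_cohort_manifest()
  sc <- scores_for(c("N1", "N2", "N3", "N4", "M1", "M2", "M3", "T1", "T2"),
                   c(1, 2, 3, 4, 1, 2, 3, 100, 100))
  bl <- compute_baselines(sc, m)
  expect_equal(bl$median_normal_ccs[bl$tissue == "Bladder"], 2.5)  # even count
  expect_equal(bl$median_normal_ccs[bl$tissue == "Brain"], 2)      # odd count

  # TCGA adjacent normals are not part of the baseline
  m2 <- dplyr::bind_rows(m, manual_manifest(list("A1", "TCGA_NORMAL", "Brain", "", "NONE")))
  sc2 <- dplyr::bind_rows(sc, scores_for("A1", 1000))
  expect_equal(compute_baselines(sc2, m2), bl)

  # tumour tissue without normals is a hard error naming the tissue
  m3 <- dplyr::bind_rows(m, manual_manifest(list("T3", "TCGA_TUMOR", "Lung", "LUAD", "NONE")))
  sc3 <- dplyr::bind_rows(sc, scores_for("T3", 5))
  expect_error(compute_baselines(sc3, m3), "Lung")
})

test_that("baselines equal a brute-force sort-and-pick on a random cohort", {
  co <- generate_cohort(tiny_config(seed = 4))
  sc <- compute_signature_score(co$expression, co$gene_sets$CCS)
  bl <- compute_baselines(sc, co$manifest)
  for (t_name in unique(bl$tissue)) {
    ids <- co$manifest$sample_id[co$manifest$tissue == t_name &
                                   co$manifest$study == "GTEX"]
    v <- sort(sc$raw_score[match(ids, sc$sample_id)])
    n <- length(v)
    manual <- if (n %% 2 == 1) v[(n + 1) / 2] else mean(v[n / 2 + 0:1])
    expect_equal(bl$median_normal_ccs[bl$tissue == t_name], manual)
  }
})

test_that("baseline-corrected score is the plain difference, sign preserved", {
  m <- small_cohort_manifest()
  sc <- scores_for(c("N1", "N2", "N3", "N4", "M1", "M2", "M3", "T1", "T2"),
                   c(1, 2, 3, 4, 1, 2, 3, 2.5, 12))
  bl <- compute_baselines(sc, m)
  bc <- compute_bc_ccs(sc, bl, m)
  # tumour exactly at its baseline scores zero
  expect_equal(bc$bc_raw[bc$sample_id == "T1"], 0)
  # baseline 2, tumour 12 -> 10; and negative corrections survive
  expect_equal(bc$bc_raw[bc$sample_id == "T2"], 10)
  sc$raw_score[sc$sample_id == "T1"] <- 1
  bc2 <- compute_bc_ccs(sc, bl, m)
  expect_equal(bc2$bc_raw[bc2$sample_id == "T1"], -1.5)
})

test_that("normals corrected against their own tissue have median zero", {
  co <- generate_cohort(tiny_config(seed = 6))
  sc <- compute_signature_score(co$expression, co$gene_sets$CCS)
  bl <- compute_baselines(sc, co$manifest)
  normals <- co$manifest |>
    dplyr::filter(study == "GTEX") |>
    dplyr::inner_join(sc, by = "sample_id") |>
    dplyr::left_join(dplyr::select(bl, tissue, median_normal_ccs), by = "tissue") |>
    dplyr::mutate(bc = raw_score - median_normal_ccs) |>
    dplyr::group_by(tissue) |>
    dplyr::summarise(m = median(bc))
  expect_equal(normals$m, rep(0, nrow(normals)))
})

test_that("purity adjustment is an element-wise product with policy for gaps", {
  m <- small_cohort_manifest()
  sc <- scores_for(c("N1", "N2", "N3", "N4", "M1", "M2", "M3", "T1", "T2"),
                   c(1, 2, 3, 4, 1, 2, 3, 7.5, 12))
  bc <- compute_bc_ccs(sc, compute_baselines(sc, m), m)

  p1 <- tibble::tibble(sample_id = c("T1", "T2"), purity = c(1, 0))
  adj <- adjust_for_purity(bc, p1)
  expect_equal(adj$bc_purity_adjusted[adj$sample_id == "T1"],
               adj$bc_raw[adj$sample_id == "T1"])
  expect_equal(adj$bc_purity_adjusted[adj$sample_id == "T2"], 0)

  # element-wise product vs loop on a random cohort
  co <- generate_cohort(tiny_config(seed = 12))
  scr <- compute_signature_score(co$expression, co$gene_sets$CCS)
  bcr <- compute_bc_ccs(scr, compute_baselines(scr, co$manifest), co$manifest)
  adjr <- adjust_for_purity(bcr, co$purity)
  for (i in sample(nrow(adjr), 25)) {
    expect_equal(adjr$bc_purity_adjusted[i],
                 adjr$bc_raw[i] * co$purity$purity[co$purity$sample_id == adjr$sample_id[i]])
  }

  # missing purity: drop with warning, or impute the cancer-type mean
  p_missing <- tibble::tibble(sample_id = "T1", purity = 0.5)
  expect_warning(dropped <- adjust_for_purity(bc, p_missing, "drop"), "1 tumour")
  expect_equal(dropped$sample_id, "T1")
  expect_error(suppressWarnings(adjust_for_purity(bc, p_missing, "impute")),
               "no purity values")

  bad <- tibble::tibble(sample_id = "T1", purity = 1.7)
  expect_error(adjust_for_purity(bc, bad), "\\[0, 1\\]")
})

test_that("purity adjustment is monotone in purity with matching sign", {
  bc <- tibble::tibble(sample_id = c("a", "b"), tissue = "x", cancer_type = "X",
                       raw_score = c(5, 1), baseline = 3, bc_raw = c(2, -2))
  lo <- adjust_for_purity(bc, tibble::tibble(sample_id = c("a", "b"), purity = c(0.2, 0.2)))
  hi <- adjust_for_purity(bc, tibble::tibble(sample_id = c("a", "b"), purity = c(0.9, 0.9)))
  expect_gt(hi$bc_purity_adjusted[1], lo$bc_purity_adjusted[1])   # positive bc
  expect_lt(hi$bc_purity_adjusted[2], lo$bc_purity_adjusted[2])   # negative bc
})

test_that("quadrant classification maps extremes, ties, and affine shifts", {
  m <- manual_manifest(
    list("N1", "GTEX", "A", "", "NONE"), list("N2", "GTEX", "B", "", "NONE"),
    list("T1", "TCGA_TUMOR", "A", "ACAN", "NONE"),
    list("T2", "TCGA_TUMOR", "B", "BCAN", "NONE")
  )
  nsc <- scores_for(c("N1", "N2"), c(0, 10))
  tsc <- scores_for(c("T1", "T2"), c(0, 10))
  q <- classify_quadrants(nsc, tsc, m)
  expect_setequal(q$quadrant, c("LOW_LOW", "HIGH_HIGH"))

  # exact-threshold tie resolves HIGH on both axes
  m3 <- dplyr::bind_rows(m, manual_manifest(
    list("N3", "GTEX", "C", "", "NONE"),
    list("T3", "TCGA_TUMOR", "C", "CCAN", "NONE")))
  nsc3 <- dplyr::bind_rows(nsc, scores_for("N3", 5))
  tsc3 <- dplyr::bind_rows(tsc, scores_for("T3", 5))
  q3 <- classify_quadrants(nsc3, tsc3, m3)
  expect_equal(q3$quadrant[q3$tissue == "C"], "HIGH_HIGH")

  # common affine transform of all raw scores changes nothing
  aff <- function(s) dplyr::mutate(s, raw_score = 3 * raw_score + 17)
  q3b <- classify_quadrants(aff(nsc3), aff(tsc3), m3)
  expect_equal(as.data.frame(q3b), as.data.frame(q3))

  expect_error(classify_quadrants(nsc[1, ], tsc[1, ], m[c(1, 3), ]), "2 tissues")
})

test_that("four configured archetypes land in their four quadrants", {
  cfg <- synthetic_config(
    tissues = tibble::tibble(
      tissue = c("LowLow", "LowHigh", "HighLow", "HighHigh"),
      cancer_type = c("LL", "LH", "HL", "HH"),
      n_normal = 30L, n_tumor = 30L,
      baseline = c(1, 1, 8, 8),
      uplift = c(0.2, 8, 0.2, 8),
      group = NA_character_
    ),
    n_signature_genes = 20, n_background_genes = 10, n_metagene_genes = 5,
    n_de_genes = 0, noise_sd = 0.5, latent_sd = 0.1, seed = 2
  )
  co <- generate_cohort(cfg)
  sc <- compute_signature_score(co$expression, co$gene_sets$CCS)
  is_t <- co$manifest$study == "TCGA_TUMOR"
  q <- classify_quadrants(sc[match(co$manifest$sample_id[!is_t], sc$sample_id), ],
                          sc[match(co$manifest$sample_id[is_t], sc$sample_id), ],
                          co$manifest)
  expect_equal(q$quadrant[q$tissue == "LowLow"], "LOW_LOW")
  expect_equal(q$quadrant[q$tissue == "LowHigh"], "LOW_HIGH")
  expect_equal(q$quadrant[q$tissue == "HighLow"], "HIGH_LOW")
  expect_equal(q$quadrant[q$tissue == "HighHigh"], "HIGH_HIGH")
})

test_that("median corrected score ranks recover configured uplift ranks", {
  co <- generate_cohort(synthetic_config(seed = 19))
  sc <- compute_signature_score(co$expression, co$gene_sets$CCS)
  bc <- compute_bc_ccs(sc, compute_baselines(sc, co$manifest), co$manifest)
  med <- bc |>
    dplyr::group_by(tissue) |>
    dplyr::summarise(m = median(bc_raw))
  truth <- co$truth$tissues
  rho <- cor(med$m[match(truth$tissue, med$tissue)], truth$uplift,
             method = "spearman")
  expect_gte(rho, 0.95)
})
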