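# A deterministic fixture manifest reproducing the published sample-selection
# bookkeeping of the combined GTEx + TCGA pan-cancer cohort: 19,131 samples
# entering, four primary exclusions (not in the two datasets, no mRNA data,
# no matched site, group smaller than ten), then testis removal and
# embedding-outlier removal, leaving 13,117 samples (4,979 normals and 8,138
# tumours). Class totals are the published ones; the tissue composition
# within each class is synthetic (the breakdown is not public) and assigned
# deterministically over 17 matched tissue sites.

# tissue -> cancer types retained in the final cohort
.fixture_site_map <- function() {
  list(
    Bladder = "BLCA", Brain = c("GBM", "LGG"), Breast = "BRCA",
    Cervix = "CESC", Colon = "COAD", Esophagus = "ESCA", HeadNeck = "HNSC",
    Kidney = c("KICH", "KIRC", "KIRP"), Liver = "LIHC",
    Lung = c("LUAD", "LUSC"), Ovary = "OV", Pancreas = "PAAD",
    Prostate = "PRAD", Skin = "SKCM", Stomach = "STAD", Thyroid = "THCA",
    Uterus = c("UCEC", "UCS")
  )
}

# Deterministically split `total` into `k` parts differing by at most 1.
.even_split <- function(total, k) {
  base <- total %/% k
  extra <- total %% k
  base + c(rep(1L, extra), rep(0L, k - extra))
}

#' Generate the CONSORT fixture manifest
#'
#' Builds a 19,131-sample manifest whose exclusion-class totals reproduce the
#' published filter cascade exactly: 734 samples from other datasets, 92
#' without mRNA data, 802 without a matched normal/tumour site, 4,043 in
#' groups of fewer than ten samples, 319 testicular samples, and 24
#' embedding outliers, leaving 13,117 retained samples that split into 4,979
#' normals and 8,138 tumours. Construction is deterministic (no randomness);
#' the within-class tissue composition is synthetic.
#'
#' @return A validated manifest tibble with 19,131 rows.
#' @seealso [apply_consort_filters()], [remove_flagged_outliers()]
#' @export
generate_consort_fixture <- function() {
  site_map <- .fixture_site_map()
  tissues <- names(site_map)
  cancers <- unlist(site_map, use.names = FALSE)

  rows <- list()
  add <- function(n, study, tissue, cancer_type, class) {
    if (n <= 0) return(invisible(NULL))
    rows[[length(rows) + 1L]] <<- tibble(
      n = n, study = study, tissue = tissue,
      cancer_type = cancer_type, exclusion_class = class
    )
    invisible(NULL)
  }

  # retained cohort: 4,979 normals + 8,138 tumours over the 17 matched sites
  n_normal <- .even_split(4979L, length(tissues))
  for (i in seq_along(tissues)) {
    # a fraction of normals come from adjacent-normal TCGA tissue
    n_tcga_n <- n_normal[i] %/% 5L
    add(n_normal[i] - n_tcga_n, "GTEX", tissues[i], "", "NONE")
    add(n_tcga_n, "TCGA_NORMAL", tissues[i], "", "NONE")
  }
  n_tumor <- .even_split(8138L, length(cancers))
  tissue_of_cancer <- rep(tissues, lengths(site_map))
  for (i in seq_along(cancers)) {
    add(n_tumor[i], "TCGA_TUMOR", tissue_of_cancer[i], cancers[i], "NONE")
  }

  # excluded classes (composition synthetic, totals as published)
  add(734L, "GTEX", "OtherDataset", "", "OTHER_DATASET")
  add(92L, "GTEX", "Brain", "", "NO_MRNA")
  add(802L, "GTEX", "UnmatchedSite", "", "NO_MATCHED_SITE")
  # small groups: many tiny normal-tissue groups, removed by the <10 rule
  n_small <- 4043L
  small_per <- 9L
  k_small <- ceiling(n_small / small_per)
  small_sizes <- .even_split(n_small, k_small)
  for (j in seq_len(k_small)) {
    add(small_sizes[j], "GTEX", sprintf("SmallSite%03d", j), "", "SMALL_GROUP")
  }
  add(319L, "GTEX", "Testis", "", "TESTIS")
  # embedding outliers of mixed origin, within retained tissues
  add(16L, "GTEX", "Skin", "", "EMBEDDING_OUTLIER")
  add(8L, "TCGA_TUMOR", "Lung", "LUAD", "EMBEDDING_OUTLIER")

  manifest <- bind_rows(rows) |>
    tidyr::uncount(weights = .data$n) |>
    mutate(sample_id = sprintf("FIX%05d", row_number())) |>
    select("sample_id", "study", "tissue", "cancer_type", "exclusion_class")
  validate_manifest(manifest)
  stopifnot(nrow(manifest) == 19131L)
  manifest
}
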