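# Baseline correction: the tumour score minus the median score of its
# normal tissue of origin, then multiplied by tumour purity, then min-max
# rescaled. The order of operations is fixed — subtract, multiply, scale —
# and the baseline uses normal-tissue reference (GTEX) samples only.

#' Per-tissue normal baselines
#'
#' The baseline of a tissue is the median raw score over its normal
#' reference (GTEX study) samples; an even count takes the mean of the two
#' central values.
#'
#' @param scores A `bccs_scores` tibble covering at least the normal samples.
#' @param manifest A manifest tibble.
#' @return A tibble (`tissue`, `median_normal_ccs`, `n_normals`) with one
#'   row per tissue that has GTEX normals. Every tissue carrying tumours
#'   must have at least one scored normal, otherwise a hard error lists the
#'   orphaned tissues.
#' @export
compute_baselines <- function(scores, manifest) {
  validate_manifest(manifest)
  normals <- manifest |>
    filter(.data$study == "GTEX") |>
    inner_join(as_tibble(scores), by = "sample_id")
  baselines <- normals |>
    group_by(.data$tissue) |>
    summarise(median_normal_ccs = median(.data$raw_score),
              n_normals = n(), .groups = "drop")
  tumor_tissues <- unique(manifest$tissue[manifest$study == "TCGA_TUMOR"])
  orphans <- setdiff(tumor_tissues, baselines$tissue)
  if (length(orphans) > 0) {
    .stop(paste0("tumour tissue(s) with no scored GTEX normals: ",
                 paste(orphans, collapse = ", ")))
  }
  baselines
}

#' Baseline-corrected score per tumour
#'
#' For every tumour sample, subtracts the baseline (median normal score) of
#' its tissue of origin from its raw score. The sign is preserved: a tumour
#' below its tissue baseline gets a negative corrected score.
#'
#' @param tumor_scores A `bccs_scores` tibble covering the tumour samples.
#' @param baselines Output of [compute_baselines()].
#' @param manifest A manifest tibble.
#' @return A tibble (`sample_id`, `tissue`, `cancer_type`, `raw_score`,
#'   `baseline`, `bc_raw`) with one row per scored tumour sample.
#' @export
compute_bc_ccs <- function(tumor_scores, baselines, manifest) {
  validate_manifest(manifest)
  tumors <- manifest |>
    filter(.data$study == "TCGA_TUMOR") |>
    inner_join(as_tibble(tumor_scores), by = "sample_id")
  missing_bl <- setdiff(unique(tumors$tissue), baselines$tissue)
  if (length(missing_bl) > 0) {
    .stop(paste0("no baseline for tissue(s): ", paste(missing_bl, collapse = ", ")))
  }
  tumors |>
    left_join(select(baselines, "tissue", baseline = "median_normal_ccs"),
              by = "tissue") |>
    mutate(bc_raw = .data$raw_score - .data$baseline) |>
    select("sample_id", "tissue", "cancer_type", "raw_score", "baseline", "bc_raw")
}

#' Multiply corrected scores by tumour purity
#'
#' Adjusts each tumour's baseline-corrected score for its malignant-cell
#' fraction: `bc_purity_adjusted = bc_raw * purity`. Purity 1 is the
#' identity; purity 0 collapses the score to 0.
#'
#' @param bc Output of [compute_bc_ccs()].
#' @param purity A purity tibble (`sample_id`, `purity` in \[0, 1\]).
#' @param missing `"drop"` (default) removes tumours without a purity value,
#'   with a warning stating how many; `"impute"` substitutes the mean purity
#'   of the tumour's cancer type.
#' @return `bc` with `purity` and `bc_purity_adjusted` columns added.
#' @export
adjust_for_purity <- function(bc, purity, missing = c("drop", "impute")) {
  missing <- match.arg(missing)
  if (any(!is.finite(purity$purity)) || any(purity$purity < 0 | purity$purity > 1)) {
    .stop("purity values must be in [0, 1]")
  }
  out <- left_join(bc, purity, by = "sample_id")
  n_missing <- sum(is.na(out$purity))
  if (n_missing > 0) {
    if (missing == "drop") {
      warn(sprintf("%d tumour(s) without purity dropped", n_missing))
      out <- filter(out, !is.na(.data$purity))
    } else {
      out <- out |>
        group_by(.data$cancer_type) |>
        mutate(purity = ifelse(is.na(.data$purity),
                               mean(.data$purity, na.rm = TRUE), .data$purity)) |>
        ungroup()
      if (any(is.na(out$purity))) {
        .stop("cancer type(s) with no purity values at all: cannot impute")
      }
    }
  }
  mutate(out, bc_purity_adjusted = .data$bc_raw * .data$purity)
}

#' Classify tissues into low/high cell-cycle quadrants
#'
#' Computes per-tissue medians of the scaled score separately for normal and
#' tumour samples, min-max rescales each axis to \[0, 1\] across tissues,
#' and assigns each tissue to a quadrant by comparing both axes to a
#' threshold. A median exactly at the threshold counts as HIGH on that axis.
#'
#' @param normal_scores,tumor_scores `bccs_scores` tibbles for normal and
#'   tumour samples (raw scores; scaling is done internally per axis).
#' @param manifest A manifest tibble.
#' @param threshold Quadrant cut on the scaled axes, in (0, 1); default 0.5.
#' @return A tibble (`tissue`, `median_normal_scaled`, `median_tumor_scaled`,
#'   `quadrant`) of class `bccs_quadrants`, quadrants in
#'   \{`LOW_LOW`, `LOW_HIGH`, `HIGH_LOW`, `HIGH_HIGH`\} (normal axis first).
#' @export
classify_quadrants <- function(normal_scores, tumor_scores, manifest,
                               threshold = 0.5) {
  validate_manifest(manifest)
  if (threshold <= 0 || threshold >= 1) .stop("threshold must be in (0, 1)")
  is_tumor <- manifest$study == "TCGA_TUMOR"
  med_normal <- manifest[!is_tumor, ] |>
    inner_join(as_tibble(normal_scores), by = "sample_id") |>
    group_by(.data$tissue) |>
    summarise(median_normal = median(.data$raw_score), .groups = "drop")
  med_tumor <- manifest[is_tumor, ] |>
    inner_join(as_tibble(tumor_scores), by = "sample_id") |>
    group_by(.data$tissue) |>
    summarise(median_tumor = median(.data$raw_score), .groups = "drop")
  quad <- inner_join(med_normal, med_tumor, by = "tissue")
  if (nrow(quad) < 2) .stop("quadrant scaling is degenerate with fewer than 2 tissues")
  quad <- quad |>
    minmax_rescale(from = "median_normal", to = "median_normal_scaled") |>
    minmax_rescale(from = "median_tumor", to = "median_tumor_scaled") |>
    mutate(
      quadrant = paste0(
        ifelse(.data$median_normal_scaled >= threshold, "HIGH", "LOW"), "_",
        ifelse(.data$median_tumor_scaled >= threshold, "HIGH", "LOW")
      )
    ) |>
    select("tissue", "median_normal_scaled", "median_tumor_scaled", "quadrant")
  structure(quad, threshold = threshold,
            class = c("bccs_quadrants", class(tibble())))
}
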