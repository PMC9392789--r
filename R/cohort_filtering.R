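# CONSORT-style exclusion cascade. Filtering is label-driven: each sample
# carries an exclusion_class, and the cascade removes classes in a fixed
# top-to-bottom order so stage-conditional counts are reproducible. A
# FilterReport tibble records (stage, n_removed, n_remaining) per stage and
# always reconciles: initial n minus the removals equals the final n.

.new_filter_report <- function(stages = tibble(stage = character(),
                                               n_removed = integer(),
                                               n_remaining = integer())) {
  structure(stages, class = c("bccs_filter_report", class(tibble())))
}

.report_stage <- function(report, stage, n_removed, n_remaining) {
  bind_rows(report, tibble(stage = stage, n_removed = as.integer(n_removed),
                           n_remaining = as.integer(n_remaining))) |>
    .new_filter_report()
}

.check_report <- function(report, n_initial) {
  if (nrow(report) == 0) return(invisible(report))
  if (any(diff(report$n_remaining) > 0)) .stop("filter report: n_remaining increased")
  expected <- n_initial - cumsum(report$n_removed)
  if (!all(report$n_remaining == expected)) {
    .stop("filter report does not reconcile: n_initial - removals != n_remaining")
  }
  invisible(report)
}

#' Apply the primary CONSORT exclusion cascade
#'
#' Removes samples flagged with the four primary exclusion classes in fixed
#' cascade order: `OTHER_DATASET` (not part of the two source datasets), then
#' `NO_MRNA` (no expression data), then `NO_MATCHED_SITE` (no matching
#' normal/tumour site in both studies), then `SMALL_GROUP` (tissue or cancer
#' group under the minimum size).
#'
#' @param manifest A manifest tibble (see [read_manifest()]).
#' @return A list with `manifest` (retained samples) and `report` (a
#'   per-stage tibble of class `bccs_filter_report` with columns `stage`,
#'   `n_removed`, `n_remaining`).
#' @export
apply_consort_filters <- function(manifest) {
  validate_manifest(manifest)
  report <- .new_filter_report()
  n0 <- nrow(manifest)
  for (stage in .primary_exclusions) {
    keep <- manifest$exclusion_class != stage
    report <- .report_stage(report, stage, sum(!keep), sum(keep))
    manifest <- manifest[keep, , drop = FALSE]
  }
  .check_report(report, n0)
  list(manifest = manifest, report = report)
}

#' Remove groups smaller than a minimum size
#'
#' Flags-independent reapplication of the small-group rule: every normal
#' tissue group and every cancer-type group with fewer than `min_n` samples
#' is removed, after which site matching is re-checked so every retained
#' tumour type still has retained normal tissue of origin and vice versa.
#'
#' @param manifest A manifest tibble.
#' @param min_n Minimum group size (default 10; groups of exactly `min_n`
#'   are kept).
#' @return The filtered manifest tibble.
#' @export
apply_small_group_rule <- function(manifest, min_n = 10) {
  validate_manifest(manifest)
  if (min_n < 1) .stop("min_n must be >= 1")
  is_tumor <- manifest$study == "TCGA_TUMOR"

  normal_sizes <- table(manifest$tissue[!is_tumor])
  keep_tissue_n <- names(normal_sizes)[normal_sizes >= min_n]
  cancer_sizes <- table(manifest$cancer_type[is_tumor])
  keep_cancer <- names(cancer_sizes)[cancer_sizes >= min_n]

  manifest <- manifest[(!is_tumor & manifest$tissue %in% keep_tissue_n) |
                         (is_tumor & manifest$cancer_type %in% keep_cancer), ,
                       drop = FALSE]

  # re-check site matching on the survivors
  is_tumor <- manifest$study == "TCGA_TUMOR"
  matched <- intersect(unique(manifest$tissue[!is_tumor]),
                       unique(manifest$tissue[is_tumor]))
  manifest[manifest$tissue %in% matched, , drop = FALSE]
}

#' Remove explicitly flagged samples
#'
#' Removes testis samples or embedding outliers by explicit sample-id flags,
#' extending a filter report. Removal is label-driven, mirroring exclusion
#' by annotated origin rather than by embedding geometry.
#'
#' @param manifest A manifest tibble.
#' @param flags Character vector of sample ids to remove; must all be
#'   present in the manifest.
#' @param reason `"TESTIS"` or `"EMBEDDING_OUTLIER"`.
#' @param report Optionally, a `bccs_filter_report` to extend.
#' @return A list with `manifest` and `report`.
#' @export
remove_flagged_outliers <- function(manifest, flags,
                                    reason = c("TESTIS", "EMBEDDING_OUTLIER"),
                                    report = NULL) {
  validate_manifest(manifest)
  reason <- match.arg(reason)
  flags <- unique(as.character(flags))
  unknown <- setdiff(flags, manifest$sample_id)
  if (length(unknown) > 0) {
    .stop(paste0("flagged sample id(s) not in manifest: ",
                 paste(head(unknown, 5), collapse = ", ")))
  }
  report <- report %||% .new_filter_report()
  keep <- !(manifest$sample_id %in% flags)
  report <- .report_stage(report, reason, sum(!keep), sum(keep))
  list(manifest = manifest[keep, , drop = FALSE], report = report)
}

#' Summarise a filtered cohort
#'
#' @param manifest A manifest tibble after filtering.
#' @return A one-row tibble with `n_samples`, `n_normals` (GTEX plus TCGA
#'   adjacent normals) and `n_tumors`.
#' @export
cohort_summary <- function(manifest) {
  validate_manifest(manifest)
  tibble(
    n_samples = nrow(manifest),
    n_normals = sum(manifest$study %in% c("GTEX", "TCGA_NORMAL")),
    n_tumors = sum(manifest$study == "TCGA_TUMOR")
  )
}
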