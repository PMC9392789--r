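# Internal helpers shared across modules.

# Study labels a manifest may carry.
.studies <- c("GTEX", "TCGA_NORMAL", "TCGA_TUMOR")

# Exclusion classes, in the cascade order they are applied.
.exclusion_classes <- c(
  "NONE", "OTHER_DATASET", "NO_MRNA", "NO_MATCHED_SITE",
  "SMALL_GROUP", "TESTIS", "EMBEDDING_OUTLIER"
)

.primary_exclusions <- c("OTHER_DATASET", "NO_MRNA", "NO_MATCHED_SITE", "SMALL_GROUP")

# stop() with a classed condition so tests can assert on the class.
.stop <- function(msg, class = "bccs_error") {
  abort(msg, class = c(class, "bccs_error"))
}

.assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    .stop(sprintf(
      "`%s` must be a single finite number in [%s, %s], got: %s",
      name, format(lower), format(upper), paste(format(x), collapse = ", ")
    ))
  }
  invisible(x)
}

# Validate a manifest tibble; returns it invisibly on success.
validate_manifest <- function(manifest) {
  required <- c("sample_id", "study", "tissue", "cancer_type", "exclusion_class")
  missing_cols <- setdiff(required, names(manifest))
  if (length(missing_cols) > 0) {
    .stop(paste0("manifest is missing column(s): ", paste(missing_cols, collapse = ", ")),
          class = "bccs_format_error")
  }
  dup <- manifest$sample_id[duplicated(manifest$sample_id)]
  if (length(dup) > 0) {
    .stop(paste0("duplicate sample_id(s): ", paste(unique(dup), collapse = ", ")),
          class = "bccs_validation_error")
  }
  bad_study <- setdiff(unique(manifest$study), .studies)
  if (length(bad_study) > 0) {
    .stop(paste0("unknown study token(s): ", paste(bad_study, collapse = ", ")),
          class = "bccs_validation_error")
  }
  bad_class <- setdiff(unique(manifest$exclusion_class), .exclusion_classes)
  if (length(bad_class) > 0) {
    .stop(paste0("unknown exclusion_class token(s): ", paste(bad_class, collapse = ", ")),
          class = "bccs_validation_error")
  }
  # tumours carry a cancer type, normals an empty string
  ct <- manifest$cancer_type
  ct[is.na(ct)] <- ""
  is_tumor <- manifest$study == "TCGA_TUMOR"
  if (any(is_tumor & ct == "")) {
    .stop("TCGA_TUMOR samples must have a non-empty cancer_type",
          class = "bccs_validation_error")
  }
  if (any(!is_tumor & ct != "")) {
    .stop("non-tumour samples must have an empty cancer_type",
          class = "bccs_validation_error")
  }
  invisible(manifest)
}

# Validate a genes x samples expression matrix.
.validate_expression <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr)) {
    .stop("expression must be a numeric matrix (genes x samples)")
  }
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    .stop("expression matrix must have gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(expr)) || anyDuplicated(colnames(expr))) {
    .stop("expression gene and sample ids must be unique")
  }
  if (any(!is.finite(expr))) {
    bad <- which(!is.finite(expr), arr.ind = TRUE)[1, ]
    .stop(sprintf(
      "non-finite expression value at gene '%s', sample '%s'",
      rownames(expr)[bad[1]], colnames(expr)[bad[2]]
    ))
  }
  invisible(expr)
}
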