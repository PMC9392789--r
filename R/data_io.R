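# Readers and writers for the on-disk artefacts consumed and produced by the
# pipeline. All tabular files are tab-separated, UTF-8, "." decimal, no
# quoting; expression can also travel as Matrix Market (.mtx) with
# .genes.txt / .samples.txt sidecars. Readers validate hard: unknown enum
# tokens, duplicate ids, and non-finite values are errors, never warnings.

#' Read a sample manifest
#'
#' A manifest lists one sample per row with its study of origin, normal
#' tissue-of-origin label, cancer-type code (empty for normals), and an
#' exclusion class driving the CONSORT filter cascade.
#'
#' @param path Path to a TSV with header columns `sample_id`, `study`,
#'   `tissue`, `cancer_type`, `exclusion_class`.
#' @return A tibble with those five character columns, validated: sample ids
#'   unique, `study` one of `GTEX`, `TCGA_NORMAL`, `TCGA_TUMOR`,
#'   `exclusion_class` a known token, and `cancer_type` non-empty exactly for
#'   `TCGA_TUMOR` rows.
#' @seealso [write_manifest()], [generate_consort_fixture()]
#' @export
read_manifest <- function(path) {
  manifest <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, na = character()
  )
  required <- c("sample_id", "study", "tissue", "cancer_type", "exclusion_class")
  missing_cols <- setdiff(required, names(manifest))
  if (length(missing_cols) > 0) {
    .stop(paste0("manifest file is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "bccs_format_error")
  }
  manifest <- manifest[, required]
  validate_manifest(manifest)
  manifest
}

#' Write a sample manifest
#'
#' @param manifest A manifest tibble (see [read_manifest()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  readr::write_tsv(manifest, path, quote = "none", progress = FALSE)
  invisible(path)
}

#' Read a genes x samples expression matrix
#'
#' Expression is consumed on an already-normalised log2-like scale; the
#' loader performs no transformation. Two dialects are supported: a dense TSV
#' with genes as rows (first column `gene_id`, one column per sample), or a
#' Matrix Market file `<path>` accompanied by sidecar files `<path>.genes.txt`
#' and `<path>.samples.txt` holding row and column names, one per line.
#'
#' @param path Path to the TSV or MTX file.
#' @param format `"tsv"` or `"mtx"`.
#' @return A dense numeric matrix with gene rownames and sample colnames, in
#'   on-disk order. Any missing or non-finite cell is a hard error reporting
#'   the offending gene and sample.
#' @export
read_expression <- function(path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
    if (names(tab)[1] != "gene_id") {
      .stop("expression TSV must have 'gene_id' as its first column",
            class = "bccs_format_error")
    }
    genes <- tab$gene_id
    expr <- as.matrix(tab[, -1, drop = FALSE])
    storage.mode(expr) <- "double"
    rownames(expr) <- genes
  } else {
    m <- Matrix::readMM(path)
    genes <- readLines(paste0(path, ".genes.txt"))
    samples <- readLines(paste0(path, ".samples.txt"))
    if (nrow(m) != length(genes) || ncol(m) != length(samples)) {
      .stop(sprintf(
        "MTX dimensions (%d x %d) do not match sidecars (%d genes, %d samples)",
        nrow(m), ncol(m), length(genes), length(samples)
      ), class = "bccs_format_error")
    }
    expr <- as.matrix(m)
    dimnames(expr) <- list(genes, samples)
  }
  .validate_expression(expr)
  expr
}

#' Write a genes x samples expression matrix
#'
#' @param expr Numeric matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @param format `"tsv"` (dense, genes as rows) or `"mtx"` (Matrix Market
#'   with `.genes.txt`/`.samples.txt` sidecars next to `path`).
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  .validate_expression(expr)
  if (format == "tsv") {
    tab <- as_tibble(expr, rownames = "gene_id")
    readr::write_tsv(tab, path, quote = "none", progress = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(expr, sparse = TRUE), path)
    writeLines(rownames(expr), paste0(path, ".genes.txt"))
    writeLines(colnames(expr), paste0(path, ".samples.txt"))
  }
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `name`, `description`, then one or more gene ids. The description is
#' discarded; duplicate genes within a set are deduplicated with a warning.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors (set name -> unique gene ids).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  set_names <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      .stop(sprintf("GMT line %d has %d field(s); at least 3 required (name, description, genes)",
                    i, length(fields)),
            class = "bccs_format_error")
    }
    genes <- fields[-(1:2)]
    if (anyDuplicated(genes)) {
      warn(sprintf("gene set '%s': %d duplicate gene id(s) removed",
                   fields[1], sum(duplicated(genes))))
      genes <- unique(genes)
    }
    set_names[i] <- fields[1]
    sets[[i]] <- genes
  }
  setNames(sets, set_names)
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Description field written for every set (GMT requires
#'   one; it carries no information here).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    .stop("gene sets must be a named list")
  }
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description, sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a tumour purity table
#'
#' @param path TSV with columns `sample_id`, `purity`.
#' @return Tibble with `sample_id` (character) and `purity` (double in
#'   \[0, 1\]); out-of-range values are a hard error.
#' @export
read_purity <- function(path) {
  tab <- readr::read_tsv(
    path,
    col_types = readr::cols(sample_id = readr::col_character(),
                            purity = readr::col_double()),
    progress = FALSE
  )
  if (any(!is.finite(tab$purity)) || any(tab$purity < 0 | tab$purity > 1)) {
    .stop("purity values must be finite fractions in [0, 1]",
          class = "bccs_validation_error")
  }
  if (anyDuplicated(tab$sample_id)) {
    .stop("duplicate sample_id in purity table", class = "bccs_validation_error")
  }
  tab
}

#' @rdname read_purity
#' @param purity A purity tibble.
#' @export
write_purity <- function(purity, path) {
  readr::write_tsv(purity, path, quote = "none", progress = FALSE)
  invisible(path)
}

#' Read a binary driver-gene mutation matrix
#'
#' @param path TSV with genes as rows: first column `gene_id`, one 0/1 column
#'   per sample (1 = non-silent mutation present).
#' @return Integer matrix (genes x samples) with values in \{0, 1\}.
#' @export
read_mutations <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  if (names(tab)[1] != "gene_id") {
    .stop("mutation TSV must have 'gene_id' as its first column",
          class = "bccs_format_error")
  }
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$gene_id
  if (any(is.na(m)) || !all(m %in% c(0, 1))) {
    .stop("mutation matrix must be binary (0/1) with no missing values",
          class = "bccs_validation_error")
  }
  storage.mode(m) <- "integer"
  m
}

#' @rdname read_mutations
#' @param mutations A binary genes x samples matrix.
#' @export
write_mutations <- function(mutations, path) {
  tab <- as_tibble(mutations, rownames = "gene_id")
  readr::write_tsv(tab, path, quote = "none", progress = FALSE)
  invisible(path)
}

#' Read a chromosome-arm call matrix
#'
#' Arm-level somatic copy-number calls, one row per arm: -1 for an arm lost,
#' +1 for an arm gained, 0 for no alteration.
#'
#' @param path TSV with first column `arm`, one column per sample.
#' @return Integer matrix (arms x samples) with values in \{-1, 0, 1\}. Arm
#'   ids must be drawn from [autosomal_arms()].
#' @export
read_arm_calls <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  if (names(tab)[1] != "arm") {
    .stop("arm-call TSV must have 'arm' as its first column",
          class = "bccs_format_error")
  }
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$arm
  bad_arm <- setdiff(rownames(m), autosomal_arms())
  if (length(bad_arm) > 0) {
    .stop(paste0("unknown arm id(s): ", paste(bad_arm, collapse = ", ")),
          class = "bccs_validation_error")
  }
  if (any(is.na(m)) || !all(m %in% c(-1, 0, 1))) {
    .stop("arm calls must be -1, 0 or +1 with no missing values",
          class = "bccs_validation_error")
  }
  storage.mode(m) <- "integer"
  m
}

#' @rdname read_arm_calls
#' @param arm_calls An arms x samples matrix with values in \{-1, 0, 1\}.
#' @export
write_arm_calls <- function(arm_calls, path) {
  tab <- as_tibble(arm_calls, rownames = "arm")
  readr::write_tsv(tab, path, quote = "none", progress = FALSE)
  invisible(path)
}
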