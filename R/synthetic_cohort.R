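# Synthetic paired normal/tumour cohort with known ground truth. The
# generator emulates the statistical structure the pipeline assumes:
# tissue-specific baseline expression of cell-cycle signature genes, a
# tumour-specific uplift on top of that baseline, a shared per-sample
# proliferation latent coupling the signature to a disjoint metagene,
# Beta-distributed tumour purity, group-enriched driver mutations and
# arm-level calls, and a hormone module shifted in the high-activity group.
# Expression is Gaussian on the log scale throughout: the pipeline consumes
# already-normalised log expression and never models counts.

#' Build a synthetic cohort configuration
#'
#' The defaults describe a desk-scale pan-cancer cohort of eight tissue sites
#' (one cancer type each), spanning the observed spectrum from high-baseline /
#' low-uplift (head & neck, kidney) to low-baseline / high-uplift
#' (gynaecological) cell-cycle activity. Four low-uplift cancer types form
#' the "low" comparison group and two gynaecological types the "high" group,
#' mirroring a lowest-vs-highest corrected-activity contrast.
#'
#' @param tissues Tibble with columns `tissue`, `cancer_type`, `n_normal`,
#'   `n_tumor`, `baseline`, `uplift`, `group` (`"low"`, `"high"` or `NA`).
#'   `baseline` is the mean log2 expression of each signature gene in normal
#'   tissue; `uplift` (>= 0) the additional mean in tumours of that tissue.
#' @param n_signature_genes,n_background_genes,n_metagene_genes,n_de_genes
#'   Gene counts for the cell-cycle signature, null background, the disjoint
#'   proliferation metagene, and planted differentially expressed genes.
#' @param noise_sd Residual SD of log expression (all genes).
#' @param latent_sd SD of the per-sample proliferation latent added to every
#'   signature and metagene gene (couples the two sets within tissue).
#' @param purity_beta `c(alpha, beta)` of the Beta distribution tumour purity
#'   is drawn from.
#' @param mutation_base_rate Per-gene background mutation probability.
#' @param mutation_rates Optional named vector of per-gene base rates
#'   overriding `mutation_base_rate` (e.g. a TP53-like gene at 0.4).
#' @param mutation_enrichment Named vector of odds multipliers applied to the
#'   "high"-group mutation probability of the named driver genes.
#' @param n_driver_genes Number of driver genes in the mutation table.
#' @param arm_base_rate Background per-arm gain and loss probability (both
#'   groups).
#' @param arm_enrichment Tibble with columns `arm`, `direction` (`"loss"` or
#'   `"gain"`), `rate_low`, `rate_high`: per-group alteration probabilities
#'   for planted arms (losses emitted as -1, gains as +1).
#' @param hormone_module_shift Mean log2 shift of the hormone-module genes
#'   (ESR1, PGR, AR plus module members) in "high"-group tumours.
#' @param de_log2fc True log2 fold change of the planted DE genes
#'   ("high" minus "low" group tumours).
#' @param correlated_gene_rho Target correlation between the planted
#'   activity-tracking gene and the per-sample (uplift + latent) signal.
#' @param seed Integer seed; the generator derives a deterministic sub-stream
#'   per component so adding components never perturbs earlier draws.
#' @return A validated config list of class `bccs_synthetic_config`.
#' @export
synthetic_config <- function(
    tissues = default_tissue_specs(),
    n_signature_genes = 50,
    n_background_genes = 300,
    n_metagene_genes = 20,
    n_de_genes = 30,
    noise_sd = 1,
    latent_sd = 0.5,
    purity_beta = c(5, 2.5),
    mutation_base_rate = 0.05,
    mutation_rates = c(TP53 = 0.45, PIK3CA = 0.30, PTEN = 0.20, FBXW7 = 0.15),
    mutation_enrichment = c(FBXW7 = 3),
    n_driver_genes = 60,
    arm_base_rate = 0.10,
    arm_enrichment = default_arm_enrichment(),
    hormone_module_shift = 1.5,
    de_log2fc = 3,
    correlated_gene_rho = 0.6,
    seed = 1L) {
  tissues <- as_tibble(tissues)
  required <- c("tissue", "cancer_type", "n_normal", "n_tumor",
                "baseline", "uplift", "group")
  if (!all(required %in% names(tissues))) {
    .stop(paste0("tissues must have columns: ", paste(required, collapse = ", ")))
  }
  if (nrow(tissues) < 2) .stop("at least 2 tissues required")
  if (anyDuplicated(tissues$tissue) || anyDuplicated(tissues$cancer_type)) {
    .stop("tissue and cancer_type labels must be unique")
  }
  if (any(tissues$n_normal < 1) || any(tissues$n_tumor < 1)) {
    .stop("n_normal and n_tumor must be >= 1 for every tissue")
  }
  if (any(tissues$uplift < 0)) .stop("tumor uplift must be >= 0")
  .assert_scalar_number(noise_sd, "noise_sd", lower = .Machine$double.xmin)
  .assert_scalar_number(latent_sd, "latent_sd", lower = 0)
  if (length(purity_beta) != 2 || any(purity_beta <= 0)) {
    .stop("purity_beta must be two positive shape parameters")
  }
  .assert_scalar_number(mutation_base_rate, "mutation_base_rate", 0, 1)
  .assert_scalar_number(arm_base_rate, "arm_base_rate", 0, 0.5)
  if (!is.null(arm_enrichment) && nrow(arm_enrichment) > 0) {
    if (!all(arm_enrichment$arm %in% autosomal_arms())) {
      .stop("arm_enrichment arms must be standard autosomal arms")
    }
    if (!all(arm_enrichment$direction %in% c("gain", "loss"))) {
      .stop("arm_enrichment direction must be 'gain' or 'loss'")
    }
    rates <- c(arm_enrichment$rate_low, arm_enrichment$rate_high)
    if (any(rates < 0 | rates > 1)) .stop("arm enrichment rates must be in [0, 1]")
  }
  if (any(mutation_rates < 0 | mutation_rates > 1)) {
    .stop("mutation_rates must be probabilities in [0, 1]")
  }
  if (any(mutation_enrichment <= 0)) .stop("odds multipliers must be > 0")
  .assert_scalar_number(correlated_gene_rho, "correlated_gene_rho", 0, 0.99)
  seed <- as.integer(seed)

  structure(
    list(
      tissues = tissues,
      n_signature_genes = as.integer(n_signature_genes),
      n_background_genes = as.integer(n_background_genes),
      n_metagene_genes = as.integer(n_metagene_genes),
      n_de_genes = as.integer(n_de_genes),
      noise_sd = noise_sd,
      latent_sd = latent_sd,
      purity_beta = purity_beta,
      mutation_base_rate = mutation_base_rate,
      mutation_rates = mutation_rates,
      mutation_enrichment = mutation_enrichment,
      n_driver_genes = as.integer(n_driver_genes),
      arm_base_rate = arm_base_rate,
      arm_enrichment = arm_enrichment,
      hormone_module_shift = hormone_module_shift,
      de_log2fc = de_log2fc,
      correlated_gene_rho = correlated_gene_rho,
      seed = seed
    ),
    class = "bccs_synthetic_config"
  )
}

#' @rdname synthetic_config
#' @export
default_tissue_specs <- function() {
  tibble(
    tissue      = c("HeadNeck", "KidneyChromophobe", "KidneyPapillary",
                    "Uterus", "Bladder", "Lung", "Cervix", "Ovary"),
    cancer_type = c("HNSC", "KICH", "KIRP", "UCEC", "BLCA", "LUAD", "CESC", "OV"),
    n_normal    = 30L,
    n_tumor     = 100L,
    baseline    = c(8, 4, 4.5, 3, 5, 5.5, 2, 1.5),
    uplift      = c(0.6, 0.8, 1.0, 1.2, 1.8, 2.2, 6.5, 7.0),
    group       = c("low", "low", "low", "low", NA, NA, "high", "high")
  )
}

#' @rdname synthetic_config
#' @export
default_arm_enrichment <- function() {
  tibble(
    arm       = c("16q", "8p", "3q", "1q"),
    direction = c("loss", "loss", "gain", "gain"),
    rate_low  = c(0.2, 0.2, 0.2, 0.2),
    rate_high = c(0.6, 0.6, 0.5, 0.5)
  )
}

# Deterministic sub-stream per component: a fixed small offset per component
# keeps every stream independent of how many draws earlier components made.
.component_seed <- function(seed, component) {
  offsets <- c(expression = 101L, latent = 211L, purity = 307L,
               mutations = 401L, arms = 503L, de = 601L)
  (seed + offsets[[component]]) %% .Machine$integer.max
}

#' Generate a synthetic paired normal/tumour cohort
#'
#' Draws every artefact the pipeline consumes — manifest, log-expression
#' matrix, purity table, binary driver-mutation matrix, arm-call matrix —
#' together with the ground-truth parameters used, for parameter-recovery
#' testing. Identical config (including seed) gives bitwise-identical output.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `bccs_cohort` with elements `manifest`,
#'   `expression`, `purity`, `mutations`, `arm_calls`, `gene_sets` (named
#'   list: `CCS`, `PROLIFERATION`, `HORMONE`, plus planted DE sets usable for
#'   enrichment testing) and `truth` (tissue baselines/uplifts, per-group
#'   mutation and arm rates, planted DE genes with true log2 fold changes).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "bccs_synthetic_config")) {
    .stop("config must come from synthetic_config()")
  }
  spec <- config$tissues
  n_per <- spec$n_normal + spec$n_tumor

  manifest <- tidyr::uncount(spec, weights = n_per, .id = "idx") |>
    group_by(.data$tissue) |>
    mutate(is_tumor = row_number() > .data$n_normal[1]) |>
    ungroup() |>
    mutate(
      study = ifelse(.data$is_tumor, "TCGA_TUMOR", "GTEX"),
      sample_id = sprintf(
        "%s_%s_%03d", ifelse(.data$is_tumor, "T", "N"), .data$tissue,
        as.integer(stats::ave(seq_along(.data$tissue),
                              paste(.data$tissue, .data$is_tumor), FUN = seq_along))
      ),
      cancer_type = ifelse(.data$is_tumor, .data$cancer_type, ""),
      exclusion_class = "NONE"
    ) |>
    select("sample_id", "study", "tissue", "cancer_type", "exclusion_class")
  validate_manifest(manifest)
  n_samples <- nrow(manifest)
  is_tumor <- manifest$study == "TCGA_TUMOR"
  tissue_of <- manifest$tissue

  group_of_tissue <- setNames(spec$group, spec$tissue)
  in_high <- is_tumor & group_of_tissue[tissue_of] %in% "high"
  in_low <- is_tumor & group_of_tissue[tissue_of] %in% "low"

  # gene panel
  sig_genes <- sprintf("CCS%03d", seq_len(config$n_signature_genes))
  met_genes <- sprintf("MET%03d", seq_len(config$n_metagene_genes))
  bg_genes <- sprintf("BG%04d", seq_len(config$n_background_genes))
  de_genes <- if (config$n_de_genes > 0) sprintf("DEG%03d", seq_len(config$n_de_genes)) else character()
  hormone_genes <- c("ESR1", "PGR", "AR", sprintf("HRM%03d", 1:10))
  tracker_gene <- "CCAT1X"  # planted activity-tracking gene
  all_genes <- c(sig_genes, met_genes, bg_genes, de_genes, hormone_genes, tracker_gene)

  # per-sample proliferation latent (shared by signature + metagene genes)
  set.seed(.component_seed(config$seed, "latent"))
  latent <- rnorm(n_samples, 0, config$latent_sd)

  # mean structure
  baseline_of <- setNames(spec$baseline, spec$tissue)
  uplift_of <- setNames(spec$uplift, spec$tissue)
  sig_mean <- baseline_of[tissue_of] + ifelse(is_tumor, uplift_of[tissue_of], 0) + latent
  mu <- matrix(0, nrow = length(all_genes), ncol = n_samples,
               dimnames = list(all_genes, manifest$sample_id))
  mu[sig_genes, ] <- matrix(sig_mean, nrow = length(sig_genes),
                            ncol = n_samples, byrow = TRUE)
  # metagene genes are co-regulated with the signature: they carry the same
  # per-sample proliferation signal (baseline + uplift + latent)
  mu[met_genes, ] <- matrix(sig_mean, nrow = length(met_genes),
                            ncol = n_samples, byrow = TRUE)
  if (length(de_genes) > 0) {
    mu[de_genes, in_high] <- config$de_log2fc
  }
  mu[hormone_genes, in_high] <- config$hormone_module_shift
  # tracker gene: standardised (uplift + latent) signal plus noise tuned so
  # cor(gene, signal) ~= correlated_gene_rho among tumours
  signal <- ifelse(is_tumor, uplift_of[tissue_of], 0) + latent
  z <- (signal - mean(signal[is_tumor])) / sd(signal[is_tumor])
  rho <- config$correlated_gene_rho
  tau <- sqrt(1 / rho^2 - 1)

  set.seed(.component_seed(config$seed, "expression"))
  expr <- mu + matrix(rnorm(length(mu), 0, config$noise_sd),
                      nrow = nrow(mu), dimnames = dimnames(mu))
  expr[tracker_gene, ] <- z + tau * rnorm(n_samples)

  # purity (tumours only)
  set.seed(.component_seed(config$seed, "purity"))
  purity <- tibble(
    sample_id = manifest$sample_id[is_tumor],
    purity = rbeta(sum(is_tumor), config$purity_beta[1], config$purity_beta[2])
  )

  # driver mutations (tumours only)
  driver_genes <- c(
    names(config$mutation_rates),
    sprintf("DRV%03d", seq_len(max(0, config$n_driver_genes - length(config$mutation_rates))))
  )
  base_rate <- setNames(rep(config$mutation_base_rate, length(driver_genes)), driver_genes)
  base_rate[names(config$mutation_rates)] <- config$mutation_rates
  rate_high <- base_rate
  for (g in names(config$mutation_enrichment)) {
    if (g %in% driver_genes) {
      odds <- config$mutation_enrichment[[g]] * base_rate[g] / (1 - base_rate[g])
      rate_high[g] <- odds / (1 + odds)
    }
  }
  set.seed(.component_seed(config$seed, "mutations"))
  n_tum <- sum(is_tumor)
  high_tum <- in_high[is_tumor]
  p_mat <- matrix(base_rate, nrow = length(driver_genes), ncol = n_tum,
                  dimnames = list(driver_genes, manifest$sample_id[is_tumor]))
  p_mat[, high_tum] <- rate_high
  mutations <- matrix(rbinom(length(p_mat), 1L, p_mat), nrow = nrow(p_mat),
                      dimnames = dimnames(p_mat))
  storage.mode(mutations) <- "integer"

  # arm calls (tumours only): per arm/direction rates, loss -> -1, gain -> +1
  arms <- autosomal_arms()
  loss_rate_low <- loss_rate_high <- setNames(rep(config$arm_base_rate, length(arms)), arms)
  gain_rate_low <- gain_rate_high <- loss_rate_low
  enr <- config$arm_enrichment
  if (!is.null(enr) && nrow(enr) > 0) {
    for (i in seq_len(nrow(enr))) {
      if (enr$direction[i] == "loss") {
        loss_rate_low[enr$arm[i]] <- enr$rate_low[i]
        loss_rate_high[enr$arm[i]] <- enr$rate_high[i]
      } else {
        gain_rate_low[enr$arm[i]] <- enr$rate_low[i]
        gain_rate_high[enr$arm[i]] <- enr$rate_high[i]
      }
    }
  }
  set.seed(.component_seed(config$seed, "arms"))
  loss_p <- matrix(loss_rate_low, nrow = length(arms), ncol = n_tum,
                   dimnames = list(arms, manifest$sample_id[is_tumor]))
  gain_p <- matrix(gain_rate_low, nrow = length(arms), ncol = n_tum,
                   dimnames = dimnames(loss_p))
  loss_p[, high_tum] <- loss_rate_high
  gain_p[, high_tum] <- gain_rate_high
  u <- matrix(runif(length(loss_p)), nrow = nrow(loss_p))
  arm_calls <- matrix(0L, nrow = length(arms), ncol = n_tum,
                      dimnames = dimnames(loss_p))
  arm_calls[u < loss_p] <- -1L
  arm_calls[u >= loss_p & u < loss_p + gain_p] <- 1L

  gene_sets <- list(
    CCS = sig_genes,
    PROLIFERATION = met_genes,
    HORMONE = hormone_genes,
    PLANTED_DE_UP = de_genes,
    NULL_SET_A = bg_genes[seq_len(min(25, length(bg_genes)))],
    NULL_SET_B = bg_genes[seq(min(26, length(bg_genes)), min(50, length(bg_genes)))]
  )
  gene_sets <- gene_sets[lengths(gene_sets) > 0]

  truth <- list(
    tissues = spec,
    groups = list(
      group1 = spec$cancer_type[spec$group %in% "low"],
      group2 = spec$cancer_type[spec$group %in% "high"]
    ),
    signature_genes = sig_genes,
    metagene_genes = met_genes,
    hormone_genes = hormone_genes,
    tracker_gene = tracker_gene,
    de_genes = tibble(gene_id = de_genes,
                      true_log2fc = rep(config$de_log2fc, length(de_genes))),
    mutation_rates = tibble(gene_id = driver_genes,
                            rate_group1 = unname(base_rate),
                            rate_group2 = unname(rate_high)),
    arm_rates = tibble(
      arm = rep(arms, 2),
      direction = rep(c("loss", "gain"), each = length(arms)),
      rate_group1 = c(unname(loss_rate_low), unname(gain_rate_low)),
      rate_group2 = c(unname(loss_rate_high), unname(gain_rate_high))
    ),
    config = config
  )

  structure(
    list(manifest = manifest, expression = expr, purity = purity,
         mutations = mutations, arm_calls = arm_calls,
         gene_sets = gene_sets, truth = truth),
    class = "bccs_cohort"
  )
}

#' Write all cohort artefacts to a directory
#'
#' @param cohort A `bccs_cohort` from [generate_cohort()].
#' @param dir Output directory (created if absent).
#' @param expression_format `"tsv"` or `"mtx"`.
#' @return `dir`, invisibly. Files written: `manifest.tsv`, `expression.tsv`
#'   (or `expression.mtx` + sidecars), `purity.tsv`, `mutations.tsv`,
#'   `arm_calls.tsv`, `gene_sets.gmt`, `truth.json`.
#' @export
write_cohort <- function(cohort, dir, expression_format = c("tsv", "mtx")) {
  expression_format <- match.arg(expression_format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_manifest(cohort$manifest, file.path(dir, "manifest.tsv"))
  ext <- if (expression_format == "tsv") "expression.tsv" else "expression.mtx"
  write_expression(cohort$expression, file.path(dir, ext), expression_format)
  write_purity(cohort$purity, file.path(dir, "purity.tsv"))
  write_mutations(cohort$mutations, file.path(dir, "mutations.tsv"))
  write_arm_calls(cohort$arm_calls, file.path(dir, "arm_calls.tsv"))
  write_gmt(cohort$gene_sets, file.path(dir, "gene_sets.gmt"))
  truth <- cohort$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
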