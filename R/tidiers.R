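# broom-style tidiers for fitted objects.

#' Tidy a moderated DE fit
#'
#' @param x A `bccs_de` object.
#' @param ... Ignored.
#' @return The per-gene results tibble (`gene_id`, `log2_fc`, `t_moderated`,
#'   `p`, `q`, `significant`).
#' @export
tidy.bccs_de <- function(x, ...) {
  x$results
}

#' One-row summary of a moderated DE fit
#'
#' @param x A `bccs_de` object.
#' @param ... Ignored.
#' @return A one-row tibble: gene and sample counts, residual and prior
#'   degrees of freedom, prior variance, and up/down significant counts.
#' @export
glance.bccs_de <- function(x, ...) {
  tibble(
    n_genes = nrow(x$results),
    n_g1 = x$n_g1,
    n_g2 = x$n_g2,
    df_residual = x$df_residual,
    prior_df = x$prior_df,
    prior_var = x$prior_var,
    n_up = sum(x$results$significant & x$results$log2_fc > 0),
    n_down = sum(x$results$significant & x$results$log2_fc < 0)
  )
}

#' Tidy a gene-set enrichment result
#'
#' @param x A `bccs_gsea` tibble.
#' @param ... Ignored.
#' @return A plain tibble with the leading edge flattened to a
#'   comma-separated string.
#' @export
tidy.bccs_gsea <- function(x, ...) {
  as_tibble(x) |>
    mutate(leading_edge = vapply(.data$leading_edge, paste, character(1),
                                 collapse = ","))
}

#' @export
tidy.bccs_scores <- function(x, ...) as_tibble(x)
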