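# broom-style tidiers for the classed result objects. Tabular results are
# already tibbles and need none.

#' @export
tidy.bulk_deconvolution <- function(x, ...) x$proportions

#' @export
glance.bulk_deconvolution <- function(x, ...) {
  tibble::tibble(
    n_samples = dplyr::n_distinct(x$proportions$sample_id),
    n_cell_types = dplyr::n_distinct(x$proportions$cell_type),
    mean_residual = mean(x$residuals$residual)
  )
}

#' @export
tidy.spot_deconvolution <- function(x, ...) x$proportions

#' @export
glance.spot_deconvolution <- function(x, ...) {
  tibble::tibble(
    K = x$K,
    n_spots = nrow(x$theta),
    n_genes = length(x$genes),
    perplexity = x$perplexity_by_k$perplexity[x$perplexity_by_k$K == x$K][1],
    elbo = tail(x$bound, 1)
  )
}

#' @export
tidy.meth_signature <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(gene_id = x$hypo_genes, list = "hypo",
      rank = seq_along(x$hypo_genes)
    ),
    tibble::tibble(gene_id = x$hyper_genes, list = "hyper",
      rank = seq_along(x$hyper_genes)
    )
  )
}

#' @export
tidy.cluster_specificity <- function(x, ...) {
  tibble::as_tibble(x$specificity, rownames = "cluster") |>
    tidyr::pivot_longer(-"cluster", names_to = "gene", values_to = "specificity")
}

#' @export
glance.run_report <- function(x, ...) {
  tibble::as_tibble(x$counts)
}
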