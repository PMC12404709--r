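# Lightweight containers for the two non-tabular inputs. Everything a
# downstream function returns is a tibble (or a small classed list of
# tibbles/matrices with tidy()/glance() methods).

#' Construct a bulk methylation dataset
#'
#' Bundles a beta matrix (probes x samples), probe genomic coordinates, and
#' sample metadata. Betas are clipped into `[eps, 1 - eps]` so the logit2
#' (M-value) transform is always finite.
#'
#' @param betas Numeric matrix of methylation proportions, probes in rows,
#'   samples in columns; dimnames required.
#' @param probe_map Tibble with columns `probe_id`, `chrom`, `pos` (0-based bp)
#'   covering every row of `betas`.
#' @param samples Tibble with columns `sample_id`, `group` (`"control"` or
#'   `"RT"`) and any numeric covariates, covering every column of `betas`.
#' @param eps Clipping bound for betas (default 1e-3).
#' @return An object of class `meth_dataset`.
#' @export
meth_dataset <- function(betas, probe_map, samples, eps = 1e-3) {
  stopifnot(is.matrix(betas), !is.null(rownames(betas)), !is.null(colnames(betas)))
  if (!all(rownames(betas) %in% probe_map$probe_id)) {
    abort("`probe_map` must cover every probe in `betas`.")
  }
  if (!all(colnames(betas) %in% samples$sample_id)) {
    abort("`samples` must cover every column of `betas`.")
  }
  if (any(!is.finite(betas)) || any(betas < 0) || any(betas > 1)) {
    abort("Betas must be finite proportions in [0, 1].")
  }
  betas <- pmin(pmax(betas, eps), 1 - eps)
  probe_map <- dplyr::arrange(
    dplyr::semi_join(probe_map, tibble::tibble(probe_id = rownames(betas)),
      by = "probe_id"
    ),
    .data$chrom, .data$pos
  )
  samples <- samples[match(colnames(betas), samples$sample_id), , drop = FALSE]
  structure(
    list(betas = betas, probe_map = probe_map, samples = samples, eps = eps),
    class = "meth_dataset"
  )
}

#' @export
print.meth_dataset <- function(x, ...) {
  cat(
    "<meth_dataset> ", nrow(x$betas), " probes x ", ncol(x$betas), " samples (",
    sum(x$samples$group == "RT"), " RT / ",
    sum(x$samples$group == "control"), " control)\n",
    sep = ""
  )
  invisible(x)
}

#' Construct a spatial transcriptomics dataset
#'
#' One capture area: a spot x gene count matrix on a hexagonal grid with
#' integer axial coordinates (`array_row`, `array_col`) and a condition label.
#'
#' @param counts Spot x gene matrix of non-negative integer counts (dense or
#'   sparse); rownames are spot barcodes, colnames gene ids.
#' @param positions Tibble with columns `barcode`, `array_row`, `array_col`;
#'   positions must be unique within the sample.
#' @param sample_id Sample identifier.
#' @param condition `"control"` or `"RT"`.
#' @param domain Optional per-spot tissue domain (`"cortex"`, `"white_matter"`,
#'   `"unknown"`).
#' @return An object of class `spatial_dataset`.
#' @export
spatial_dataset <- function(counts, positions, sample_id, condition,
                            domain = NULL) {
  stopifnot(!is.null(rownames(counts)), !is.null(colnames(counts)))
  if (!condition %in% c("control", "RT")) {
    abort("`condition` must be 'control' or 'RT'.")
  }
  if (!all(rownames(counts) %in% positions$barcode)) {
    abort("`positions` must cover every spot in `counts`.")
  }
  if (anyDuplicated(positions[, c("array_row", "array_col")])) {
    abort("Duplicate spot positions within a sample.")
  }
  if (any(counts < 0)) abort("Counts must be non-negative.")
  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "generalMatrix")
  counts <- methods::as(counts, "CsparseMatrix")
  positions <- positions[match(rownames(counts), positions$barcode), , drop = FALSE]
  if (is.null(domain)) domain <- rep("unknown", nrow(counts))
  structure(
    list(
      counts = counts, positions = positions, sample_id = sample_id,
      condition = condition, domain = domain
    ),
    class = "spatial_dataset"
  )
}

#' @export
print.spatial_dataset <- function(x, ...) {
  cat(
    "<spatial_dataset> ", x$sample_id, " (", x$condition, "): ",
    nrow(x$counts), " spots x ", ncol(x$counts), " genes\n",
    sep = ""
  )
  invisible(x)
}

# Combine a list of spatial datasets into one spot table keyed by
# (sample_id, barcode), with a shared gene space. Internal.
bind_spatial <- function(datasets) {
  if (inherits(datasets, "spatial_dataset")) datasets <- list(datasets)
  genes <- Reduce(intersect, lapply(datasets, function(d) colnames(d$counts)))
  if (length(genes) == 0) abort("Datasets share no genes.")
  counts <- do.call(rbind, lapply(datasets, function(d) d$counts[, genes, drop = FALSE]))
  meta <- purrr::map_dfr(datasets, function(d) {
    tibble::tibble(
      sample_id = d$sample_id, barcode = rownames(d$counts),
      condition = d$condition,
      array_row = d$positions$array_row, array_col = d$positions$array_col
    )
  })
  rownames(counts) <- paste(meta$sample_id, meta$barcode, sep = "_")
  list(counts = counts, meta = meta, genes = genes)
}
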