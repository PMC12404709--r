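# Readers and writers for the plain-text interchange formats: beta matrix
# TSV, probe map TSV, annotation BED6+2, MTX counts with genes/barcodes TSVs
# and a Visium-style tissue_positions CSV, and truth/report JSON.

#' Write / read a bulk methylation dataset as TSV
#'
#' Writes `betas.tsv` (probe rows, sample-id header), `probe_map.tsv`
#' (`probe_id`, `chrom`, `pos`) and `samples.tsv` (metadata incl. covariates).
#'
#' @param data A [meth_dataset()].
#' @param dir Output directory (created if needed).
#' @return `write_methylation()` the directory, invisibly;
#'   `read_methylation()` a [meth_dataset()].
#' @export
write_methylation <- function(data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(
    dplyr::bind_cols(
      tibble::tibble(probe_id = rownames(data$betas)),
      tibble::as_tibble(data$betas)
    ),
    file.path(dir, "betas.tsv")
  )
  readr::write_tsv(data$probe_map, file.path(dir, "probe_map.tsv"))
  readr::write_tsv(data$samples, file.path(dir, "samples.tsv"))
  invisible(dir)
}

#' @rdname write_methylation
#' @export
read_methylation <- function(dir) {
  b <- readr::read_tsv(file.path(dir, "betas.tsv"), show_col_types = FALSE)
  betas <- as.matrix(b[, -1])
  rownames(betas) <- b$probe_id
  meth_dataset(
    betas,
    readr::read_tsv(file.path(dir, "probe_map.tsv"), show_col_types = FALSE),
    readr::read_tsv(file.path(dir, "samples.tsv"), show_col_types = FALSE)
  )
}

#' Write / read a genome annotation as BED6+2
#'
#' Columns: chrom, start, end, name, score, strand, gene_id, feature_class
#' (0-based half-open).
#'
#' @param annotation Feature tibble.
#' @param path Output file.
#' @export
write_annotation <- function(annotation, path) {
  bed <- dplyr::transmute(
    annotation,
    chrom = .data$chrom, start = .data$start, end = .data$end,
    name = paste0("f", dplyr::row_number()), score = 0L, strand = .data$strand,
    gene_id = dplyr::coalesce(.data$gene_id, "."),
    feature_class = .data$feature_class
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  bed <- readr::read_tsv(
    path,
    col_names = c(
      "chrom", "start", "end", "name", "score", "strand", "gene_id",
      "feature_class"
    ),
    show_col_types = FALSE
  )
  dplyr::select(
    dplyr::mutate(bed, gene_id = dplyr::na_if(.data$gene_id, ".")),
    "chrom", "start", "end", "strand", "gene_id", "feature_class"
  )
}

#' Write / read a spatial dataset (MTX + TSV + positions CSV)
#'
#' Writes `matrix.mtx` (genes x spots, MatrixMarket), `genes.tsv`,
#' `barcodes.tsv`, and `tissue_positions.csv` with columns `barcode`,
#' `in_tissue`, `array_row`, `array_col` (Visium dialect), plus a small
#' `sample.json` with the sample id and condition.
#'
#' @param data A [spatial_dataset()].
#' @param dir Output directory.
#' @export
write_spatial <- function(data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(methods::as(Matrix::t(data$counts), "CsparseMatrix"),
    file.path(dir, "matrix.mtx")
  )
  readr::write_tsv(
    tibble::tibble(gene = colnames(data$counts)),
    file.path(dir, "genes.tsv"),
    col_names = FALSE
  )
  readr::write_tsv(
    tibble::tibble(barcode = rownames(data$counts)),
    file.path(dir, "barcodes.tsv"),
    col_names = FALSE
  )
  readr::write_csv(
    dplyr::transmute(
      data$positions,
      barcode = .data$barcode, in_tissue = 1L,
      array_row = .data$array_row, array_col = .data$array_col
    ),
    file.path(dir, "tissue_positions.csv")
  )
  jsonlite::write_json(
    list(sample_id = data$sample_id, condition = data$condition),
    file.path(dir, "sample.json"),
    auto_unbox = TRUE
  )
  invisible(dir)
}

#' @rdname write_spatial
#' @export
read_spatial <- function(dir) {
  m <- Matrix::t(Matrix::readMM(file.path(dir, "matrix.mtx")))
  genes <- readr::read_tsv(file.path(dir, "genes.tsv"),
    col_names = "gene", show_col_types = FALSE
  )$gene
  barcodes <- readr::read_tsv(file.path(dir, "barcodes.tsv"),
    col_names = "barcode", show_col_types = FALSE
  )$barcode
  dimnames(m) <- list(barcodes, genes)
  pos <- readr::read_csv(file.path(dir, "tissue_positions.csv"), show_col_types = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "sample.json"))
  spatial_dataset(m, pos, sample_id = meta$sample_id, condition = meta$condition)
}

#' Write a receptor-ligand pair table
#' @param pairs R-L tibble.
#' @param path Output TSV.
#' @export
write_rl_pairs <- function(pairs, path) {
  readr::write_tsv(pairs[, c("pair_id", "ligand", "receptor")], path)
  invisible(path)
}
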