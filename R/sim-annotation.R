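#' Simulate a toy genome annotation
#'
#' Lays `n_genes` genes along one toy chromosome and tiles it with the seven
#' feature classes used throughout the package: promoter, 5'UTR, exon, intron,
#' 3'UTR, transposable element (TE) and intergenic. Promoters are strand-aware
#' windows from 1500 bp upstream to 500 bp downstream of the transcription
#' start site; the downstream 500 bp are assigned to the promoter class so the
#' genic classes tile without overlap. TEs are carved out of introns and
#' intergenic gaps only, so no TE ever overlaps a promoter. After intergenic
#' fill the features form a partition of the chromosome: disjoint, 0-based
#' half-open, covering every base.
#'
#' @param n_genes Number of genes (>= 1).
#' @param n_te Number of transposable-element features (>= 0).
#' @param seed Integer seed; the output is deterministic given the seed.
#' @return A tibble with columns `chrom`, `start`, `end`, `strand`, `gene_id`
#'   (NA outside genes and promoters), `feature_class`.
#' @export
simulate_annotation <- function(n_genes, n_te = 0, seed = 1) {
  n_genes <- check_scalar_int(n_genes, "n_genes", min = 1L)
  n_te <- check_scalar_int(n_te, "n_te", min = 0L)
  with_seed(seed, {
    feats <- list()
    cursor <- 0L
    for (g in seq_len(n_genes)) {
      gene_id <- sprintf("gene%04d", g)
      strand <- sample(c("+", "-"), 1L)
      # leave room for an upstream promoter plus an intergenic gap
      gap <- sample(2000:10000, 1L)
      cursor <- cursor + gap
      n_exons <- sample(1:5, 1L)
      utr5_len <- sample(100:300, 1L)
      utr3_len <- sample(200:800, 1L)
      exon_lens <- sample(200:1000, n_exons, replace = TRUE)
      intron_lens <- if (n_exons > 1) sample(500:3000, n_exons - 1L, replace = TRUE) else integer(0)
      # genic blocks in transcription order: promoter head, utr5, exons/introns, utr3
      blocks <- c(
        list(c("promoter", 500L), c("utr5", utr5_len)),
        purrr::flatten(purrr::map(seq_len(n_exons), function(i) {
          out <- list(c("exon", exon_lens[i]))
          if (i < n_exons) out <- c(out, list(c("intron", intron_lens[i])))
          out
        })),
        list(c("utr3", utr3_len))
      )
      if (strand == "-") blocks <- rev(blocks)
      # upstream promoter arm sits before the gene on + strand, after on -
      if (strand == "+") {
        feats[[length(feats) + 1L]] <- tibble::tibble(
          start = cursor, end = cursor + 1500L, strand = strand,
          gene_id = gene_id, feature_class = "promoter"
        )
        cursor <- cursor + 1500L
      }
      for (b in blocks) {
        len <- as.integer(b[2])
        feats[[length(feats) + 1L]] <- tibble::tibble(
          start = cursor, end = cursor + len, strand = strand,
          gene_id = gene_id, feature_class = b[1]
        )
        cursor <- cursor + len
      }
      if (strand == "-") {
        feats[[length(feats) + 1L]] <- tibble::tibble(
          start = cursor, end = cursor + 1500L, strand = strand,
          gene_id = gene_id, feature_class = "promoter"
        )
        cursor <- cursor + 1500L
      }
    }
    chrom_len <- cursor + sample(2000:10000, 1L)
    ann <- dplyr::bind_rows(feats)
    # intergenic fill between consecutive features and at both ends
    gaps <- tibble::tibble(
      start = c(0L, ann$end), end = c(ann$start, chrom_len)
    )
    gaps <- gaps[gaps$end > gaps$start, , drop = FALSE]
    ann <- dplyr::bind_rows(
      ann,
      tibble::tibble(
        start = gaps$start, end = gaps$end, strand = "+",
        gene_id = NA_character_, feature_class = "intergenic"
      )
    )
    ann <- dplyr::arrange(ann, .data$start)
    # carve TEs out of introns and intergenic segments
    for (t in seq_len(n_te)) {
      te_len <- sample(300:3000, 1L)
      host_idx <- which(
        ann$feature_class %in% c("intron", "intergenic") &
          (ann$end - ann$start) >= te_len + 2L
      )
      if (length(host_idx) == 0) break
      i <- host_idx[sample.int(length(host_idx), 1L)]
      host <- ann[i, ]
      off <- sample.int(host$end - host$start - te_len, 1L)
      te_start <- host$start + off
      pieces <- dplyr::bind_rows(
        dplyr::mutate(host, end = te_start),
        dplyr::mutate(host,
          start = te_start, end = te_start + te_len,
          feature_class = "TE", gene_id = NA_character_
        ),
        dplyr::mutate(host, start = te_start + te_len)
      )
      pieces <- pieces[pieces$end > pieces$start, , drop = FALSE]
      ann <- dplyr::bind_rows(ann[-i, ], pieces)
      ann <- dplyr::arrange(ann, .data$start)
    }
    dplyr::mutate(ann, chrom = "chr1", .before = 1)
  })
}

#' Gene body and TSS table from an annotation
#'
#' Summarises a feature annotation into one row per gene with the gene span
#' (including the promoter arms) and the strand-aware transcription start site.
#'
#' @param annotation Tibble as returned by [simulate_annotation()].
#' @return Tibble with columns `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `tss`.
#' @export
gene_table <- function(annotation) {
  genic <- dplyr::filter(annotation, !is.na(.data$gene_id))
  dplyr::summarise(
    dplyr::group_by(genic, .data$gene_id),
    chrom = .data$chrom[1],
    start = min(.data$start),
    end = max(.data$end),
    strand = .data$strand[1],
    tss = dplyr::if_else(.data$strand[1] == "+", min(.data$start) + 1500L, max(.data$end) - 1500L),
    .groups = "drop"
  )
}
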