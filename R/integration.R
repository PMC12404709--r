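#' Call differentially expressed genes
#'
#' Counts are normalised to log2(CPM + 1); per gene, ordinary least squares on
#' the group indicator plus covariates with a two-sided t-test on the group
#' coefficient and BH adjustment. Genes with zero counts in every sample are
#' dropped (with a message).
#'
#' @param counts Gene x sample matrix of non-negative integer counts.
#' @param samples Tibble with `sample_id`, `group`, and covariate columns.
#' @param covariates Character vector of covariate names.
#' @return Tibble sorted by p: `gene_id`, `log_fc` (group effect on the
#'   log2-CPM scale), `statistic`, `p`, `q`.
#' @export
call_degs <- function(counts, samples, covariates = NULL) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)))
  counts <- counts[, samples$sample_id, drop = FALSE]
  if (min(table(samples$group)) < 2) abort("Need >= 2 samples per group.")
  lib <- colSums(counts)
  if (any(lib <= 0)) abort("Library sizes must be positive.")
  keep <- rowSums(counts) > 0
  if (any(!keep)) {
    inform(sprintf("Dropping %d genes with all-zero counts.", sum(!keep)))
    counts <- counts[keep, , drop = FALSE]
  }
  logcpm <- log2(t(t(counts) / lib) * 1e6 + 1)
  design <- group_design(samples, covariates)
  fit <- fit_rowwise_lm(logcpm, design, coef = "group")
  out <- tibble::tibble(
    gene_id = rownames(counts),
    log_fc = fit$estimate,
    statistic = fit$statistic,
    p = fit$p,
    q = p.adjust(fit$p, method = "BH")
  )
  dplyr::arrange(out, .data$p, .data$gene_id)
}

#' Overlap differentially methylated and differentially expressed genes
#'
#' @param dmgs DMG tibble from [map_dmgs()].
#' @param degs DEG tibble from [call_degs()].
#' @param q_thresh DEG significance threshold.
#' @return Sorted character vector of genes in both sets.
#' @export
overlap_dmg_deg <- function(dmgs, degs, q_thresh = 0.05) {
  sig <- degs$gene_id[degs$q < q_thresh]
  sort(intersect(unique(dmgs$gene_id), sig))
}

# The region-dependent concordance rule: expression change anti-correlated
# with methylation at promoter/5'UTR/exon, correlated at 3'UTR/intron/
# intergenic. TE-class entries are excluded from evaluation.
concordance_rule <- function(region_class, methyl_direction, expr_direction) {
  anti <- region_class %in% c("promoter", "utr5", "exon")
  corr <- region_class %in% c("utr3", "intron", "intergenic")
  msign <- ifelse(methyl_direction == "hyper", 1L, -1L)
  esign <- ifelse(expr_direction == "up", 1L, -1L)
  (anti & msign != esign) | (corr & msign == esign)
}

#' Region-aware methylation-expression concordance
#'
#' Evaluates the concordance rule over genes in the DMG-DEG overlap: a record
#' is concordant iff the region class is promoter/5'UTR/exon and the
#' expression change opposes the methylation change (hypo with up, hyper with
#' down), or the region class is 3'UTR/intron/intergenic and the two agree.
#' TE-class entries are excluded and counted separately. One record is emitted
#' per (gene, region class); a gene with several DMRs in one class
#' contributes the entry with the largest |mean delta beta|.
#'
#' @param dmgs DMG tibble from [map_dmgs()].
#' @param degs DEG tibble from [call_degs()].
#' @param q_thresh DEG significance threshold.
#' @return Tibble: `gene_id`, `region_class`, `methyl_direction`,
#'   `expr_direction`, `log_fc`, `concordant`; attribute `n_te_excluded`
#'   records the TE entries set aside. Use [concordant_genes()] for the
#'   gene-level call (any concordant record).
#' @export
classify_concordance <- function(dmgs, degs, q_thresh = 0.05) {
  if (!all(dmgs$region_class %in% names(default_coupling))) {
    abort("Unknown region class in `dmgs`.")
  }
  genes <- overlap_dmg_deg(dmgs, degs, q_thresh)
  d <- dplyr::filter(dmgs, .data$gene_id %in% genes)
  n_te <- sum(d$region_class == "TE")
  d <- dplyr::filter(d, .data$region_class != "TE")
  d <- dplyr::slice_max(
    dplyr::group_by(d, .data$gene_id, .data$region_class),
    abs(.data$mean_delta_beta),
    n = 1, with_ties = FALSE
  )
  d <- dplyr::ungroup(d)
  d <- dplyr::inner_join(
    d, dplyr::select(degs, "gene_id", "log_fc"),
    by = "gene_id"
  )
  out <- dplyr::transmute(
    d,
    gene_id = .data$gene_id,
    region_class = .data$region_class,
    methyl_direction = .data$direction,
    expr_direction = ifelse(.data$log_fc > 0, "up", "down"),
    log_fc = .data$log_fc,
    concordant = concordance_rule(
      .data$region_class, .data$direction, ifelse(.data$log_fc > 0, "up", "down")
    )
  )
  out <- dplyr::arrange(out, .data$gene_id, .data$region_class)
  attr(out, "n_te_excluded") <- n_te
  out
}

#' Gene-level concordance call
#'
#' A gene is concordant if any of its (gene, region class) records is.
#'
#' @param records Tibble from [classify_concordance()].
#' @return Sorted character vector of concordant genes.
#' @export
concordant_genes <- function(records) {
  sort(unique(records$gene_id[records$concordant]))
}

#' Build hypo-/hypermethylation gene signatures
#'
#' Restricts DMG entries to promoter/5'UTR/exon region classes, collapses each
#' gene to its largest-|delta beta| entry, and returns the `k` genes with the
#' most negative mean delta beta (hypo list) and the `k` with the most
#' positive (hyper list). Ties break by gene id; a gene appears in at most one
#' list.
#'
#' @param dmgs DMG tibble from [map_dmgs()].
#' @param k Target list length (default 200).
#' @return A list of class `meth_signature`: `hypo_genes`, `hyper_genes`
#'   (ordered character vectors), `stats` (tibble with the ranking statistic).
#' @export
build_methylation_signature <- function(dmgs, k = 200) {
  elig <- dplyr::filter(dmgs, .data$region_class %in% c("promoter", "utr5", "exon"))
  per_gene <- dplyr::ungroup(dplyr::slice_max(
    dplyr::group_by(elig, .data$gene_id),
    abs(.data$mean_delta_beta),
    n = 1, with_ties = FALSE
  ))
  hypo <- dplyr::filter(per_gene, .data$mean_delta_beta < 0)
  hyper <- dplyr::filter(per_gene, .data$mean_delta_beta > 0)
  hypo <- dplyr::arrange(hypo, .data$mean_delta_beta, .data$gene_id)
  hyper <- dplyr::arrange(hyper, dplyr::desc(.data$mean_delta_beta), .data$gene_id)
  if (nrow(hypo) < k || nrow(hyper) < k) {
    warn(sprintf(
      "Fewer than %d eligible genes (%d hypo, %d hyper); returning shorter lists.",
      k, nrow(hypo), nrow(hyper)
    ))
  }
  structure(
    list(
      hypo_genes = head(hypo$gene_id, k),
      hyper_genes = head(hyper$gene_id, k),
      stats = dplyr::select(
        per_gene, "gene_id", "region_class", "direction", "mean_delta_beta"
      )
    ),
    class = "meth_signature"
  )
}
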