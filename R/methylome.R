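#' Beta to M-value transform
#'
#' `beta_to_m()` is the logit2 transform `log2(beta / (1 - beta))`;
#' `m_to_beta()` is its inverse. Modelling is done on the M scale, where
#' variance is approximately homoscedastic.
#'
#' @param beta Numeric vector/matrix of proportions in \[0, 1\]; values are
#'   clipped to `[eps, 1 - eps]` before the transform.
#' @param m Numeric vector/matrix of M-values.
#' @param eps Clipping bound.
#' @return Numeric of the same shape.
#' @export
beta_to_m <- function(beta, eps = 1e-3) {
  if (any(!is.finite(beta)) || any(beta < 0) || any(beta > 1)) {
    abort("`beta` must be finite proportions in [0, 1].")
  }
  beta <- pmin(pmax(beta, eps), 1 - eps)
  log2(beta / (1 - beta))
}

#' @rdname beta_to_m
#' @export
m_to_beta <- function(m) {
  x <- 2^m
  x / (1 + x)
}

#' Call differentially methylated probes
#'
#' Per probe, ordinary least squares of the M-value on a group indicator
#' (RT = 1, control = 0) plus any covariates, with a two-sided t-test on the
#' group coefficient and Benjamini-Hochberg adjustment across all probes.
#'
#' @param data A [meth_dataset()].
#' @param covariates Character vector of covariate column names in
#'   `data$samples` to adjust for.
#' @return Tibble sorted by p, one row per probe: `probe_id`, `chrom`, `pos`,
#'   `effect_m` (group coefficient, M scale), `delta_beta` (mean RT minus
#'   control beta), `statistic`, `p`, `q`.
#' @export
call_dmps <- function(data, covariates = NULL) {
  stopifnot(inherits(data, "meth_dataset"))
  if (min(table(data$samples$group)) < 2) abort("Need >= 2 samples per group.")
  design <- group_design(data$samples, covariates)
  m <- beta_to_m(data$betas, eps = data$eps)
  fit <- fit_rowwise_lm(m, design, coef = "group")
  is_rt <- data$samples$group == "RT"
  delta_beta <- rowMeans(data$betas[, is_rt, drop = FALSE]) -
    rowMeans(data$betas[, !is_rt, drop = FALSE])
  out <- tibble::tibble(
    probe_id = rownames(data$betas),
    effect_m = fit$estimate,
    delta_beta = delta_beta,
    statistic = fit$statistic,
    p = fit$p,
    q = p.adjust(fit$p, method = "BH")
  )
  out <- dplyr::left_join(out, data$probe_map, by = "probe_id")
  dplyr::arrange(
    dplyr::relocate(out, "chrom", "pos", .after = "probe_id"),
    .data$p, .data$probe_id
  )
}

#' Merge significant probes into differentially methylated regions
#'
#' Significant probes (q below `q_thresh`) are sorted by position; maximal
#' runs of same-chromosome, same-sign probes with inter-probe gaps at most
#' `maxgap_bp` and at least `min_probes` members become DMRs. The DMR
#' direction is the sign of the mean effect (hypo = lower in RT) and the
#' interval spans the first to last probe plus one base. The result is
#' invariant to the input row order.
#'
#' @param dmps DMP tibble from [call_dmps()].
#' @param q_thresh Significance threshold on the BH-adjusted p.
#' @param maxgap_bp Maximum gap (bp) between consecutive probes in a region.
#' @param min_probes Minimum probes per region.
#' @return Tibble: `dmr_id`, `chrom`, `start`, `end`, `n_probes`, `direction`
#'   (`"hypo"`/`"hyper"`), `mean_delta_beta`, `length_bp`, `probe_ids`
#'   (list-column). Empty input yields an empty tibble.
#' @export
call_dmrs <- function(dmps, q_thresh = 0.05, maxgap_bp = 1000, min_probes = 3) {
  sig <- dplyr::arrange(
    dplyr::filter(dmps, .data$q < q_thresh, .data$effect_m != 0),
    .data$chrom, .data$pos
  )
  empty <- tibble::tibble(
    dmr_id = character(), chrom = character(), start = integer(),
    end = integer(), n_probes = integer(), direction = character(),
    mean_delta_beta = numeric(), length_bp = integer(), probe_ids = list()
  )
  if (nrow(sig) == 0) return(empty)
  new_run <- c(
    TRUE,
    sig$chrom[-1] != sig$chrom[-nrow(sig)] |
      diff(sig$pos) > maxgap_bp |
      sign(sig$effect_m[-1]) != sign(sig$effect_m[-nrow(sig)])
  )
  sig$run <- cumsum(new_run)
  out <- dplyr::summarise(
    dplyr::group_by(sig, .data$run),
    chrom = .data$chrom[1],
    start = min(.data$pos),
    end = max(.data$pos) + 1L,
    n_probes = dplyr::n(),
    direction = dplyr::if_else(mean(.data$effect_m) < 0, "hypo", "hyper"),
    mean_delta_beta = mean(.data$delta_beta),
    probe_ids = list(.data$probe_id),
    .groups = "drop"
  )
  out <- dplyr::filter(out, .data$n_probes >= min_probes)
  if (nrow(out) == 0) return(empty)
  out <- dplyr::arrange(out, .data$chrom, .data$start)
  dplyr::relocate(
    dplyr::mutate(out,
      dmr_id = sprintf("dmr%05d", dplyr::row_number()),
      length_bp = .data$end - .data$start,
      run = NULL
    ),
    "dmr_id", "chrom", "start", "end", "n_probes", "direction",
    "mean_delta_beta", "length_bp", "probe_ids"
  )
}

# Feature-class precedence used wherever an interval gets exactly one class.
region_precedence <- c(
  "promoter", "utr5", "utr3", "exon", "intron", "TE", "intergenic"
)

# Assign one region class (midpoint overlap, precedence order) and the list of
# overlapping genes to each interval. Internal; shared by DMR annotation and
# the planted-truth annotator.
classify_intervals <- function(intervals, annotation) {
  intervals <- dplyr::mutate(
    intervals,
    mid = (.data$start + .data$end) %/% 2L
  )
  ann <- dplyr::mutate(annotation,
    fstart = .data$start, fend = .data$end,
    start = NULL, end = NULL
  )
  hit <- dplyr::inner_join(
    intervals, ann,
    by = dplyr::join_by(chrom, mid >= fstart, mid < fend)
  )
  cls <- dplyr::summarise(
    dplyr::group_by(hit, .data$dmr_id),
    region_class = {
      i <- match(.data$feature_class, region_precedence)
      region_precedence[if (length(i) > 0) min(i) else NA_integer_]
    },
    .groups = "drop"
  )
  ov <- dplyr::inner_join(
    intervals, dplyr::filter(ann, !is.na(.data$gene_id)),
    by = dplyr::join_by(chrom, start < fend, end > fstart)
  )
  genes <- dplyr::summarise(
    dplyr::group_by(ov, .data$dmr_id),
    gene_ids = list(sort(unique(.data$gene_id))),
    .groups = "drop"
  )
  out <- dplyr::left_join(intervals, cls, by = "dmr_id")
  out <- dplyr::left_join(out, genes, by = "dmr_id")
  if (any(is.na(out$region_class))) {
    warn("Intervals on unannotated chromosomes classified as intergenic.")
    out$region_class[is.na(out$region_class)] <- "intergenic"
  }
  out$gene_ids <- purrr::map(out$gene_ids, function(g) g %||% character(0))
  dplyr::select(out, -"mid")
}

# Nearest gene by TSS distance within max_dist, else NA. Internal.
nearest_gene <- function(start, end, genes, max_dist = 10000L) {
  mid <- (start + end) %/% 2L
  d <- abs(genes$tss - mid)
  i <- which.min(d)
  if (length(i) == 0 || d[i] > max_dist) NA_character_ else genes$gene_id[i]
}

#' Annotate DMRs with genomic feature classes and genes
#'
#' Each DMR gets exactly one region class by midpoint overlap with precedence
#' promoter > 5'UTR > 3'UTR > exon > intron > TE > intergenic, plus the list
#' of genes whose features overlap the DMR interval at all.
#'
#' @param dmrs Tibble from [call_dmrs()].
#' @param annotation Feature tibble from [simulate_annotation()] (or any table
#'   with the same columns).
#' @return The input with `region_class` and `gene_ids` (list-column) added.
#' @export
annotate_dmrs <- function(dmrs, annotation) {
  if (nrow(dmrs) == 0) {
    return(dplyr::mutate(dmrs, region_class = character(0), gene_ids = list()))
  }
  classify_intervals(dmrs, annotation)
}

#' DMR genomic location table with array background
#'
#' Percentage of DMRs per region class, overall and split by direction,
#' alongside the array background: every probe on the array classified by the
#' same midpoint-precedence rule.
#'
#' @param annotated Annotated DMR tibble from [annotate_dmrs()].
#' @param probe_map Probe coordinate tibble (`probe_id`, `chrom`, `pos`).
#' @param annotation Feature tibble.
#' @return Tibble: `feature_class`, `set` (`background`, `all`, `hypo`,
#'   `hyper`), `n`, `pct`.
#' @export
dmr_location_table <- function(annotated, probe_map, annotation) {
  bg <- classify_intervals(
    tibble::tibble(
      dmr_id = probe_map$probe_id, chrom = probe_map$chrom,
      start = probe_map$pos, end = probe_map$pos + 1L
    ),
    annotation
  )
  count_set <- function(cls, set) {
    tb <- table(factor(cls, levels = region_precedence))
    tibble::tibble(
      feature_class = names(tb), set = set, n = as.integer(tb),
      pct = 100 * as.integer(tb) / max(1L, length(cls))
    )
  }
  dplyr::bind_rows(
    count_set(bg$region_class, "background"),
    count_set(annotated$region_class, "all"),
    count_set(annotated$region_class[annotated$direction == "hypo"], "hypo"),
    count_set(annotated$region_class[annotated$direction == "hyper"], "hyper")
  )
}

#' Region-class enrichment of DMRs against the array background
#'
#' For each region class and each DMR set (all, hypo, hyper), a two-sided
#' Fisher exact test of (DMRs in class vs not) against (background probes in
#' class vs not), with the odds ratio (conditional MLE), BH adjustment across
#' the tested set, and an enriched/depleted label at q < 0.05.
#'
#' @param location_table Tibble from [dmr_location_table()].
#' @return Tibble: `feature_class`, `set`, `n_dmr`, `n_bg`, `odds_ratio`,
#'   `p`, `q`, `label` (`enriched`/`depleted`/`ns`), `degenerate` flag set
#'   when a table margin is zero.
#' @export
region_enrichment <- function(location_table) {
  bg <- dplyr::filter(location_table, .data$set == "background")
  if (any(bg$n <= 0)) abort("Background counts must be positive for every class.")
  fg <- dplyr::filter(location_table, .data$set != "background")
  bg_tot <- sum(bg$n)
  out <- dplyr::group_modify(
    dplyr::group_by(fg, .data$set, .data$feature_class),
    function(df, key) {
      n_bg <- bg$n[bg$feature_class == key$feature_class]
      fg_tot <- sum(fg$n[fg$set == key$set])
      tab <- matrix(
        c(df$n, fg_tot - df$n, n_bg, bg_tot - n_bg), 2, 2
      )
      ft <- fisher.test(tab)
      tibble::tibble(
        n_dmr = df$n, n_bg = n_bg,
        odds_ratio = unname(ft$estimate), p = ft$p.value,
        degenerate = any(rowSums(tab) == 0) || any(colSums(tab) == 0)
      )
    }
  )
  out <- dplyr::ungroup(out)
  out$q <- p.adjust(out$p, method = "BH")
  out$label <- dplyr::case_when(
    out$q < 0.05 & out$odds_ratio > 1 ~ "enriched",
    out$q < 0.05 & out$odds_ratio < 1 ~ "depleted",
    TRUE ~ "ns"
  )
  dplyr::arrange(out, .data$set, .data$feature_class)
}

#' Map DMRs to differentially methylated genes
#'
#' Genic DMRs map to every overlapping gene; intergenic-class DMRs with no
#' overlapping gene map to the nearest TSS within `max_dist` bp, else to no
#' gene. A gene may carry several entries (one per DMR), each with its region
#' class, direction and mean delta beta.
#'
#' @param annotated Annotated DMR tibble from [annotate_dmrs()].
#' @param annotation Feature tibble (used for TSS positions).
#' @param max_dist Nearest-gene cutoff in bp for intergenic DMRs.
#' @return Tibble: `gene_id`, `dmr_id`, `region_class`, `direction`,
#'   `mean_delta_beta`, sorted by gene.
#' @export
map_dmgs <- function(annotated, annotation, max_dist = 10000L) {
  gt <- gene_table(annotation)
  rows <- purrr::pmap_dfr(
    dplyr::select(
      annotated, "dmr_id", "start", "end", "region_class", "direction",
      "mean_delta_beta", "gene_ids"
    ),
    function(dmr_id, start, end, region_class, direction, mean_delta_beta, gene_ids) {
      genes <- gene_ids
      if (length(genes) == 0) {
        ng <- nearest_gene(start, end, gt, max_dist = max_dist)
        genes <- if (is.na(ng)) character(0) else ng
      }
      if (length(genes) == 0) return(NULL)
      tibble::tibble(
        gene_id = genes, dmr_id = dmr_id, region_class = region_class,
        direction = direction, mean_delta_beta = mean_delta_beta
      )
    }
  )
  dplyr::arrange(rows, .data$gene_id, .data$dmr_id)
}

#' Input for the most-variable-probe heatmap
#'
#' Selects the top `k` probes by variance, z-scores each across samples, and
#' orders rows and columns by average-linkage hierarchical clustering on
#' Euclidean distance. Variance ties break by probe id.
#'
#' @param data A [meth_dataset()].
#' @param k Number of probes to keep.
#' @return A list of class `probe_heatmap`: `z` (probe x sample z-scores),
#'   `row_order`, `col_order` (leaf orders), `row_hclust`, `col_hclust`.
#' @export
variable_probe_matrix <- function(data, k) {
  stopifnot(inherits(data, "meth_dataset"))
  k <- check_scalar_int(k, "k")
  if (k > nrow(data$betas)) abort("`k` exceeds the number of probes.")
  v <- apply(data$betas, 1, var)
  ord <- order(-v, rownames(data$betas))
  top <- data$betas[ord[seq_len(k)], , drop = FALSE]
  z <- (top - rowMeans(top)) / pmax(apply(top, 1, sd), 1e-12)
  rh <- hclust(dist(z), method = "average")
  ch <- hclust(dist(t(z)), method = "average")
  structure(
    list(
      z = z, row_order = rh$order, col_order = ch$order,
      row_hclust = rh, col_hclust = ch
    ),
    class = "probe_heatmap"
  )
}
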