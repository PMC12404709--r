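#' Quality-filter spatial spots
#'
#' Removes spots with fewer than `min_counts` total counts or fewer than
#' `min_genes` detected genes.
#'
#' @param datasets A [spatial_dataset()] or list thereof.
#' @param min_counts,min_genes Thresholds (0 keeps everything).
#' @return A list: `datasets` (filtered, same order) and `report` (tibble with
#'   spots kept/removed per sample).
#' @export
qc_filter_spots <- function(datasets, min_counts = 0, min_genes = 0) {
  single <- inherits(datasets, "spatial_dataset")
  if (single) datasets <- list(datasets)
  report <- list()
  out <- purrr::map(datasets, function(d) {
    tot <- Matrix::rowSums(d$counts)
    det <- Matrix::rowSums(d$counts > 0)
    keep <- tot >= min_counts & det >= min_genes
    report[[length(report) + 1L]] <<- tibble::tibble(
      sample_id = d$sample_id, n_spots = length(keep),
      n_kept = sum(keep), n_removed = sum(!keep)
    )
    if (!any(keep)) abort(sprintf("All spots removed in sample %s.", d$sample_id))
    d$counts <- d$counts[keep, , drop = FALSE]
    d$positions <- d$positions[keep, , drop = FALSE]
    d$domain <- d$domain[keep]
    d
  })
  list(datasets = if (single) out[[1]] else out, report = dplyr::bind_rows(report))
}

#' Cluster spots into micro-environmental niches
#'
#' Joint unsupervised clustering across samples: per-spot depth normalisation
#' to the median total, log1p, top highly-variable genes, linear (PCA)
#' dimensionality reduction, a k-nearest-neighbour graph, and Louvain
#' community detection at the given resolution under a fixed seed.
#'
#' @param datasets A [spatial_dataset()] or list thereof (shared gene space).
#' @param n_hvg Number of highly variable genes (capped at the gene count).
#' @param n_pcs Number of principal components.
#' @param k Neighbours in the kNN graph.
#' @param resolution Louvain resolution.
#' @param seed Integer seed.
#' @return A tibble of class `spot_clustering`: `sample_id`, `barcode`,
#'   `condition`, `cluster` (contiguous integers from 1).
#' @export
cluster_spots <- function(datasets, n_hvg = 2000, n_pcs = 30, k = 15,
                          resolution = 1, seed = 0) {
  b <- bind_spatial(datasets)
  if (nrow(b$counts) <= k) abort("Fewer spots than `k` neighbours.")
  x <- log_normalise(b$counts)
  v <- apply(as.matrix(x), 2, var)
  hvg <- order(-v, colnames(x))[seq_len(min(n_hvg, ncol(x)))]
  xm <- as.matrix(x[, hvg, drop = FALSE])
  n_pcs <- min(n_pcs, ncol(xm) - 1L, nrow(xm) - 1L)
  if (all(v[hvg] == 0)) {
    cl <- rep(1L, nrow(xm))
  } else {
    pc <- with_seed(seed, prcomp(xm, rank. = n_pcs, center = TRUE, scale. = FALSE)$x)
    d <- as.matrix(dist(pc))
    nn <- t(apply(d, 1, function(r) order(r)[2:(k + 1)]))
    edges <- cbind(rep(seq_len(nrow(nn)), each = k), as.vector(t(nn)))
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::simplify(g)
    cl <- with_seed(
      seed,
      as.integer(igraph::membership(
        igraph::cluster_louvain(g, resolution = resolution)
      ))
    )
  }
  cl <- as.integer(factor(cl, levels = sort(unique(cl))))
  structure(
    dplyr::mutate(b$meta[, c("sample_id", "barcode", "condition")], cluster = cl),
    class = c("spot_clustering", "tbl_df", "tbl", "data.frame")
  )
}

#' One-vs-rest marker genes per cluster
#'
#' Wilcoxon rank-sum (asymptotic, tie-corrected) of each gene in each cluster
#' against all other spots, on log-normalised expression, with BH adjustment
#' within cluster. `log_fc` is the log2 ratio of mean normalised expression
#' (pseudocount 1).
#'
#' @param datasets A [spatial_dataset()] or list thereof.
#' @param labels A `spot_clustering` tibble (or any tibble with `sample_id`,
#'   `barcode`, `cluster`).
#' @param q_max,lfc_min Reporting thresholds.
#' @return Tibble: `cluster`, `gene`, `log_fc`, `statistic`, `p`, `q`, sorted
#'   by cluster then q then decreasing log_fc. Singleton clusters are flagged
#'   with a warning.
#' @export
find_markers <- function(datasets, labels, q_max = 0.05, lfc_min = 0.25) {
  b <- bind_spatial(datasets)
  lab <- dplyr::left_join(
    b$meta[, c("sample_id", "barcode")], labels,
    by = c("sample_id", "barcode")
  )$cluster
  if (anyNA(lab)) abort("`labels` must cover every spot.")
  clusters <- sort(unique(lab))
  if (length(clusters) < 2) abort("Need >= 2 clusters.")
  x <- as.matrix(log_normalise(b$counts))
  n <- nrow(x)
  ranks <- apply(x, 2, rank)
  # per-gene tie correction for the rank-sum variance
  tie_term <- apply(ranks, 2, function(r) {
    t <- table(r)
    sum(t^3 - t)
  })
  ex <- expm1(x)
  out <- purrr::map_dfr(clusters, function(cc) {
    idx <- lab == cc
    n1 <- sum(idx)
    n2 <- n - n1
    if (n1 < 2) warn(sprintf("Cluster %s is (near-)singleton; markers are low-powered.", cc))
    r1 <- colSums(ranks[idx, , drop = FALSE])
    u <- r1 - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    z <- (u - mu) / sqrt(pmax(sigma2, 1e-12))
    z[sigma2 <= 0] <- 0
    p <- 2 * stats::pnorm(-abs(z))
    lfc <- log2((colMeans(ex[idx, , drop = FALSE]) + 1) /
      (colMeans(ex[!idx, , drop = FALSE]) + 1))
    tibble::tibble(
      cluster = cc, gene = colnames(x), log_fc = lfc,
      statistic = u, p = p, q = p.adjust(p, method = "BH")
    )
  })
  out <- dplyr::filter(out, .data$q < q_max, .data$log_fc > lfc_min)
  dplyr::arrange(out, .data$cluster, .data$q, dplyr::desc(.data$log_fc))
}

#' Cluster gene-specificity scores and cluster-cluster correlation
#'
#' Specificity of gene g in cluster c is the mean log-normalised expression of
#' g in c divided by its mean across all spots (0/0 defined as 0). Pearson
#' correlation between cluster specificity rows is computed over the union of
#' marker genes, with average-linkage ordering.
#'
#' @param markers Marker tibble from [find_markers()].
#' @param datasets A [spatial_dataset()] or list thereof.
#' @param labels A `spot_clustering` tibble.
#' @return A list of class `cluster_specificity`: `specificity` (cluster x
#'   gene matrix), `correlation` (cluster x cluster), `order` (dendrogram leaf
#'   order).
#' @export
specificity_and_correlation <- function(markers, datasets, labels) {
  genes <- sort(unique(markers$gene))
  if (length(genes) == 0) abort("No marker genes.")
  b <- bind_spatial(datasets)
  lab <- dplyr::left_join(
    b$meta[, c("sample_id", "barcode")], labels,
    by = c("sample_id", "barcode")
  )$cluster
  x <- as.matrix(log_normalise(b$counts))[, genes, drop = FALSE]
  overall <- colMeans(x)
  clusters <- sort(unique(lab))
  spec <- t(vapply(clusters, function(cc) {
    m <- colMeans(x[lab == cc, , drop = FALSE])
    out <- m / overall
    out[overall == 0] <- 0
    out
  }, numeric(length(genes))))
  dimnames(spec) <- list(as.character(clusters), genes)
  cm <- suppressWarnings(cor(t(spec)))
  cm[!is.finite(cm)] <- 0
  diag(cm) <- 1
  ord <- if (nrow(cm) > 2) hclust(dist(spec), method = "average")$order else seq_len(nrow(cm))
  structure(
    list(specificity = spec, correlation = cm, order = ord),
    class = "cluster_specificity"
  )
}

#' Bin-matched signature score per spot
#'
#' On log-normalised expression: score = mean over signature genes minus mean
#' over control genes, where controls are drawn for each signature gene from
#' its average-expression bin (`n_bins` bins over all genes, `n_ctrl` draws
#' per signature gene, fixed seed). Signature genes absent from the data are
#' dropped with a warning; duplicates are ignored.
#'
#' @param datasets A [spatial_dataset()] or list thereof (or a plain spot x
#'   gene count matrix for cell-level data).
#' @param gene_set Character vector of signature genes.
#' @param n_bins,n_ctrl Control-matching parameters.
#' @param seed Integer seed for control sampling.
#' @return Tibble: `sample_id`, `barcode`, `condition`, `score`.
#' @export
score_signature <- function(datasets, gene_set, n_bins = 25, n_ctrl = 50,
                            seed = 0) {
  if (is.matrix(datasets) || inherits(datasets, "Matrix")) {
    b <- list(
      counts = datasets,
      meta = tibble::tibble(
        sample_id = "cells", barcode = rownames(datasets), condition = "control"
      )
    )
  } else {
    b <- bind_spatial(datasets)
  }
  gene_set <- unique(gene_set)
  present <- intersect(gene_set, colnames(b$counts))
  if (length(present) < length(gene_set)) {
    warn(sprintf("%d signature genes absent from the data; dropped.",
      length(gene_set) - length(present)
    ))
  }
  if (length(present) == 0) abort("No signature gene present in the data.")
  x <- as.matrix(log_normalise(b$counts))
  avg <- colMeans(x)
  bin <- dplyr::ntile(rank(avg, ties.method = "first"), n_bins)
  names(bin) <- colnames(x)
  ctrl <- with_seed(seed, unlist(lapply(present, function(g) {
    pool <- colnames(x)[bin == bin[[g]]]
    sample(pool, min(n_ctrl, length(pool)), replace = length(pool) < n_ctrl)
  })))
  score <- rowMeans(x[, present, drop = FALSE]) - rowMeans(x[, ctrl, drop = FALSE])
  tibble::tibble(
    sample_id = b$meta$sample_id, barcode = b$meta$barcode,
    condition = b$meta$condition, score = unname(score)
  )
}

#' Correlate signature scores with deconvolved cell-type proportions
#'
#' Pearson correlation between each cell-type proportion column and the spot
#' signature score, over all spots and within each condition.
#'
#' @param scores Tibble from [score_signature()].
#' @param decon A `spot_deconvolution` from [deconvolve_spots()] or a long
#'   proportions tibble (`sample_id`, `barcode`, `cell_type`, `proportion`).
#' @param signature Name recorded in the output.
#' @return Tibble: `cell_type`, `condition` (`all`/`control`/`RT`),
#'   `signature`, `r`, `p`, `constant` flag (r set to 0 when either variable
#'   is constant).
#' @export
correlate_signature_proportions <- function(scores, decon, signature = "signature") {
  props <- if (inherits(decon, "spot_deconvolution")) decon$proportions else decon
  joined <- dplyr::inner_join(scores, props, by = c("sample_id", "barcode"))
  if (nrow(joined) == 0) abort("Scores and proportions share no spots.")
  eval_set <- function(df, cond) {
    purrr::map_dfr(sort(unique(df$cell_type)), function(ct) {
      d <- df[df$cell_type == ct, ]
      const <- sd(d$proportion) == 0 || sd(d$score) == 0
      if (const) {
        tibble::tibble(
          cell_type = ct, condition = cond, signature = signature,
          r = 0, p = NA_real_, constant = TRUE
        )
      } else {
        ct_test <- cor.test(d$score, d$proportion)
        tibble::tibble(
          cell_type = ct, condition = cond, signature = signature,
          r = unname(ct_test$estimate), p = ct_test$p.value, constant = FALSE
        )
      }
    })
  }
  dplyr::bind_rows(
    eval_set(joined, "all"),
    purrr::map_dfr(
      intersect(c("control", "RT"), unique(joined$condition)),
      function(cc) eval_set(joined[joined$condition == cc, ], cc)
    )
  )
}
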