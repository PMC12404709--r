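#' Read a receptor-ligand pair table
#'
#' Tab-separated file with columns `pair_id`, `ligand`, `receptor`; multi-
#' subunit complexes are ";"-joined within a field.
#'
#' @param path Path to the TSV.
#' @return Validated tibble: `pair_id`, `ligand`, `receptor`.
#' @export
read_rl_pairs <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("pair_id", "ligand", "receptor") %in% names(df))) {
    abort("R-L table must have columns pair_id, ligand, receptor.")
  }
  validate_rl_pairs(df)
}

validate_rl_pairs <- function(df) {
  for (i in seq_len(nrow(df))) {
    lig <- split_genes(df$ligand[i])
    rec <- split_genes(df$receptor[i])
    if (length(lig) == 0 || length(rec) == 0 || any(!nzchar(c(lig, rec))) ||
      anyNA(c(lig, rec))) {
      abort(sprintf("Malformed R-L row at line %d.", i + 1L))
    }
    if (anyDuplicated(lig) || anyDuplicated(rec)) {
      abort(sprintf("Duplicate subunit within a side at line %d.", i + 1L))
    }
  }
  if (anyDuplicated(df$pair_id)) {
    dup <- df$pair_id[duplicated(df$pair_id)][1]
    abort(sprintf("Duplicate pair_id '%s'.", dup))
  }
  tibble::as_tibble(df[, c("pair_id", "ligand", "receptor")])
}

#' Hexagonal spot adjacency
#'
#' Neighbour list on integer axial coordinates: the six hex-adjacent positions
#' present in the same sample, plus the spot itself (self-loop), so an
#' interior spot of a full grid has degree 7. Adjacency never crosses samples.
#'
#' @param positions Tibble with `sample_id`, `barcode`, `array_row`,
#'   `array_col`, or a list of [spatial_dataset()]s.
#' @return Tibble of undirected-plus-self edges: `sample_id`, `from`, `to`
#'   (barcodes); each unordered neighbour pair appears once, each spot has one
#'   self edge.
#' @export
spot_adjacency <- function(positions) {
  if (!is.data.frame(positions)) {
    datasets <- if (inherits(positions, "spatial_dataset")) list(positions) else positions
    positions <- purrr::map_dfr(datasets, function(d) {
      dplyr::mutate(d$positions, sample_id = d$sample_id, .before = 1)
    })
  }
  dirs <- cbind(
    dr = c(0L, 0L, 1L, -1L, 1L, -1L),
    dc = c(1L, -1L, 0L, 0L, -1L, 1L)
  )
  purrr::map_dfr(split(positions, positions$sample_id), function(p) {
    if (anyDuplicated(p[, c("array_row", "array_col")])) {
      abort(sprintf("Duplicate position in sample %s.", p$sample_id[1]))
    }
    key <- paste(p$array_row, p$array_col)
    lookup <- setNames(p$barcode, key)
    edges <- purrr::map_dfr(seq_len(6), function(j) {
      nk <- paste(p$array_row + dirs[j, 1], p$array_col + dirs[j, 2])
      hit <- nk %in% key
      tibble::tibble(from = p$barcode[hit], to = unname(lookup[nk[hit]]))
    })
    swap <- edges$from > edges$to
    tmp <- edges$from[swap]
    edges$from[swap] <- edges$to[swap]
    edges$to[swap] <- tmp
    edges <- dplyr::distinct(edges)
    dplyr::mutate(
      dplyr::bind_rows(edges, tibble::tibble(from = p$barcode, to = p$barcode)),
      sample_id = p$sample_id[1], .before = 1
    )
  })
}

# Complex expression: minimum over subunits of log-normalised expression.
complex_expression <- function(x, subunit_str) {
  subs <- split_genes(subunit_str)
  subs <- intersect(subs, colnames(x))
  if (length(subs) == 0) return(NULL)
  if (length(subs) == 1) return(x[, subs])
  apply(x[, subs, drop = FALSE], 1, min)
}

#' Score receptor-ligand interactions over adjacent spot pairs
#'
#' For every ordered adjacent spot pair (sender -> receiver, self-pairs
#' included) and every R-L pair: score = sqrt(L(sender) x R(receiver)), where
#' L and R are complex expressions (minimum over subunits) on log-normalised
#' counts. The score is zero whenever either side is zero. Pairs referencing
#' genes absent from the data are skipped with a message.
#'
#' @param datasets A [spatial_dataset()] or list thereof.
#' @param pairs R-L tibble from [read_rl_pairs()] / [simulate_rl_pairs()].
#' @param labels A `spot_clustering` tibble assigning each spot a cluster.
#' @param adjacency Optional precomputed [spot_adjacency()] table.
#' @return A list of class `rl_scores`: `scores` (edge x pair matrix),
#'   `edges` (tibble: `sample_id`, `condition`, `sender_cluster`,
#'   `receiver_cluster` per ordered adjacent pair), `pairs` (tibble of scored
#'   pairs), `skipped` (pair ids not scored).
#' @export
interaction_scores <- function(datasets, pairs, labels, adjacency = NULL) {
  if (inherits(datasets, "spatial_dataset")) datasets <- list(datasets)
  adjacency <- adjacency %||% spot_adjacency(datasets)
  b <- bind_spatial(datasets)
  x <- as.matrix(log_normalise(b$counts))
  rownames(x) <- paste(b$meta$sample_id, b$meta$barcode, sep = "_")
  lab <- dplyr::left_join(
    b$meta, labels[, c("sample_id", "barcode", "cluster")],
    by = c("sample_id", "barcode")
  )
  if (anyNA(lab$cluster)) abort("`labels` must cover every spot.")
  key <- function(s, bc) paste(s, bc, sep = "_")
  lab_of <- setNames(lab$cluster, key(lab$sample_id, lab$barcode))
  cond_of <- setNames(lab$condition, key(lab$sample_id, lab$barcode))
  # ordered edges: both directions of each neighbour pair, one self edge each
  self <- adjacency$from == adjacency$to
  fwd <- adjacency
  bwd <- adjacency[!self, ]
  edges <- dplyr::bind_rows(
    tibble::tibble(sample_id = fwd$sample_id, sender = fwd$from, receiver = fwd$to),
    tibble::tibble(sample_id = bwd$sample_id, sender = bwd$to, receiver = bwd$from)
  )
  s_key <- key(edges$sample_id, edges$sender)
  r_key <- key(edges$sample_id, edges$receiver)
  edge_meta <- tibble::tibble(
    sample_id = edges$sample_id,
    condition = unname(cond_of[s_key]),
    sender_cluster = unname(lab_of[s_key]),
    receiver_cluster = unname(lab_of[r_key])
  )
  lmat <- list()
  kept <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    l <- complex_expression(x, pairs$ligand[i])
    r <- complex_expression(x, pairs$receptor[i])
    lsub <- split_genes(pairs$ligand[i])
    rsub <- split_genes(pairs$receptor[i])
    ok <- all(lsub %in% colnames(x)) && all(rsub %in% colnames(x))
    if (!ok) next
    kept[i] <- TRUE
    lmat[[pairs$pair_id[i]]] <- sqrt(l[s_key] * r[r_key])
  }
  if (sum(kept) == 0) abort("No R-L pair could be scored.")
  if (any(!kept)) {
    inform(sprintf("Skipped %d R-L pairs referencing absent genes.", sum(!kept)))
  }
  structure(
    list(
      scores = do.call(cbind, lmat),
      edges = edge_meta,
      pairs = pairs[kept, , drop = FALSE],
      skipped = pairs$pair_id[!kept]
    ),
    class = "rl_scores"
  )
}

#' @export
print.rl_scores <- function(x, ...) {
  cat(
    "<rl_scores> ", ncol(x$scores), " R-L pairs x ", nrow(x$edges),
    " ordered adjacent spot pairs\n",
    sep = ""
  )
  invisible(x)
}

#' Compare interaction scores between conditions
#'
#' For each R-L pair and each directed (sender group -> receiver group) of
#' niche-cluster groups: two-sided Wilcoxon rank-sum between the RT and
#' control spot-pair score distributions, BH-adjusted across all tested
#' (pair x direction) hypotheses. A hypothesis is tested only when both
#' conditions have at least `min_n` spot pairs and at least 10% (by default)
#' of the spot pairs are nonzero in one of the conditions.
#'
#' @param scores An `rl_scores` from [interaction_scores()].
#' @param cluster_groups Named list mapping a group label to the cluster ids
#'   it contains; default one group per cluster.
#' @param focal Optional list with `sender` and/or `receiver` group labels to
#'   restrict the directed group pairs tested.
#' @param min_frac_nonzero Minimum nonzero fraction in at least one condition.
#' @param min_n Minimum spot pairs per condition.
#' @param aggregate `"none"` (default) tests spot pairs directly, accepting
#'   pseudo-replication across spots; `"sample"` first averages scores per
#'   sample and tests the per-sample means (exact Wilcoxon, few units).
#' @return Tibble of class `rl_test`: `pair_id`, `sender_group`,
#'   `receiver_group`, `statistic`, `p`, `q`, `effect` (median RT minus
#'   control score), `n_rt`, `n_control`, sorted by q.
#' @export
compare_conditions <- function(scores, cluster_groups = NULL, focal = NULL,
                               min_frac_nonzero = 0.1, min_n = 10,
                               aggregate = c("none", "sample")) {
  stopifnot(inherits(scores, "rl_scores"))
  aggregate <- match.arg(aggregate)
  e <- scores$edges
  if (is.null(cluster_groups)) {
    ids <- sort(unique(c(e$sender_cluster, e$receiver_cluster)))
    cluster_groups <- setNames(as.list(ids), as.character(ids))
  }
  group_of <- function(cl) {
    out <- rep(NA_character_, length(cl))
    for (g in names(cluster_groups)) out[cl %in% cluster_groups[[g]]] <- g
    out
  }
  sg <- group_of(e$sender_cluster)
  rg <- group_of(e$receiver_cluster)
  senders <- focal$sender %||% names(cluster_groups)
  receivers <- focal$receiver %||% names(cluster_groups)
  rows <- list()
  for (a in senders) {
    for (bb in receivers) {
      idx <- which(sg == a & rg == bb)
      if (length(idx) == 0) next
      is_rt <- e$condition[idx] == "RT"
      n_rt <- sum(is_rt)
      n_ct <- sum(!is_rt)
      if (n_rt < min_n || n_ct < min_n) next
      sub <- scores$scores[idx, , drop = FALSE]
      nz <- pmax(
        colMeans(sub[is_rt, , drop = FALSE] > 0),
        colMeans(sub[!is_rt, , drop = FALSE] > 0)
      )
      samp <- e$sample_id[idx]
      for (j in which(nz >= min_frac_nonzero)) {
        if (aggregate == "sample") {
          mrt <- tapply(sub[is_rt, j], samp[is_rt], mean)
          mct <- tapply(sub[!is_rt, j], samp[!is_rt], mean)
          if (length(mrt) < 2 || length(mct) < 2) next
          wt <- suppressWarnings(wilcox.test(mrt, mct))
          eff <- median(mrt) - median(mct)
        } else {
          wt <- suppressWarnings(
            wilcox.test(sub[is_rt, j], sub[!is_rt, j], exact = FALSE)
          )
          eff <- median(sub[is_rt, j]) - median(sub[!is_rt, j])
        }
        rows[[length(rows) + 1L]] <- tibble::tibble(
          pair_id = colnames(scores$scores)[j],
          sender_group = a, receiver_group = bb,
          statistic = unname(wt$statistic), p = wt$p.value,
          effect = eff,
          n_rt = n_rt, n_control = n_ct
        )
      }
    }
  }
  if (length(rows) == 0) {
    warn("No (pair x direction) hypothesis passed the testing guards.")
    return(structure(
      tibble::tibble(
        pair_id = character(), sender_group = character(),
        receiver_group = character(), statistic = numeric(), p = numeric(),
        q = numeric(), effect = numeric(), n_rt = integer(), n_control = integer()
      ),
      class = c("rl_test", "tbl_df", "tbl", "data.frame")
    ))
  }
  out <- dplyr::bind_rows(rows)
  out$q <- p.adjust(out$p, method = "BH")
  out <- dplyr::relocate(out, "q", .after = "p")
  structure(
    dplyr::arrange(out, .data$q, .data$p, .data$pair_id),
    class = c("rl_test", "tbl_df", "tbl", "data.frame")
  )
}

#' Count significant interactions per directed cluster pair
#'
#' @param results An `rl_test` tibble from [compare_conditions()].
#' @param q_thresh Significance threshold.
#' @return A list: `counts` (tibble `sender_group`, `receiver_group`, `n`,
#'   including zero rows for tested pairs) and `summary` (within- vs
#'   between-group significant totals).
#' @export
count_significant <- function(results, q_thresh = 0.05) {
  counts <- dplyr::summarise(
    dplyr::group_by(results, .data$sender_group, .data$receiver_group),
    n = sum(.data$q < q_thresh),
    .groups = "drop"
  )
  within <- counts$sender_group == counts$receiver_group
  summary <- tibble::tibble(
    scope = c("within", "between"),
    n = c(sum(counts$n[within]), sum(counts$n[!within])),
    n_pairs = c(sum(within), sum(!within)),
    mean_n = c(
      if (any(within)) mean(counts$n[within]) else 0,
      if (any(!within)) mean(counts$n[!within]) else 0
    )
  )
  list(counts = counts, summary = summary)
}

#' Top-k table of differential interactions
#'
#' @param results An `rl_test` tibble.
#' @param k Number of rows.
#' @return The `k` smallest-q rows.
#' @export
top_interactions <- function(results, k = 25) {
  head(dplyr::arrange(results, .data$q, .data$p), k)
}
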