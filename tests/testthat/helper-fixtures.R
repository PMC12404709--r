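# Small programmatic fixtures shared across test files.

# A hand-built methylation dataset: `betas` is probes x samples, positions
# every 100 bp on one chromosome.
make_meth <- function(betas, groups, covars = NULL) {
  probe_map <- tibble::tibble(
    probe_id = rownames(betas), chrom = "chr1",
    pos = seq_len(nrow(betas)) * 100L
  )
  samples <- tibble::tibble(sample_id = colnames(betas), group = groups)
  if (!is.null(covars)) samples <- dplyr::bind_cols(samples, covars)
  meth_dataset(betas, probe_map, samples)
}

# A DMP tibble with explicit positions, for DMR-merging tests.
make_dmps <- function(pos, effect, q, chrom = "chr1") {
  n <- length(pos)
  tibble::tibble(
    probe_id = sprintf("p%02d", seq_len(n)), chrom = chrom, pos = pos,
    effect_m = effect, delta_beta = effect / 4, statistic = effect,
    p = q, q = q
  )
}

# A tiny spatial dataset on a full hex grid with named gene columns.
make_spatial <- function(counts, sample_id = "s1", condition = "control") {
  n <- nrow(counts)
  side <- ceiling(sqrt(n))
  pos <- tidyr::expand_grid(
    array_row = seq_len(side) - 1L, array_col = seq_len(side) - 1L
  )[seq_len(n), ]
  pos$barcode <- sprintf("b%03d", seq_len(n))
  rownames(counts) <- pos$barcode
  spatial_dataset(counts, pos, sample_id = sample_id, condition = condition)
}

# Direct step-up BH oracle (independent of stats::p.adjust).
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  out <- numeric(n)
  out[o] <- pmin(q, 1)
  out
}

# Exact two-sided rank-sum p-value by full enumeration (no ties assumed).
wilcox_enum <- function(x, y) {
  n <- length(x) + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  combos <- utils::combn(n, length(x))
  ws <- apply(combos, 2, function(i) sum(r[i])) - length(x) * (length(x) + 1) / 2
  min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
}

# Exhaustive hypergeometric two-sided Fisher p for a 2x2 table (a b; c d),
# conditioning on the margins.
fisher_enum <- function(a, b, c, d) {
  m <- a + c
  n_ <- b + d
  k <- a + b
  lo <- max(0, k - n_)
  hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n_, k)
  p_obs <- stats::dhyper(a, m, n_, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
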