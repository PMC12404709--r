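test_that("QC filtering is the identity at zero thresholds and exact on planted spots", {
  set.seed(71)
  counts <- matrix(rpois(100 * 20, 10), 100, 20,
    dimnames = list(NULL, sprintf("g%02d", 1:20))
  )
  counts[5, ] <- 0
  counts[9, ] <- c(5, rep(0, 19))
  d <- make_spatial(counts)
  id <- qc_filter_spots(d, 0, 0)
  expect_equal(nrow(id$datasets$counts), 100)
  expect_equal(id$report$n_removed, 0)
  f <- qc_filter_spots(d, min_counts = 10, min_genes = 2)
  expect_equal(f$report$n_removed, 2)
  expect_false(any(c("b005", "b009") %in% rownames(f$datasets$counts)))
  expect_error(qc_filter_spots(d, min_counts = 1e9), "All spots")
})

test_that("a 20x20 grid has 400 spots and interior spots have 6 hex neighbours", {
  ss <- simulate_spatial(samples = c(s1 = "control"), grid = c(20, 20), seed = 72)
  d <- ss$datasets$s1
  expect_equal(nrow(d$counts), 400)
  adj <- spot_adjacency(dplyr::mutate(d$positions, sample_id = "s1"))
  deg <- table(c(adj$from, adj$to[adj$from != adj$to]))
  interior <- d$positions$barcode[
    d$positions$array_row %in% 5:14 & d$positions$array_col %in% 5:14
  ]
  expect_true(all(deg[interior] == 7))
  corner <- d$positions$barcode[d$positions$array_row == 0 & d$positions$array_col == 0]
  expect_lte(deg[[corner]], 4)
})

test_that("well-separated planted niches are recovered by clustering", {
  prof <- simulate_celltype_profiles(n_celltypes = 4, n_genes = 200, marker_fold = 25, seed = 73)
  arch <- diag(4) * 30 + 1
  arch <- arch / rowSums(arch)
  rownames(arch) <- sprintf("niche%d", 1:4)
  colnames(arch) <- rownames(prof)
  ss <- simulate_spatial(
    samples = c(a = "control", b = "RT"),
    celltype_profiles = prof, niche_archetypes = arch,
    grid = c(12, 12), depth = 2000, concentration = 500,
    neuro_niche = "none", seed = 74
  )
  lab <- cluster_spots(ss$datasets, n_hvg = 200, k = 10, resolution = 0.3, seed = 0)
  j <- dplyr::inner_join(lab, ss$truth$niche_map, by = c("sample_id", "barcode"))
  expect_gte(mclust::adjustedRandIndex(j$cluster, j$niche), 0.9)
  # determinism
  lab2 <- cluster_spots(ss$datasets, n_hvg = 200, k = 10, resolution = 0.3, seed = 0)
  expect_identical(lab$cluster, lab2$cluster)
})

test_that("identical spots collapse to a single cluster", {
  counts <- matrix(5L, 36, 10, dimnames = list(NULL, sprintf("g%02d", 1:10)))
  d <- make_spatial(counts)
  lab <- cluster_spots(d, n_hvg = 10, k = 5, seed = 0)
  expect_equal(unique(lab$cluster), 1L)
})

test_that("an exclusive gene is its cluster's top marker; null clusters give none", {
  set.seed(75)
  counts <- matrix(rpois(80 * 30, 5), 80, 30,
    dimnames = list(NULL, sprintf("g%02d", 1:30))
  )
  counts[1:40, 30] <- 0
  counts[41:80, 30] <- 50        # g30 exclusive to cluster 2
  d <- make_spatial(counts)
  labels <- tibble::tibble(
    sample_id = "s1", barcode = rownames(d$counts),
    cluster = rep(1:2, each = 40)
  )
  mk <- find_markers(d, labels)
  top2 <- mk[mk$cluster == 2, ]
  expect_equal(top2$gene[1], "g30")
  # identical clusters (homogeneous data): no markers most of the time
  set.seed(76)
  d0 <- make_spatial(matrix(rpois(80 * 30, 5), 80, 30,
    dimnames = list(NULL, sprintf("g%02d", 1:30))
  ))
  null_hits <- vapply(1:20, function(i) {
    set.seed(i)
    lab0 <- dplyr::mutate(labels, cluster = sample(cluster))
    nrow(find_markers(d0, lab0))
  }, numeric(1))
  expect_gte(mean(null_hits == 0), 0.95)
})

test_that("specificity is 1 for uniform genes; identical clusters correlate at 1", {
  # clusters 1 and 2 identical; cluster 3 shifts g3 counts onto g1 at equal
  # depth, so depth normalisation leaves the uniform gene g4 untouched
  counts <- matrix(8L, 60, 8, dimnames = list(NULL, sprintf("g%d", 1:8)))
  counts[41:60, 1] <- 16L
  counts[41:60, 3] <- 0L
  d <- make_spatial(counts)
  labels <- tibble::tibble(
    sample_id = "s1", barcode = rownames(d$counts),
    cluster = rep(1:3, each = 20)
  )
  markers <- tibble::tibble(
    cluster = 3L, gene = c("g1", "g2", "g3", "g4"),
    log_fc = 1, statistic = 1, p = 0.01, q = 0.01
  )
  sp <- specificity_and_correlation(markers, d, labels)
  # g4 is uniform across all spots: specificity 1 in every cluster
  expect_equal(unname(sp$specificity[, "g4"]), rep(1, 3), tolerance = 1e-12)
  expect_equal(sp$correlation["1", "2"], 1)
  expect_lt(sp$correlation["1", "3"], 1)
  # permuting the marker row order changes nothing
  sp2 <- specificity_and_correlation(markers[c(3, 1, 4, 2), ], d, labels)
  expect_equal(sp, sp2)
})

test_that("signature scoring dedupes genes, warns on absent ones, errors when empty", {
  ss <- simulate_spatial(samples = c(s1 = "control"), grid = c(10, 10), seed = 76)
  gs <- c("g0010", "g0011", "g0010")
  s1 <- score_signature(ss$datasets, gs, seed = 3)
  s2 <- score_signature(ss$datasets, unique(gs), seed = 3)
  expect_equal(s1, s2)
  expect_warning(score_signature(ss$datasets, c("g0010", "nope"), seed = 3), "absent")
  expect_error(
    suppressWarnings(score_signature(ss$datasets, "nope", seed = 3)),
    "No signature gene"
  )
})

test_that("a planted up-scaled signature scores highest in its niche", {
  ss <- simulate_spatial(
    samples = c(ctl = "control", rt = "RT"), grid = c(14, 14),
    neuro_fold = 3, seed = 77
  )
  sc <- score_signature(ss$datasets, ss$truth$neuropeptide_genes, seed = 5)
  j <- dplyr::inner_join(sc, ss$truth$niche_map, by = c("sample_id", "barcode"))
  rt <- j[j$condition == "RT", ]
  means <- tapply(rt$score, rt$niche, mean)
  expect_equal(names(which.max(means)), "neuron")
})

test_that("signature-proportion correlation is exact on a self-match and flags constants", {
  ss <- simulate_spatial(samples = c(s1 = "control"), grid = c(8, 8), seed = 78)
  props <- ss$truth$proportions
  one <- props[props$cell_type == "ct01", ]
  scores <- tibble::tibble(
    sample_id = one$sample_id, barcode = one$barcode,
    condition = "control", score = one$proportion
  )
  tab <- correlate_signature_proportions(scores, props, "self")
  expect_equal(tab$r[tab$cell_type == "ct01" & tab$condition == "all"], 1)
  const <- dplyr::mutate(props, proportion = ifelse(cell_type == "ct02", 0.5, proportion))
  tab2 <- correlate_signature_proportions(scores, const, "self")
  expect_true(tab2$constant[tab2$cell_type == "ct02" & tab2$condition == "all"])
  expect_equal(tab2$r[tab2$cell_type == "ct02" & tab2$condition == "all"], 0)
})
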