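# A hand-laid annotation for precedence and mapping tests:
# chr1: 0-1000 intergenic | 1000-2000 promoter(gA) | 2000-2500 utr5(gA) |
# 2500-3500 exon(gA) | 3500-4500 intron(gA) | 4500-5000 utr3(gA) |
# 5000-6000 TE | 6000-50000 intergenic
toy_ann <- tibble::tibble(
  chrom = "chr1",
  start = c(0L, 1000L, 2000L, 2500L, 3500L, 4500L, 5000L, 6000L),
  end = c(1000L, 2000L, 2500L, 3500L, 4500L, 5000L, 6000L, 50000L),
  strand = "+",
  gene_id = c(NA, "gA", "gA", "gA", "gA", "gA", NA, NA),
  feature_class = c(
    "intergenic", "promoter", "utr5", "exon", "intron", "utr3", "TE",
    "intergenic"
  )
)

make_dmr <- function(start, end, direction = "hypo", id = "dmr1") {
  tibble::tibble(
    dmr_id = id, chrom = "chr1", start = start, end = end, n_probes = 3L,
    direction = direction, mean_delta_beta = ifelse(direction == "hypo", -0.2, 0.2),
    length_bp = end - start, probe_ids = list(sprintf("p%d", 1:3))
  )
}

test_that("midpoint precedence assigns promoter over overlapped classes", {
  # midpoint 1950 in promoter; interval also overlaps utr5 and exon
  ad <- annotate_dmrs(make_dmr(1300L, 2600L), toy_ann)
  expect_equal(ad$region_class, "promoter")
  expect_equal(ad$gene_ids[[1]], "gA")
})

test_that("a DMR between genes is intergenic and unannotated chroms warn", {
  ad <- annotate_dmrs(make_dmr(30000L, 30500L), toy_ann)
  expect_equal(ad$region_class, "intergenic")
  expect_equal(length(ad$gene_ids[[1]]), 0)
  off <- dplyr::mutate(make_dmr(10L, 50L), chrom = "chrUn")
  expect_warning(ad2 <- annotate_dmrs(off, toy_ann), "intergenic")
  expect_equal(ad2$region_class, "intergenic")
})

test_that("uniformly placed DMRs reproduce the background location mix", {
  ann <- simulate_annotation(40, 15, seed = 21)
  len <- max(ann$end)
  set.seed(22)
  starts <- sort(sample.int(len - 600L, 400))
  dmrs <- purrr::map_dfr(seq_along(starts), function(i) {
    make_dmr(starts[i], starts[i] + 500L, id = sprintf("d%03d", i))
  })
  probe_map <- tibble::tibble(
    probe_id = sprintf("cg%04d", 1:2000), chrom = "chr1",
    pos = sort(sample.int(len - 1L, 2000))
  )
  ad <- annotate_dmrs(dmrs, ann)
  loc <- dmr_location_table(ad, probe_map, ann)
  all_pct <- loc[loc$set == "all", ]
  bg_pct <- loc[loc$set == "background", ]
  for (cl in unique(all_pct$feature_class)) {
    p_bg <- bg_pct$pct[bg_pct$feature_class == cl] / 100
    se <- sqrt(p_bg * (1 - p_bg) / 400)
    expect_lt(
      abs(all_pct$pct[all_pct$feature_class == cl] / 100 - p_bg),
      4 * se + 0.02
    )
  }
  enr <- region_enrichment(loc)
  expect_true(all(enr$q >= enr$p))
})

test_that("enrichment of DMRs concentrated in promoters is detected", {
  ad <- purrr::map_dfr(1:20, function(i) {
    dplyr::mutate(
      annotate_dmrs(make_dmr(1100L + 10L * i, 1150L + 10L * i, id = sprintf("d%d", i)), toy_ann)
    )
  })
  probe_map <- tibble::tibble(
    probe_id = sprintf("cg%03d", 1:500), chrom = "chr1",
    pos = as.integer(seq(10, 49000, length.out = 500))
  )
  loc <- dmr_location_table(ad, probe_map, toy_ann)
  enr <- region_enrichment(loc)
  prom <- enr[enr$set == "all" & enr$feature_class == "promoter", ]
  expect_equal(prom$label, "enriched")
  expect_true(is.infinite(prom$odds_ratio) || prom$odds_ratio > 50)
  expect_equal(min(enr$q[enr$set == "all"]), prom$q)
})

test_that("DMGs aggregate region classes per gene and respect the 10 kb cutoff", {
  dmrs <- dplyr::bind_rows(
    make_dmr(1100L, 1300L, "hypo", "d1"),     # promoter gA
    make_dmr(3600L, 3900L, "hyper", "d2"),    # intron gA
    make_dmr(40000L, 40500L, "hypo", "d3")    # intergenic, ~37 kb from gA TSS
  )
  ad <- annotate_dmrs(dmrs, toy_ann)
  dmgs <- map_dmgs(ad, toy_ann)
  expect_equal(unique(dmgs$gene_id), "gA")
  expect_setequal(dmgs$region_class, c("promoter", "intron"))
  expect_setequal(dmgs$direction, c("hypo", "hyper"))
  # nearby intergenic maps to the closest TSS within 10 kb
  near <- annotate_dmrs(make_dmr(7000L, 7400L, "hypo", "d4"), toy_ann)
  expect_equal(map_dmgs(near, toy_ann)$gene_id, "gA")
})
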