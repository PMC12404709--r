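test_that("methylation-expression coupling plants the region-dependent signs", {
  ann <- simulate_annotation(40, 10, seed = 61)
  sim <- simulate_methylation(ann, 6000, n_dmrs = 30, frac_hypo = 0.5, seed = 62)
  se <- simulate_expression(sim$truth, ann, seed = 63)
  tr <- dplyr::inner_join(
    se$truth$concordant_truth,
    se$truth$deg_truth,
    by = "gene_id"
  )
  anti <- tr[tr$region_class %in% c("promoter", "utr5", "exon"), ]
  corr <- tr[tr$region_class %in% c("utr3", "intron", "intergenic"), ]
  # promoter/5'UTR/exon: hypomethylation pairs with up-regulation
  expect_true(all(sign(anti$log_fc) ==
    ifelse(anti$methyl_direction == "hypo", 1, -1)))
  # 3'UTR/intron/intergenic: hypomethylation pairs with down-regulation
  expect_true(all(sign(corr$log_fc) ==
    ifelse(corr$methyl_direction == "hypo", -1, 1)))
  # zero coupling plants no expression change on DMR genes
  se0 <- simulate_expression(sim$truth, ann,
    coupling = setNames(rep(0, 7), names(methniche:::default_coupling)),
    n_deg_only = 0, seed = 64
  )
  expect_equal(nrow(se0$truth$concordant_truth), 0)
  expect_true(all(se0$truth$deg_truth$log_fc == 0))
  expect_error(
    simulate_expression(sim$truth, ann, coupling = c(promoter = 1), seed = 1),
    "region class"
  )
})

test_that("DEG calling is calibrated under the null and finds planted shifts", {
  ann <- simulate_annotation(30, 0, seed = 65)
  null_truth <- list(dmr_truth = tibble::tibble(
    dmr_id = character(), gene_id = character(), direction = character(),
    region_class = character()
  ))
  se <- simulate_expression(null_truth, ann, n_deg_only = 0, seed = 66)
  degs <- call_degs(se$counts, se$samples)
  ks <- suppressWarnings(stats::ks.test(degs$p, "punif"))
  expect_gt(ks$p.value, 0.01)
  # planted decoys rank on top
  se2 <- simulate_expression(null_truth, ann, n_deg_only = 10, seed = 67)
  degs2 <- call_degs(se2$counts, se2$samples)
  planted <- se2$truth$deg_only
  auroc <- mean(rank(-abs(degs2$statistic))[match(planted, degs2$gene_id)] <=
    length(planted) + 2)
  expect_gt(auroc, 0.8)
  expect_true(all(degs2$q >= degs2$p))
})

test_that("all-zero genes are dropped with a message", {
  counts <- matrix(rpois(40, 10), 10, 4,
    dimnames = list(sprintf("g%d", 1:10), sprintf("s%d", 1:4))
  )
  counts[3, ] <- 0
  samples <- tibble::tibble(
    sample_id = sprintf("s%d", 1:4), group = rep(c("control", "RT"), 2)
  )
  expect_message(degs <- call_degs(counts, samples), "all-zero")
  expect_false("g3" %in% degs$gene_id)
})

test_that("DMG/DEG overlap behaves on disjoint and nested inputs", {
  dmgs <- tibble::tibble(gene_id = c("a", "b"))
  degs <- tibble::tibble(gene_id = c("c", "d"), q = c(0.01, 0.01))
  expect_equal(overlap_dmg_deg(dmgs, degs), character(0))
  degs2 <- tibble::tibble(gene_id = c("a", "b", "z"), q = c(0.01, 0.2, 0.001))
  expect_equal(overlap_dmg_deg(dmgs, degs2), "a")
  degs3 <- tibble::tibble(gene_id = c("b", "a", "z"), q = rep(0.001, 3))
  expect_equal(overlap_dmg_deg(dmgs, degs3), c("a", "b"))
})

test_that("the concordance rule matches the exhaustive 24-case truth table", {
  cases <- tidyr::expand_grid(
    region_class = c("promoter", "utr5", "exon", "utr3", "intron", "intergenic"),
    methyl_direction = c("hypo", "hyper"),
    expr_direction = c("up", "down")
  )
  # hand-written rule table: anti-correlation at promoter/utr5/exon,
  # correlation at utr3/intron/intergenic
  expected <- with(cases, ifelse(
    region_class %in% c("promoter", "utr5", "exon"),
    (methyl_direction == "hypo") == (expr_direction == "up"),
    (methyl_direction == "hypo") == (expr_direction == "down")
  ))
  got <- purrr::pmap_lgl(cases, function(region_class, methyl_direction, expr_direction) {
    dmgs <- tibble::tibble(
      gene_id = "g", dmr_id = "d", region_class = region_class,
      direction = methyl_direction, mean_delta_beta = ifelse(methyl_direction == "hypo", -0.2, 0.2)
    )
    degs <- tibble::tibble(
      gene_id = "g", log_fc = ifelse(expr_direction == "up", 1.5, -1.5),
      statistic = 5, p = 1e-4, q = 1e-3
    )
    rec <- classify_concordance(dmgs, degs)
    expect_equal(nrow(rec), 1)
    rec$concordant
  })
  expect_equal(got, expected)
})

test_that("TE entries are excluded and records are order-invariant", {
  dmgs <- tibble::tibble(
    gene_id = c("g", "g"), dmr_id = c("d1", "d2"),
    region_class = c("TE", "promoter"),
    direction = c("hypo", "hypo"), mean_delta_beta = c(-0.3, -0.2)
  )
  degs <- tibble::tibble(gene_id = "g", log_fc = 2, statistic = 5, p = 1e-4, q = 1e-3)
  rec <- classify_concordance(dmgs, degs)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$region_class, "promoter")
  expect_equal(attr(rec, "n_te_excluded"), 1)
  rec2 <- classify_concordance(dmgs[2:1, ], degs)
  expect_equal(as.data.frame(rec), as.data.frame(rec2))
  expect_equal(concordant_genes(rec), "g")
})

test_that("signature building follows the magnitude rule and eligibility", {
  dmgs <- tibble::tibble(
    gene_id = c("gA", "gA", "gB", "gC", "gD"),
    dmr_id = sprintf("d%d", 1:5),
    region_class = c("promoter", "exon", "promoter", "intron", "utr5"),
    direction = c("hypo", "hyper", "hyper", "hypo", "hypo"),
    mean_delta_beta = c(-0.3, 0.1, 0.25, -0.4, -0.15)
  )
  expect_warning(sig <- build_methylation_signature(dmgs, k = 200), "Fewer")
  # gA: promoter -0.3 beats exon +0.1 -> hypo list; gC intron ineligible
  expect_equal(sig$hypo_genes, c("gA", "gD"))
  expect_equal(sig$hyper_genes, "gB")
  # adding non-eligible DMGs does not change the lists
  more <- dplyr::bind_rows(dmgs, tibble::tibble(
    gene_id = "gE", dmr_id = "d6", region_class = "utr3",
    direction = "hypo", mean_delta_beta = -0.5
  ))
  expect_warning(sig2 <- build_methylation_signature(more, k = 200), "Fewer")
  expect_equal(sig2$hypo_genes, sig$hypo_genes)
  expect_equal(sig2$hyper_genes, sig$hyper_genes)
  td <- tidy(sig)
  expect_equal(nrow(td), 3)
})
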