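test_that("R-L tables parse simple pairs and complexes; duplicates error", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    pair_id = c("P1", "P2"), ligand = c("L1", "L1"),
    receptor = c("R1", "R1;R2")
  ), path)
  pairs <- read_rl_pairs(path)
  expect_equal(nrow(pairs), 2)
  expect_equal(methniche:::split_genes(pairs$receptor[2]), c("R1", "R2"))
  readr::write_tsv(tibble::tibble(
    pair_id = c("P1", "P1"), ligand = "L1", receptor = "R1"
  ), path)
  expect_error(read_rl_pairs(path), "Duplicate pair_id")
  readr::write_tsv(tibble::tibble(
    pair_id = "P3", ligand = "L1", receptor = "R1;R1"
  ), path)
  expect_error(read_rl_pairs(path), "line 2")
})

test_that("adjacency never crosses samples and rejects duplicate positions", {
  pos <- tidyr::expand_grid(array_row = 0:2, array_col = 0:2)
  pos$barcode <- sprintf("b%d", seq_len(nrow(pos)))
  two <- dplyr::bind_rows(
    dplyr::mutate(pos, sample_id = "s1"),
    dplyr::mutate(pos, sample_id = "s2")
  )
  adj <- spot_adjacency(two)
  one <- spot_adjacency(dplyr::mutate(pos, sample_id = "s1"))
  # each sample contributes exactly its own within-sample edges
  expect_equal(nrow(adj), 2 * nrow(one))
  expect_equal(
    nrow(adj[adj$sample_id == "s1", ]),
    nrow(adj[adj$sample_id == "s2", ])
  )
  dup <- dplyr::mutate(two, array_row = 0L, array_col = 0L)
  expect_error(spot_adjacency(dup), "Duplicate position")
})

test_that("interaction scores follow the min-subunit and geometric-mean rules", {
  # 4 spots in a row; constructed expression after log-normalisation
  counts <- rbind(
    c(L = 0L, R1 = 0L, R2 = 0L, F1 = 10L),
    c(L = 15L, R1 = 4L, R2 = 1L, F1 = 0L),
    c(L = 15L, R1 = 4L, R2 = 1L, F1 = 0L),
    c(L = 0L, R1 = 0L, R2 = 0L, F1 = 10L)
  )
  colnames(counts) <- c("L", "R1", "R2", "F1")
  d <- make_spatial(counts)
  labels <- tibble::tibble(
    sample_id = "s1", barcode = rownames(d$counts), cluster = 1L
  )
  pairs <- tibble::tibble(
    pair_id = c("simple", "complex", "absent"),
    ligand = c("L", "L", "L"),
    receptor = c("R1", "R1;R2", "GONE")
  )
  expect_message(sc <- interaction_scores(d, pairs, labels), "Skipped 1")
  expect_equal(sc$skipped, "absent")
  x <- as.matrix(methniche:::log_normalise(d$counts))
  # self-pair of spot b002: sqrt(L * R1)
  b2 <- x["b002", ]
  expected_self <- sqrt(b2[["L"]] * b2[["R1"]])
  expect_true(any(abs(sc$scores[, "simple"] - expected_self) < 1e-12))
  # complex expression is min over subunits, then the geometric mean
  expected_complex <- sqrt(b2[["L"]] * min(b2[["R1"]], b2[["R2"]]))
  expect_true(any(abs(sc$scores[, "complex"] - expected_complex) < 1e-12))
  expect_true(all(sc$scores >= 0))
  # a zero ligand annihilates the score (spots b001/b004 have L = 0)
  expect_true(any(sc$scores[, "simple"] == 0))
})

test_that("the geometric mean reduces to x when both sides equal x", {
  x <- c(0.5, 2, 7)
  expect_equal(sqrt(x * x), x)
  # min-rule worked example: receptor complex (4, 1) with ligand 4 -> sqrt(4*1) = 2
  expect_equal(sqrt(4 * min(4, 1)), 2)
})

test_that("condition comparison guards small and all-zero hypotheses", {
  set.seed(91)
  counts <- matrix(rpois(64 * 6, 8), 64, 6,
    dimnames = list(NULL, c("La", "Ra", "Lb", "Rb", "x1", "x2"))
  )
  d1 <- make_spatial(counts, "s1", "control")
  d2 <- make_spatial(counts, "s2", "RT")
  labels <- purrr::map_dfr(list(d1, d2), function(d) {
    tibble::tibble(
      sample_id = d$sample_id, barcode = rownames(d$counts), cluster = 1L
    )
  })
  pairs <- tibble::tibble(pair_id = "P1", ligand = "La", receptor = "Ra")
  sc <- interaction_scores(list(d1, d2), pairs, labels)
  res <- compare_conditions(sc)
  expect_equal(nrow(res), 1)
  expect_true(all(res$q >= res$p))
  # min_n guard: demand more pairs than exist
  res2 <- suppressWarnings(compare_conditions(sc, min_n = 1e6))
  expect_equal(nrow(res2), 0)
  # nonzero-fraction guard
  res3 <- suppressWarnings(compare_conditions(sc, min_frac_nonzero = 1.01))
  expect_equal(nrow(res3), 0)
})

test_that("significant-interaction counting matches thresholds exactly", {
  res <- structure(
    tibble::tibble(
      pair_id = sprintf("P%d", 1:4),
      sender_group = c("a", "a", "b", "b"),
      receiver_group = c("a", "b", "a", "b"),
      statistic = 1, p = c(0.001, 0.2, 0.3, 0.01),
      q = c(0.004, 0.4, 0.45, 0.03),
      effect = 1, n_rt = 10L, n_control = 10L
    ),
    class = c("rl_test", "tbl_df", "tbl", "data.frame")
  )
  cnt <- count_significant(res, q_thresh = 0.05)
  expect_equal(cnt$counts$n[cnt$counts$sender_group == "a" & cnt$counts$receiver_group == "a"], 1)
  expect_equal(cnt$summary$n[cnt$summary$scope == "within"], 2)
  expect_equal(cnt$summary$n[cnt$summary$scope == "between"], 0)
  # q_thresh = 1 counts every tested hypothesis
  cnt_all <- count_significant(res, q_thresh = 1.01)
  expect_equal(sum(cnt_all$counts$n), 4)
  expect_equal(nrow(top_interactions(res, 2)), 2)
})

test_that("per-sample aggregation mode tests sample means", {
  set.seed(92)
  mk <- function(id, cond, shift) {
    counts <- matrix(rpois(64 * 3, 8 + shift), 64, 3,
      dimnames = list(NULL, c("La", "Ra", "x"))
    )
    make_spatial(counts, id, cond)
  }
  ds <- list(
    mk("c1", "control", 0), mk("c2", "control", 0),
    mk("r1", "RT", 6), mk("r2", "RT", 6)
  )
  labels <- purrr::map_dfr(ds, function(d) {
    tibble::tibble(sample_id = d$sample_id, barcode = rownames(d$counts), cluster = 1L)
  })
  pairs <- tibble::tibble(pair_id = "P1", ligand = "La", receptor = "Ra")
  sc <- interaction_scores(ds, pairs, labels)
  res <- compare_conditions(sc, aggregate = "sample")
  expect_equal(nrow(res), 1)
  expect_gt(res$effect, 0)
})
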