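test_that("beta/M transform hits the textbook anchor points and inverts", {
  expect_equal(beta_to_m(0.5), 0)
  expect_equal(beta_to_m(0.8), 2)
  expect_equal(beta_to_m(0.2), -2)
  b <- runif(100, 0.01, 0.99)
  expect_equal(m_to_beta(beta_to_m(b)), b, tolerance = 1e-12)
  expect_error(beta_to_m(1.2), "proportions")
  expect_error(beta_to_m(-0.1), "proportions")
})

test_that("a strongly planted probe attains the smallest q", {
  set.seed(31)
  n <- 200
  base <- runif(n, 0.3, 0.7)
  m <- beta_to_m(base) + matrix(rnorm(n * 20, 0, 0.3), n, 20)
  m[1, 11:20] <- m[1, 11:20] + (beta_to_m(base[1] + 0.3) - beta_to_m(base[1]))
  betas <- m_to_beta(m)
  dimnames(betas) <- list(sprintf("cg%03d", 1:n), sprintf("s%02d", 1:20))
  data <- make_meth(betas, rep(c("control", "RT"), each = 10))
  dmps <- call_dmps(data)
  expect_equal(dmps$probe_id[1], "cg001")
  expect_gt(dmps$delta_beta[1], 0.2)
  expect_equal(sign(dmps$effect_m[1]), unname(sign(dmps$delta_beta[1])))
  expect_true(all(dmps$q >= dmps$p))
})

test_that("covariate adjustment attenuates a confounded group effect", {
  set.seed(32)
  n_probe <- 50
  groups <- rep(c("control", "RT"), each = 8)
  age <- rnorm(16) + 2 * (groups == "RT")     # confounded covariate
  m <- matrix(rnorm(n_probe * 16, 0, 0.3), n_probe, 16)
  m <- m + outer(rep(0.5, n_probe), age)      # probes respond to age only
  betas <- m_to_beta(m)
  dimnames(betas) <- list(sprintf("cg%03d", 1:n_probe), sprintf("s%02d", 1:16))
  data <- make_meth(betas, groups, covars = tibble::tibble(age = age))
  raw <- call_dmps(data)
  adj <- call_dmps(data, covariates = "age")
  expect_lt(
    mean(abs(adj$effect_m)),
    0.5 * mean(abs(raw$effect_m))
  )
})

test_that("per-probe OLS matches lm() on a spot check", {
  set.seed(33)
  betas <- matrix(runif(5 * 12, 0.2, 0.8), 5, 12,
    dimnames = list(sprintf("cg%d", 1:5), sprintf("s%02d", 1:12))
  )
  cov <- tibble::tibble(age = rnorm(12))
  data <- make_meth(betas, rep(c("control", "RT"), 6), covars = cov)
  dmps <- call_dmps(data, covariates = "age")
  m <- beta_to_m(data$betas)
  for (pid in rownames(betas)) {
    ref <- summary(lm(m[pid, ] ~ I(data$samples$group == "RT") + cov$age))
    row <- dmps[dmps$probe_id == pid, ]
    expect_equal(row$effect_m, unname(ref$coefficients[2, 1]), tolerance = 1e-10)
    expect_equal(row$p, unname(ref$coefficients[2, 4]), tolerance = 1e-10)
  }
})

test_that("rank-deficient designs fail naming the collinear column", {
  betas <- matrix(runif(10 * 8, 0.2, 0.8), 10, 8,
    dimnames = list(sprintf("cg%d", 1:10), sprintf("s%d", 1:8))
  )
  groups <- rep(c("control", "RT"), each = 4)
  data <- make_meth(betas, groups,
    covars = tibble::tibble(dup = as.numeric(groups == "RT"))
  )
  expect_error(call_dmps(data, covariates = "dup"), "dup")
})

test_that("three same-sign significant probes merge into one DMR", {
  dmps <- make_dmps(pos = c(100L, 400L, 900L), effect = c(-1, -1, -1), q = rep(0.001, 3))
  dmrs <- call_dmrs(dmps, q_thresh = 0.05, maxgap_bp = 1000, min_probes = 3)
  expect_equal(nrow(dmrs), 1)
  expect_equal(dmrs$start, 100L)
  expect_equal(dmrs$end, 901L)
  expect_equal(dmrs$direction, "hypo")
  expect_equal(dmrs$length_bp, 801L)
  expect_equal(dmrs$probe_ids[[1]], c("p01", "p02", "p03"))
})

test_that("a sign break or a large gap splits the run below min_probes", {
  flip <- make_dmps(pos = c(100L, 400L, 900L), effect = c(-1, 1, -1), q = rep(0.001, 3))
  expect_equal(nrow(call_dmrs(flip, min_probes = 3)), 0)
  gap <- make_dmps(pos = c(100L, 400L, 2000L), effect = c(-1, -1, -1), q = rep(0.001, 3))
  expect_equal(nrow(call_dmrs(gap, maxgap_bp = 1000, min_probes = 3)), 0)
  expect_equal(nrow(call_dmrs(gap, maxgap_bp = 2000, min_probes = 3)), 1)
})

test_that("DMR construction ignores input row order and empty input", {
  dmps <- make_dmps(
    pos = c(100L, 300L, 500L, 5000L, 5200L, 5400L),
    effect = c(-1, -1, -1, 1, 1, 1), q = rep(0.01, 6)
  )
  shuffled <- dmps[c(4, 1, 6, 2, 5, 3), ]
  expect_equal(call_dmrs(dmps), call_dmrs(shuffled))
  expect_equal(nrow(call_dmrs(dmps[0, ])), 0)
})

test_that("variable probe selection z-scores and clusters deterministically", {
  set.seed(34)
  betas <- matrix(runif(50 * 6, 0.2, 0.8), 50, 6,
    dimnames = list(sprintf("cg%02d", 1:50), sprintf("s%d", 1:6))
  )
  betas[, 6] <- betas[, 5]          # two identical samples
  data <- make_meth(betas, rep(c("control", "RT"), each = 3))
  hm <- variable_probe_matrix(data, k = 20)
  expect_equal(dim(hm$z), c(20, 6))
  expect_equal(unname(rowMeans(hm$z)), rep(0, 20), tolerance = 1e-12)
  d <- as.matrix(dist(t(hm$z)))
  expect_equal(d["s5", "s6"], 0)
  leaf <- hm$col_order
  expect_equal(abs(which(leaf == 5) - which(leaf == 6)), 1)
  # k = all probes is the identity selection
  hm_all <- variable_probe_matrix(data, k = 50)
  expect_setequal(rownames(hm_all$z), rownames(betas))
  expect_error(variable_probe_matrix(data, k = 0), "k")
})
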