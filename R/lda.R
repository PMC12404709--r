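# Reference-free deconvolution of spots into cell-type "topics" by latent
# Dirichlet allocation, fitted with batch variational EM (mean-field VB with
# Dirichlet expectations, as in standard online/batch LDA).

# Gene filter for LDA: keep genes detected in [min_frac, max_frac] of spots
# and over-dispersed relative to Poisson (variance/mean ratio > disp_min).
filter_lda_genes <- function(counts, min_frac = 0.05, max_frac = 0.95,
                             disp_min = 1) {
  det <- Matrix::colMeans(counts > 0)
  m <- Matrix::colMeans(counts)
  v <- apply(as.matrix(counts), 2, var)
  keep <- det >= min_frac & det <= max_frac & (v / pmax(m, 1e-12)) > disp_min
  colnames(counts)[keep]
}

dirichlet_expectation <- function(a) {
  if (is.matrix(a)) digamma(a) - digamma(rowSums(a)) else digamma(a) - digamma(sum(a))
}

# One variational E-step: optimise per-spot topic posteriors gamma given
# expElogbeta. Returns gamma and the sufficient statistics / phinorm needed
# by the M-step and the bound.
lda_e_step <- function(n_mat, exp_elog_beta, alpha, gamma0 = NULL,
                       inner_iter = 60, inner_tol = 1e-4) {
  d <- nrow(n_mat)
  k <- nrow(exp_elog_beta)
  gamma <- gamma0 %||% matrix(1, d, k)
  for (it in seq_len(inner_iter)) {
    exp_elog_theta <- exp(dirichlet_expectation(gamma))
    phinorm <- exp_elog_theta %*% exp_elog_beta + 1e-100
    gamma_new <- alpha + exp_elog_theta * ((n_mat / phinorm) %*% t(exp_elog_beta))
    delta <- mean(abs(gamma_new - gamma))
    gamma <- gamma_new
    if (delta < inner_tol) break
  }
  exp_elog_theta <- exp(dirichlet_expectation(gamma))
  phinorm <- exp_elog_theta %*% exp_elog_beta + 1e-100
  sstats <- t(exp_elog_theta) %*% (n_mat / phinorm)
  list(gamma = gamma, phinorm = phinorm, sstats = sstats)
}

lda_bound <- function(n_mat, gamma, lambda, phinorm, alpha, eta) {
  d <- nrow(gamma)
  k <- ncol(gamma)
  g <- ncol(lambda)
  elog_theta <- dirichlet_expectation(gamma)
  elog_beta <- dirichlet_expectation(lambda)
  score <- sum(n_mat * log(phinorm))
  score <- score + sum((alpha - gamma) * elog_theta) +
    sum(lgamma(gamma)) - sum(lgamma(rowSums(gamma))) +
    d * (lgamma(k * alpha) - k * lgamma(alpha))
  score + sum((eta - lambda) * elog_beta) +
    sum(lgamma(lambda)) - sum(lgamma(rowSums(lambda))) +
    k * (lgamma(g * eta) - g * lgamma(eta))
}

# Batch variational EM for LDA on a spots x genes count matrix. Restarted
# from `n_restarts` random initialisations; the fit with the best final ELBO
# wins (the variational objective is multi-modal and the bound discriminates
# good from degenerate local optima).
lda_vem <- function(n_mat, k, alpha = 1 / k, eta = 1 / k, max_iter = 200,
                    tol = 1e-6, seed = 0, n_restarts = 8) {
  fits <- lapply(seq_len(n_restarts), function(r) {
    lda_vem_once(n_mat, k, alpha, eta, max_iter, tol,
      seed = derive_seed(seed, paste0("restart", r))
    )
  })
  fits[[which.max(vapply(fits, function(f) tail(f$bound, 1), numeric(1)))]]
}

lda_vem_once <- function(n_mat, k, alpha, eta, max_iter, tol, seed) {
  stopifnot(k >= 2)
  lambda <- with_seed(
    seed,
    matrix(stats::rgamma(k * ncol(n_mat), 100, 100), k, ncol(n_mat))
  )
  gamma <- NULL
  bound_trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    exp_elog_beta <- exp(dirichlet_expectation(lambda))
    es <- lda_e_step(n_mat, exp_elog_beta, alpha, gamma0 = gamma)
    gamma <- es$gamma
    lambda <- eta + es$sstats * exp_elog_beta
    bound <- lda_bound(n_mat, gamma, lambda, es$phinorm, alpha, eta)
    bound_trace <- c(bound_trace, bound)
    if (it > 1 && abs(bound - bound_trace[it - 1]) <
      tol * abs(bound_trace[it - 1])) {
      break
    }
  }
  theta <- gamma / rowSums(gamma)
  beta <- lambda / rowSums(lambda)
  dimnames(theta) <- list(rownames(n_mat), sprintf("topic%02d", seq_len(k)))
  dimnames(beta) <- list(sprintf("topic%02d", seq_len(k)), colnames(n_mat))
  list(
    theta = theta, beta = beta, gamma = gamma, lambda = lambda,
    bound = bound_trace, alpha = alpha, eta = eta
  )
}

# Per-token held-out perplexity of counts under point estimates, folding the
# held-out spots in by an E-step against the trained topics.
lda_perplexity <- function(n_mat, fit) {
  exp_elog_beta <- exp(dirichlet_expectation(fit$lambda))
  es <- lda_e_step(n_mat, exp_elog_beta, fit$alpha)
  theta <- es$gamma / rowSums(es$gamma)
  beta <- fit$lambda / rowSums(fit$lambda)
  ll <- sum(n_mat * log(theta %*% beta + 1e-300))
  exp(-ll / sum(n_mat))
}

#' Reference-free deconvolution of spots by topic modelling
#'
#' Fits latent Dirichlet allocation (batch variational EM, fixed seed) to the
#' raw spot counts after an informative-gene filter, over a grid of candidate
#' topic numbers K. K is chosen to minimise held-out perplexity (20% of spots
#' held out) after discarding K values that produce any rare topic (mean
#' proportion below `rare_topic`); the final model is refitted on all spots at
#' the chosen K. Topics play the role of cell types.
#'
#' @param datasets A [spatial_dataset()] or list thereof.
#' @param k_grid Integer vector of candidate K (each >= 2).
#' @param min_frac,max_frac,disp_min Gene filter: detection-rate window and
#'   minimum variance/mean over-dispersion.
#' @param rare_topic Mean-proportion threshold below which a topic marks its K
#'   as over-fitted.
#' @param holdout_frac Fraction of spots held out for perplexity.
#' @param max_iter Variational EM iteration cap.
#' @param n_restarts Random restarts per fit; the best final ELBO wins.
#' @param seed Integer seed.
#' @return A list of class `spot_deconvolution`: `proportions` (long tibble:
#'   `sample_id`, `barcode`, `cell_type`, `proportion`), `theta` (spot x K
#'   matrix), `topic_profiles` (K x gene multinomial rows), `K`,
#'   `perplexity_by_k` (tibble with the rare-topic flag), `bound` (ELBO trace
#'   of the final fit), `genes` (genes used).
#' @export
deconvolve_spots <- function(datasets, k_grid = 2:7, min_frac = 0.05,
                             max_frac = 0.95, disp_min = 1,
                             rare_topic = 0.02, holdout_frac = 0.2,
                             max_iter = 200, n_restarts = 8, seed = 0) {
  if (any(k_grid < 2)) abort("All K in `k_grid` must be >= 2.")
  b <- bind_spatial(datasets)
  genes <- filter_lda_genes(b$counts, min_frac, max_frac, disp_min)
  if (length(genes) == 0) abort("No gene passes the LDA filter.")
  n_mat <- as.matrix(b$counts[, genes, drop = FALSE])
  n_spots <- nrow(n_mat)
  test_idx <- with_seed(
    derive_seed(seed, "lda_holdout"),
    sort(sample.int(n_spots, max(1L, round(holdout_frac * n_spots))))
  )
  train <- n_mat[-test_idx, , drop = FALSE]
  test <- n_mat[test_idx, , drop = FALSE]
  grid <- purrr::map_dfr(sort(unique(k_grid)), function(k) {
    fit <- lda_vem(train, k,
      max_iter = max_iter, n_restarts = n_restarts,
      seed = derive_seed(seed, paste0("lda_k", k))
    )
    tibble::tibble(
      K = k,
      perplexity = lda_perplexity(test, fit),
      min_topic_mean = min(colMeans(fit$theta)),
      rare = min(colMeans(fit$theta)) < rare_topic
    )
  })
  eligible <- if (all(grid$rare)) grid else grid[!grid$rare, , drop = FALSE]
  k_best <- eligible$K[which.min(eligible$perplexity)]
  fit <- lda_vem(n_mat, k_best,
    max_iter = max_iter, n_restarts = n_restarts,
    seed = derive_seed(seed, paste0("lda_k", k_best))
  )
  props <- dplyr::mutate(
    tidyr::pivot_longer(
      dplyr::bind_cols(b$meta[, c("sample_id", "barcode")], tibble::as_tibble(fit$theta)),
      -c("sample_id", "barcode"),
      names_to = "cell_type", values_to = "proportion"
    )
  )
  structure(
    list(
      proportions = props, theta = fit$theta, topic_profiles = fit$beta,
      K = k_best, perplexity_by_k = grid, bound = fit$bound, genes = genes
    ),
    class = "spot_deconvolution"
  )
}

#' @export
print.spot_deconvolution <- function(x, ...) {
  cat(
    "<spot_deconvolution> K = ", x$K, " topics over ", nrow(x$theta),
    " spots, ", length(x$genes), " genes\n",
    sep = ""
  )
  invisible(x)
}

#' Match topics to reference profiles
#'
#' Finds the topic-to-cell-type assignment maximising the total Pearson
#' correlation between topic gene profiles and reference profiles (Hungarian
#' algorithm when the `clue` package is available, else exhaustive search for
#' small K).
#'
#' @param decon A `spot_deconvolution`.
#' @param profiles Reference cell-type x gene rate matrix.
#' @return Tibble: `cell_type` (topic id), `matched_type`, `r`.
#' @export
match_topics <- function(decon, profiles) {
  genes <- intersect(colnames(decon$topic_profiles), colnames(profiles))
  a <- decon$topic_profiles[, genes, drop = FALSE]
  bm <- profiles[, genes, drop = FALSE]
  cm <- cor(t(a), t(bm))          # topics x ref types
  k <- nrow(cm)
  m <- ncol(cm)
  if (requireNamespace("clue", quietly = TRUE)) {
    if (k <= m) {
      sol <- as.integer(clue::solve_LSAP(pmax(cm, -1) + 1, maximum = TRUE))
    } else {
      sol_t <- as.integer(clue::solve_LSAP(t(pmax(cm, -1) + 1), maximum = TRUE))
      sol <- rep(NA_integer_, k)
      sol[sol_t] <- seq_len(m)
    }
  } else {
    stopifnot(k <= 8)
    perms <- gtools_permutations(m, k)
    best <- which.max(apply(perms, 1, function(p) sum(cm[cbind(seq_len(k), p)])))
    sol <- perms[best, ]
  }
  tibble::tibble(
    cell_type = rownames(cm),
    matched_type = colnames(cm)[sol],
    r = cm[cbind(seq_len(k), sol)]
  )
}

# All injective assignments of k slots into m items (k <= m). Small sizes only.
gtools_permutations <- function(m, k) {
  idx <- seq_len(m)
  rec <- function(chosen) {
    if (length(chosen) == k) return(matrix(chosen, nrow = 1))
    do.call(rbind, lapply(setdiff(idx, chosen), function(i) rec(c(chosen, i))))
  }
  rec(integer(0))
}
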