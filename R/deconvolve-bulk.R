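#' Simulate a reference methylation atlas
#'
#' Builds a cell-type x probe matrix of mean betas in which each cell type
#' owns a block of discriminating probes that are highly methylated in that
#' type and lowly methylated elsewhere, plus shared non-discriminating probes.
#' Used as the reference for [deconvolve_bulk()].
#'
#' @param n_celltypes Number of cell types (>= 2).
#' @param n_disc Discriminating probes per cell type.
#' @param n_shared Shared background probes.
#' @param profiles Optional pre-made cell-type x probe beta matrix; when given,
#'   discriminating probes are detected as those with beta range > 0.5.
#' @param seed Integer seed.
#' @return A list of class `reference_atlas`: `profiles` (cell type x probe
#'   betas) and `discriminating` (tibble `cell_type`, `probe_id`).
#' @export
simulate_atlas <- function(n_celltypes = 5, n_disc = 40, n_shared = 100,
                           profiles = NULL, seed = 1) {
  if (is.null(profiles)) {
    n_celltypes <- check_scalar_int(n_celltypes, "n_celltypes", min = 2L)
    with_seed(seed, {
      types <- sprintf("type%02d", seq_len(n_celltypes))
      n_probes <- n_celltypes * n_disc + n_shared
      probes <- sprintf("ref%05d", seq_len(n_probes))
      prof <- matrix(
        rbeta(n_celltypes * n_probes, 5, 5), n_celltypes, n_probes,
        dimnames = list(types, probes)
      )
      disc <- list()
      for (k in seq_len(n_celltypes)) {
        idx <- ((k - 1) * n_disc + 1):(k * n_disc)
        prof[, idx] <- runif(n_celltypes * n_disc, 0.05, 0.2)
        prof[k, idx] <- runif(n_disc, 0.8, 0.95)
        disc[[k]] <- tibble::tibble(cell_type = types[k], probe_id = probes[idx])
      }
      profiles <- prof
      discriminating <- dplyr::bind_rows(disc)
    })
  } else {
    if (nrow(profiles) < 2) abort("Need at least 2 cell types.")
    rng <- apply(profiles, 2, function(x) max(x) - min(x))
    discriminating <- purrr::map_dfr(rownames(profiles), function(ct) {
      hit <- which(rng > 0.5 & profiles[ct, ] == apply(profiles, 2, max))
      tibble::tibble(cell_type = ct, probe_id = colnames(profiles)[hit])
    })
  }
  if (any(profiles <= 0) || any(profiles >= 1)) {
    profiles <- pmin(pmax(profiles, 1e-3), 1 - 1e-3)
  }
  if (any(!nzchar(discriminating$probe_id)) || nrow(discriminating) == 0) {
    abort("Atlas has no discriminating probes.")
  }
  structure(
    list(profiles = profiles, discriminating = discriminating),
    class = "reference_atlas"
  )
}

#' Simulate bulk methylomes as planted cell-type mixtures
#'
#' Mixes atlas cell-type profiles with given proportions (betas mix linearly
#' in cell fractions), then adds Gaussian noise on the M scale.
#'
#' @param atlas A `reference_atlas`.
#' @param proportions Sample x cell-type matrix of mixing fractions (rows on
#'   the simplex); when `NULL`, `n_samples` Dirichlet(1) rows are drawn.
#' @param n_samples Number of samples when `proportions` is NULL.
#' @param sigma_m Noise SD on the M scale.
#' @param seed Integer seed.
#' @return A list: `data` (a [meth_dataset()], all samples labelled control)
#'   and `truth` (the proportion matrix used).
#' @export
simulate_bulk_mixture <- function(atlas, proportions = NULL, n_samples = 20,
                                  sigma_m = 0.3, seed = 1) {
  with_seed(seed, {
    k <- nrow(atlas$profiles)
    if (is.null(proportions)) {
      g <- matrix(rexp(n_samples * k), n_samples, k)
      proportions <- g / rowSums(g)
      dimnames(proportions) <- list(
        sprintf("mix%02d", seq_len(n_samples)), rownames(atlas$profiles)
      )
    }
    clean <- proportions %*% atlas$profiles          # samples x probes
    noisy <- m_to_beta(
      beta_to_m(t(clean)) + rnorm(length(clean), 0, sigma_m)
    )
    probe_map <- tibble::tibble(
      probe_id = colnames(atlas$profiles), chrom = "chrA",
      pos = seq_len(ncol(atlas$profiles)) * 100L
    )
    samples <- tibble::tibble(
      sample_id = rownames(proportions), group = "control"
    )
    list(
      data = meth_dataset(noisy, probe_map, samples),
      truth = proportions
    )
  })
}

#' Reference-based deconvolution of bulk methylomes
#'
#' Per sample, constrained least squares of observed betas on the atlas
#' cell-type profiles over the union of discriminating probes, with
#' non-negativity and sum-to-one constraints (solved as a quadratic program).
#'
#' @param data A [meth_dataset()].
#' @param atlas A `reference_atlas` from [simulate_atlas()] (or equivalent).
#' @return A list of class `bulk_deconvolution`: `proportions` (tibble, one
#'   row per sample x cell type) and `residuals` (per-sample residual norm).
#' @export
deconvolve_bulk <- function(data, atlas) {
  stopifnot(inherits(data, "meth_dataset"))
  probes <- intersect(unique(atlas$discriminating$probe_id), rownames(data$betas))
  if (length(probes) == 0) abort("No discriminating atlas probe present in the data.")
  a <- t(atlas$profiles[, probes, drop = FALSE])     # probes x K
  k <- ncol(a)
  dmat <- crossprod(a) + diag(1e-10, k)
  amat <- cbind(rep(1, k), diag(k))
  bvec <- c(1, rep(0, k))
  res <- purrr::map(colnames(data$betas), function(s) {
    b <- data$betas[probes, s]
    sol <- quadprog::solve.QP(dmat, crossprod(a, b), amat, bvec, meq = 1)
    w <- pmax(sol$solution, 0)
    w <- w / sum(w)
    list(w = w, resid = sqrt(sum((a %*% w - b)^2)))
  })
  props <- purrr::map_dfr(seq_along(res), function(i) {
    tibble::tibble(
      sample_id = colnames(data$betas)[i],
      cell_type = colnames(a),
      proportion = res[[i]]$w
    )
  })
  structure(
    list(
      proportions = props,
      residuals = tibble::tibble(
        sample_id = colnames(data$betas),
        residual = purrr::map_dbl(res, "resid")
      )
    ),
    class = "bulk_deconvolution"
  )
}

#' @export
print.bulk_deconvolution <- function(x, ...) {
  cat(
    "<bulk_deconvolution> ", dplyr::n_distinct(x$proportions$sample_id),
    " samples x ", dplyr::n_distinct(x$proportions$cell_type), " cell types\n",
    sep = ""
  )
  invisible(x)
}
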