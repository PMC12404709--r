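#' Simulate a bulk methylation cohort with planted DMRs
#'
#' Generates an array-style beta matrix for a two-group design (control vs
#' irradiated) with planted differentially methylated regions, optional
#' confounding covariates, and probe-specific Gaussian noise added on the
#' M-scale (logit2 of beta) and mapped back, mirroring the heteroscedastic
#' variance of beta values.
#'
#' Planted DMRs are runs of 3-10 consecutive probes whose irradiated-group
#' betas are shifted by a draw from `delta_beta_range`; the shift is
#' hypomethylating with probability `frac_hypo` (default 0.75, the
#' hypomethylation bias the analysis is designed to detect). Baselines inside
#' planted runs are placed away from the boundaries so the planted shift is
#' realised without clipping.
#'
#' @param annotation Feature tibble from [simulate_annotation()].
#' @param n_probes Number of probes tiled over the chromosome.
#' @param n_per_group Integer pair: samples in (control, RT).
#' @param n_dmrs Number of planted DMRs (may be 0).
#' @param frac_hypo Probability a planted DMR is hypomethylated.
#' @param delta_beta_range Length-2 numeric; planted |delta beta| drawn
#'   uniformly from this interval (use `c(0, 0)` for a pure null).
#' @param covariate_spec Named list; each element a list with fields
#'   `values` (optional function(n) returning sample values; default standard
#'   normal), `effect_sd` (per-probe effect SD on the M-scale, default 0),
#'   `frac_probes` (fraction of probes the covariate affects, default 0.1) and
#'   `group_shift` (mean difference RT minus control in the covariate itself,
#'   creating confounding; default 0).
#' @param sigma_m_range Per-probe noise SD on the M-scale, drawn uniformly.
#' @param seed Integer seed.
#' @return A list with elements `data` (a [meth_dataset()]) and `truth` (a
#'   list with `dmr_truth`, a tibble of planted intervals with direction,
#'   delta beta, probe ids, region class and gene assignment).
#' @export
simulate_methylation <- function(annotation, n_probes, n_per_group = c(12, 14),
                                 n_dmrs = 0, frac_hypo = 0.75,
                                 delta_beta_range = c(0.15, 0.3),
                                 covariate_spec = NULL,
                                 sigma_m_range = c(0.2, 0.4), seed = 1) {
  n_probes <- check_scalar_int(n_probes, "n_probes", min = 10L)
  n_dmrs <- check_scalar_int(n_dmrs, "n_dmrs", min = 0L)
  frac_hypo <- check_proportion(frac_hypo, "frac_hypo")
  stopifnot(length(n_per_group) == 2, length(delta_beta_range) == 2)
  chrom_len <- max(annotation$end)
  with_seed(seed, {
    # planted DMR windows first, then probes: each planted region is a run of
    # 3-10 tightly spaced probes inside its own window; background probes fill
    # the rest of the chromosome (with a small buffer so planted regions never
    # merge with their surroundings)
    run_lens <- if (n_dmrs > 0) sample(3:10, n_dmrs, replace = TRUE) else integer(0)
    if (sum(run_lens) + n_dmrs > n_probes) {
      abort("`n_probes` too small to host `n_dmrs` non-overlapping runs.")
    }
    win_len <- run_lens * 300L + 200L
    buffer <- 600L
    win_start <- integer(0)
    if (n_dmrs > 0) {
      # one window per equal-width stratum, at a random offset: spreads the
      # planted regions over the whole chromosome and guarantees separation
      stratum <- (chrom_len - buffer) %/% n_dmrs
      if (stratum < max(win_len) + buffer) {
        abort("Chromosome too short to host `n_dmrs` non-overlapping regions.")
      }
      offsets <- vapply(seq_len(n_dmrs), function(i) {
        sample.int(stratum - win_len[i] - buffer, 1L)
      }, integer(1))
      win_start <- (seq_len(n_dmrs) - 1L) * stratum + offsets
    }
    planted_pos <- purrr::map2(win_start, run_lens, function(s, len) {
      s + cumsum(sample(80:250, len, replace = TRUE))
    })
    in_window <- function(p) {
      if (n_dmrs == 0) return(rep(FALSE, length(p)))
      hit <- rep(FALSE, length(p))
      for (i in seq_len(n_dmrs)) {
        hit <- hit | (p >= win_start[i] - buffer & p <= win_start[i] + win_len[i] + buffer)
      }
      hit
    }
    n_bg <- n_probes - sum(run_lens)
    bg <- integer(0)
    while (length(bg) < n_bg) {
      draw <- sample.int(chrom_len - 1L, min(2L * n_bg, chrom_len - 1L))
      draw <- draw[!in_window(draw)]
      bg <- unique(c(bg, draw))
    }
    bg <- bg[seq_len(n_bg)]
    pos <- sort(c(bg, unlist(planted_pos)))
    probe_id <- sprintf("cg%06d", seq_len(n_probes))
    n1 <- as.integer(n_per_group[1])
    n2 <- as.integer(n_per_group[2])
    samples <- tibble::tibble(
      sample_id = c(sprintf("ctl%02d", seq_len(n1)), sprintf("rt%02d", seq_len(n2))),
      group = rep(c("control", "RT"), c(n1, n2))
    )
    n <- n1 + n2

    # bimodal baseline typical of array betas
    comp <- sample.int(3L, n_probes, replace = TRUE, prob = c(0.4, 0.4, 0.2))
    base_beta <- c(
      rbeta(n_probes, 2, 10), rbeta(n_probes, 10, 2), rbeta(n_probes, 4, 4)
    )[seq_len(n_probes) + (comp - 1L) * n_probes]
    base_beta <- pmin(pmax(base_beta, 0.03), 0.97)

    # apply planted effects on the probes of each planted window
    dmr_truth <- tibble::tibble(
      dmr_id = character(), chrom = character(), start = integer(),
      end = integer(), direction = character(), delta_beta = numeric(),
      probe_ids = list(), probe_idx = list()
    )
    effect_beta <- rep(0, n_probes)
    if (n_dmrs > 0) {
      rows <- vector("list", n_dmrs)
      for (i in seq_len(n_dmrs)) {
        idx <- match(planted_pos[[i]], pos)
        dir <- if (runif(1) < frac_hypo) "hypo" else "hyper"
        db <- runif(1, delta_beta_range[1], delta_beta_range[2])
        # baseline with headroom for the shift
        base_beta[idx] <- if (dir == "hypo") {
          runif(length(idx), 0.55, 0.9)
        } else {
          runif(length(idx), 0.1, 0.45)
        }
        effect_beta[idx] <- if (dir == "hypo") -db else db
        rows[[i]] <- tibble::tibble(
          dmr_id = sprintf("planted%04d", i), chrom = "chr1",
          start = min(pos[idx]), end = max(pos[idx]) + 1L,
          direction = dir, delta_beta = db,
          probe_ids = list(probe_id[idx]), probe_idx = list(idx)
        )
      }
      dmr_truth <- dplyr::bind_rows(rows)
    }

    # covariates: sample values, optional group confounding, per-probe effects
    cov_effects <- matrix(0, n_probes, n)
    for (nm in names(covariate_spec)) {
      spec <- covariate_spec[[nm]]
      vals <- if (!is.null(spec$values)) spec$values(n) else rnorm(n)
      shift <- spec$group_shift %||% 0
      vals <- vals + shift * (samples$group == "RT")
      samples[[nm]] <- vals
      esd <- spec$effect_sd %||% 0
      if (esd > 0) {
        frac <- spec$frac_probes %||% 0.1
        hit <- runif(n_probes) < frac
        eff <- rnorm(n_probes, 0, esd) * hit
        cov_effects <- cov_effects + outer(eff, vals)
      }
    }

    m_base <- beta_to_m(base_beta)
    m_shift <- beta_to_m(pmin(pmax(base_beta + effect_beta, 0.02), 0.98)) - m_base
    sigma_m <- runif(n_probes, sigma_m_range[1], sigma_m_range[2])
    noise <- matrix(rnorm(n_probes * n, 0, sigma_m), n_probes, n)
    m <- m_base + outer(m_shift, as.numeric(samples$group == "RT")) +
      cov_effects + noise
    betas <- m_to_beta(m)
    dimnames(betas) <- list(probe_id, samples$sample_id)
    probe_map <- tibble::tibble(probe_id = probe_id, chrom = "chr1", pos = pos)
    data <- meth_dataset(betas, probe_map, samples)

    # annotate planted intervals the same way DMRs are annotated downstream
    if (nrow(dmr_truth) > 0) {
      ann_t <- classify_intervals(
        dplyr::select(dmr_truth, "dmr_id", "chrom", "start", "end"),
        annotation
      )
      dmr_truth <- dplyr::left_join(
        dmr_truth, dplyr::select(ann_t, "dmr_id", "region_class", "gene_ids"),
        by = "dmr_id"
      )
      gt <- gene_table(annotation)
      dmr_truth$gene_id <- purrr::map2_chr(
        dmr_truth$gene_ids, seq_len(nrow(dmr_truth)),
        function(gs, i) {
          if (length(gs) > 0) return(gs[[1]])
          nearest_gene(dmr_truth$start[i], dmr_truth$end[i], gt, max_dist = 10000L)
        }
      )
    }
    list(data = data, truth = list(dmr_truth = dmr_truth))
  })
}
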