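#' Default pipeline configuration
#'
#' All stage parameters with their defaults. Unknown keys passed to
#' [run_pipeline()] are rejected. Sizes are chosen so a full simulated run
#' finishes in a few minutes on one CPU.
#'
#' @return Named list of parameters.
#' @export
default_config <- function() {
  list(
    n_genes = 120, n_te = 40,
    n_probes = 8000, n_dmrs = 60, frac_hypo = 0.75,
    delta_beta_range = c(0.15, 0.3), meth_n_per_group = c(12, 14),
    covariate_spec = list(
      age = list(effect_sd = 0.15, frac_probes = 0.1),
      sex = list(
        values = function(n) rbinom(n, 1, 0.5),
        effect_sd = 0.15, frac_probes = 0.1
      )
    ),
    dmp_covariates = c("age", "sex"),
    q_thresh = 0.05, maxgap_bp = 1000, min_probes = 3,
    expr_n_per_group = c(10, 10), n_deg_only = 30,
    spatial_samples = c(ctl1 = "control", rt1 = "RT"),
    grid = c(16, 16), lda_k_grid = 2:5,
    min_counts = 100, min_genes = 20,
    cluster_resolution = 1, cluster_k = 15, n_hvg = 2000, n_pcs = 30,
    n_rl_pairs = 40, rl_q_thresh = 0.05,
    signature_k = 200
  )
}

#' Run the full simulated analysis pipeline
#'
#' Orchestrates simulate -> methylome -> integration -> spatial -> R-L as one
#' configured run: generates every input with planted truth, calls DMPs and
#' DMRs, annotates and enriches them, maps DMGs, calls DEGs, evaluates the
#' concordance rule, builds the methylation signature, clusters and
#' deconvolves the spatial spots, scores the signature on spots, and tests
#' directional R-L interactions between conditions. All per-stage randomness
#' derives from `seed` via [derive_seed()], so the report is reproducible.
#'
#' @param config Named list overriding entries of [default_config()].
#' @param seed Global integer seed.
#' @param outdir Optional directory; when given, stage tables are written as
#'   TSV/JSON there.
#' @return A list of class `run_report` with per-stage headline counts,
#'   the seed, and wall time; the full stage outputs are attached in
#'   `$results`.
#' @export
run_pipeline <- function(config = list(), seed = 1, outdir = NULL) {
  t0 <- Sys.time()
  cfg <- default_config()
  unknown <- setdiff(names(config), names(cfg))
  if (length(unknown) > 0) {
    abort(paste("Unknown config keys:", paste(unknown, collapse = ", ")))
  }
  cfg[names(config)] <- config

  ann <- simulate_annotation(cfg$n_genes, cfg$n_te, seed = derive_seed(seed, "annotation"))
  sim_m <- simulate_methylation(
    ann, cfg$n_probes,
    n_per_group = cfg$meth_n_per_group, n_dmrs = cfg$n_dmrs,
    frac_hypo = cfg$frac_hypo, delta_beta_range = cfg$delta_beta_range,
    covariate_spec = cfg$covariate_spec, seed = derive_seed(seed, "methylation")
  )
  dmps <- call_dmps(sim_m$data, covariates = cfg$dmp_covariates)
  dmrs <- call_dmrs(dmps,
    q_thresh = cfg$q_thresh, maxgap_bp = cfg$maxgap_bp,
    min_probes = cfg$min_probes
  )
  ann_dmrs <- annotate_dmrs(dmrs, ann)
  loc <- dmr_location_table(ann_dmrs, sim_m$data$probe_map, ann)
  enr <- region_enrichment(loc)
  dmgs <- map_dmgs(ann_dmrs, ann)

  sim_e <- simulate_expression(
    sim_m$truth, ann,
    n_per_group = cfg$expr_n_per_group, n_deg_only = cfg$n_deg_only,
    seed = derive_seed(seed, "expression")
  )
  degs <- call_degs(sim_e$counts, sim_e$samples)
  overlap <- overlap_dmg_deg(dmgs, degs, q_thresh = cfg$q_thresh)
  conc <- classify_concordance(dmgs, degs, q_thresh = cfg$q_thresh)
  signature <- suppressWarnings(build_methylation_signature(dmgs, k = cfg$signature_k))

  rl_pairs <- simulate_rl_pairs(
    sprintf("g%04d", seq_len(300)),
    n_pairs = cfg$n_rl_pairs, seed = derive_seed(seed, "rl_pairs")
  )
  planted_rl <- dplyr::mutate(
    head(rl_pairs, 5),
    sender_niche = "neuron", receiver_niche = "neuron", multiplier = 3
  )
  sim_s <- simulate_spatial(
    samples = cfg$spatial_samples, grid = cfg$grid,
    rl_truth = planted_rl, seed = derive_seed(seed, "spatial")
  )
  qc <- qc_filter_spots(sim_s$datasets, cfg$min_counts, cfg$min_genes)
  labels <- cluster_spots(
    qc$datasets,
    n_hvg = cfg$n_hvg, n_pcs = cfg$n_pcs, k = cfg$cluster_k,
    resolution = cfg$cluster_resolution, seed = derive_seed(seed, "cluster")
  )
  decon <- deconvolve_spots(qc$datasets,
    k_grid = cfg$lda_k_grid,
    seed = derive_seed(seed, "lda")
  )
  sig_scores <- suppressWarnings(score_signature(
    qc$datasets, sim_s$truth$neuropeptide_genes,
    seed = derive_seed(seed, "score")
  ))
  sig_cor <- correlate_signature_proportions(sig_scores, decon, "neuropeptide")

  rl_sc <- interaction_scores(qc$datasets, rl_pairs, labels)
  rl_res <- compare_conditions(rl_sc)
  rl_counts <- count_significant(rl_res, q_thresh = cfg$rl_q_thresh)

  report <- structure(
    list(
      seed = seed,
      config = cfg,
      counts = list(
        probes = nrow(sim_m$data$betas),
        dmps_q05 = sum(dmps$q < cfg$q_thresh),
        dmrs = nrow(dmrs),
        pct_hypo = if (nrow(dmrs) > 0) 100 * mean(dmrs$direction == "hypo") else NA_real_,
        dmgs = dplyr::n_distinct(dmgs$gene_id),
        degs = sum(degs$q < cfg$q_thresh),
        overlap = length(overlap),
        concordant = length(concordant_genes(conc)),
        spots_kept = sum(qc$report$n_kept),
        clusters = dplyr::n_distinct(labels$cluster),
        lda_k = decon$K,
        rl_tested = nrow(rl_res),
        rl_significant = sum(rl_res$q < cfg$rl_q_thresh)
      ),
      wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
      results = list(
        annotation = ann, meth = sim_m, dmps = dmps, dmrs = ann_dmrs,
        location_table = loc, enrichment = enr, dmgs = dmgs,
        expression = sim_e, degs = degs, overlap = overlap,
        concordance = conc, signature = signature,
        spatial = sim_s, qc_report = qc$report, labels = labels,
        deconvolution = decon, signature_scores = sig_scores,
        signature_correlation = sig_cor, rl_results = rl_res,
        rl_counts = rl_counts
      )
    ),
    class = "run_report"
  )
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  r <- report$results
  readr::write_tsv(r$dmps, file.path(outdir, "dmps.tsv"))
  readr::write_tsv(
    dplyr::mutate(r$dmrs,
      probe_ids = purrr::map_chr(.data$probe_ids, paste, collapse = ";"),
      gene_ids = purrr::map_chr(.data$gene_ids, paste, collapse = ";")
    ),
    file.path(outdir, "dmrs.tsv")
  )
  readr::write_tsv(r$location_table, file.path(outdir, "location_table.tsv"))
  readr::write_tsv(r$enrichment, file.path(outdir, "enrichment.tsv"))
  readr::write_tsv(r$dmgs, file.path(outdir, "dmgs.tsv"))
  readr::write_tsv(r$degs, file.path(outdir, "degs.tsv"))
  readr::write_tsv(r$concordance, file.path(outdir, "concordance.tsv"))
  readr::write_tsv(r$labels, file.path(outdir, "labels.tsv"))
  readr::write_tsv(r$deconvolution$proportions, file.path(outdir, "proportions.tsv"))
  readr::write_tsv(r$signature_scores, file.path(outdir, "signature_scores.tsv"))
  readr::write_tsv(r$rl_results, file.path(outdir, "rl_results.tsv"))
  readr::write_tsv(r$rl_counts$counts, file.path(outdir, "chords.tsv"))
  jsonlite::write_json(
    c(list(seed = report$seed), report$counts),
    file.path(outdir, "run_report.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(outdir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> seed ", x$seed, "\n", sep = "")
  cnt <- x$counts
  for (nm in names(cnt)) {
    cat(sprintf("  %-14s %s\n", nm, format(cnt[[nm]], digits = 4)))
  }
  invisible(x)
}
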