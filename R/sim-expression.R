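# Default region-dependent coupling between methylation and expression:
# -1 = anti-correlated (promoter/5'UTR/exon), +1 = correlated
# (3'UTR/intron/intergenic), 0 = uncoupled (TE).
default_coupling <- c(
  promoter = -1, utr5 = -1, exon = -1,
  utr3 = 1, intron = 1, intergenic = 1, TE = 0
)

#' Simulate a bulk expression cohort coupled to planted methylation truth
#'
#' Negative-binomial counts for every annotated gene in a two-group design.
#' Genes carrying a planted DMR get a log2 fold change whose sign is
#' `coupling[region_class] * methyl_sign` (methyl_sign: hyper = +1,
#' hypo = -1), so with the default coupling a promoter-hypomethylated gene is
#' up-regulated and an intron-hypomethylated gene is down-regulated — the
#' planted set is concordant by construction. Two decoy sets give the
#' concordance stage true negatives: `n_deg_only` genes with an expression
#' shift but no methylation change, and (when `coupling_frac < 1`) DMR genes
#' left without any expression shift.
#'
#' @param truth Planted-truth list from [simulate_methylation()].
#' @param annotation Feature tibble.
#' @param n_per_group Integer pair (control, RT).
#' @param coupling Named numeric map region class -> sign in `{-1, 0, 1}`.
#' @param coupling_frac Fraction of DMR genes that receive the coupled
#'   expression shift; the rest are methylation-only decoys.
#' @param lfc_range Magnitude range of planted |log2 fold change|.
#' @param n_deg_only Number of expression-only decoy genes.
#' @param nb_dispersion Negative-binomial dispersion (1/size).
#' @param seed Integer seed.
#' @return A list: `counts` (gene x sample integer matrix), `samples`
#'   (tibble), `truth` (list with `deg_truth` — gene, planted log2 fold
#'   change — and `concordant_truth` — gene, region_class, methyl_direction,
#'   expr_direction).
#' @export
simulate_expression <- function(truth, annotation, n_per_group = c(10, 10),
                                coupling = default_coupling,
                                coupling_frac = 1, lfc_range = c(1, 2),
                                n_deg_only = 30, nb_dispersion = 0.1,
                                seed = 1) {
  if (!all(names(default_coupling) %in% names(coupling))) {
    abort("`coupling` must name all seven region classes.")
  }
  if (!all(names(coupling) %in% names(default_coupling))) {
    abort(paste(
      "Unknown region class in `coupling`:",
      paste(setdiff(names(coupling), names(default_coupling)), collapse = ", ")
    ))
  }
  dmr_truth <- truth$dmr_truth
  with_seed(seed, {
    genes <- sort(unique(annotation$gene_id[!is.na(annotation$gene_id)]))
    n1 <- as.integer(n_per_group[1])
    n2 <- as.integer(n_per_group[2])
    samples <- tibble::tibble(
      sample_id = c(sprintf("ectl%02d", seq_len(n1)), sprintf("ert%02d", seq_len(n2))),
      group = rep(c("control", "RT"), c(n1, n2))
    )
    base_mu <- exp(rnorm(length(genes), 4, 1.2))
    names(base_mu) <- genes

    lfc <- setNames(rep(0, length(genes)), genes)
    concordant <- NULL
    dmr_genes <- dmr_truth[!is.na(dmr_truth$gene_id), , drop = FALSE]
    if (nrow(dmr_genes) > 0) {
      # only genes hosting exactly one planted DMR are eligible for coupling,
      # so every planted concordant gene has one coherent (region, direction);
      # genes with several planted DMRs stay expression-neutral decoys
      single <- names(which(table(dmr_genes$gene_id) == 1))
      per_gene <- dmr_genes[dmr_genes$gene_id %in% single, , drop = FALSE]
      coupled <- runif(nrow(per_gene)) < coupling_frac
      msign <- ifelse(per_gene$direction == "hyper", 1, -1)
      esign <- coupling[per_gene$region_class] * msign * coupled
      mag <- runif(nrow(per_gene), lfc_range[1], lfc_range[2])
      lfc[per_gene$gene_id] <- esign * mag
      concordant <- tibble::tibble(
        gene_id = per_gene$gene_id,
        region_class = per_gene$region_class,
        methyl_direction = per_gene$direction,
        expr_direction = ifelse(esign > 0, "up", ifelse(esign < 0, "down", "none"))
      )
      concordant <- dplyr::filter(concordant, .data$expr_direction != "none")
    }
    decoy_pool <- setdiff(genes, dmr_genes$gene_id)
    deg_only <- sort(sample(decoy_pool, min(n_deg_only, length(decoy_pool))))
    lfc[deg_only] <- sample(c(-1, 1), length(deg_only), replace = TRUE) *
      runif(length(deg_only), lfc_range[1], lfc_range[2])

    libf <- runif(n1 + n2, 0.7, 1.3)
    mu <- outer(base_mu, libf) *
      2^outer(lfc, as.numeric(samples$group == "RT"))
    counts <- matrix(
      rnbinom(length(mu), mu = mu, size = 1 / nb_dispersion),
      nrow = length(genes),
      dimnames = list(genes, samples$sample_id)
    )
    list(
      counts = counts, samples = samples,
      truth = list(
        deg_truth = tibble::tibble(gene_id = genes, log_fc = unname(lfc)),
        concordant_truth = concordant %||%
          tibble::tibble(
            gene_id = character(), region_class = character(),
            methyl_direction = character(), expr_direction = character()
          ),
        deg_only = deg_only
      )
    )
  })
}
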