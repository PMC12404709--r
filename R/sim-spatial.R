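# Default niche archetypes over 5 cell types: a neuron-dominated niche, a
# glia-dominated niche, and a mixed immune/vascular niche.
default_archetypes <- function(types) {
  k <- length(types)
  arch <- rbind(
    neuron = c(0.70, 0.15, 0.05, 0.05, 0.05),
    glia = c(0.05, 0.50, 0.30, 0.10, 0.05),
    immune_vasc = c(0.05, 0.15, 0.10, 0.35, 0.35)
  )[, seq_len(k), drop = FALSE]
  arch <- arch / rowSums(arch)
  colnames(arch) <- types
  arch
}

#' Simulate cell-type expression profiles
#'
#' Each cell type gets a block of exclusive marker genes up-weighted over a
#' shared baseline; rows are normalised to multinomial rates.
#'
#' @param n_celltypes,n_genes,n_markers Sizes.
#' @param marker_fold Up-weighting of a type's own markers.
#' @param seed Integer seed.
#' @return Cell type x gene rate matrix (rows sum to 1).
#' @export
simulate_celltype_profiles <- function(n_celltypes = 5, n_genes = 300,
                                       n_markers = 30, marker_fold = 10,
                                       seed = 1) {
  with_seed(seed, {
    types <- sprintf("ct%02d", seq_len(n_celltypes))
    genes <- sprintf("g%04d", seq_len(n_genes))
    prof <- matrix(
      rexp(n_celltypes * n_genes, 1), n_celltypes, n_genes,
      dimnames = list(types, genes)
    )
    for (k in seq_len(n_celltypes)) {
      idx <- ((k - 1) * n_markers + 1):(k * n_markers)
      idx <- idx[idx <= n_genes]
      prof[k, idx] <- prof[k, idx] * marker_fold
    }
    prof / rowSums(prof)
  })
}

#' Simulate spatial transcriptomics samples with planted niches
#'
#' Spots live on a hexagonal grid with integer axial coordinates. Each sample
#' is partitioned into spatially contiguous niche blocks (nearest-seed
#' assignment in hex space); each spot draws a cell-type proportion vector
#' from a Dirichlet centred on its niche archetype, and counts are Poisson
#' with expectation depth x (proportions x cell-type profiles). In irradiated
#' samples, `neuropeptide_genes` are up-scaled in spots of `neuro_niche`, and
#' each row of `rl_truth` up-scales its ligand genes in sender-niche spots and
#' receptor genes in receiver-niche spots.
#'
#' @param samples Named character vector: sample id -> `"control"`/`"RT"`.
#' @param celltype_profiles Cell type x gene rate matrix (rows sum to 1);
#'   default from [simulate_celltype_profiles()].
#' @param niche_archetypes Niche x cell-type simplex matrix; default three
#'   niches (neuron / glia / immune-vascular).
#' @param grid Integer pair (rows, cols) of the hex grid.
#' @param depth Expected counts per spot.
#' @param concentration Dirichlet concentration around the archetype.
#' @param seeds_per_niche Seed points per niche per sample (spatial blocks).
#' @param neuropeptide_genes Genes up-scaled in RT neuronal niches.
#' @param neuro_fold Fold change applied to `neuropeptide_genes`.
#' @param neuro_niche Niche receiving the neuropeptide effect.
#' @param rl_truth Optional tibble: `pair_id`, `ligand` (list or ";"-joined),
#'   `receptor`, `sender_niche`, `receiver_niche`, `multiplier`.
#' @param seed Integer seed.
#' @return List: `datasets` (list of [spatial_dataset()]) and `truth` (list
#'   with `niche_map`, `proportions` (long tibble), `celltype_profiles`,
#'   `niche_archetypes`, `neuropeptide_genes`, `rl_truth`).
#' @export
simulate_spatial <- function(samples = c(ctl1 = "control", rt1 = "RT"),
                             celltype_profiles = NULL,
                             niche_archetypes = NULL,
                             grid = c(20, 20), depth = 1000,
                             concentration = 5, seeds_per_niche = 2,
                             neuropeptide_genes = NULL, neuro_fold = 3,
                             neuro_niche = "neuron",
                             rl_truth = NULL, seed = 1) {
  if (is.null(celltype_profiles)) {
    celltype_profiles <- simulate_celltype_profiles(seed = derive_seed(seed, "profiles"))
  }
  types <- rownames(celltype_profiles)
  if (is.null(niche_archetypes)) niche_archetypes <- default_archetypes(types)
  if (any(abs(rowSums(niche_archetypes) - 1) > 1e-9) || any(niche_archetypes < 0)) {
    abort("`niche_archetypes` rows must lie on the simplex.")
  }
  niches <- rownames(niche_archetypes)
  genes <- colnames(celltype_profiles)
  if (is.null(neuropeptide_genes) && neuro_niche %in% niches) {
    neuropeptide_genes <- head(genes, 5)
  }
  with_seed(seed, {
    rows <- grid[1]
    cols <- grid[2]
    pos <- tidyr::expand_grid(array_row = seq_len(rows) - 1L, array_col = seq_len(cols) - 1L)
    pos$barcode <- sprintf("s%03d_%03d", pos$array_row, pos$array_col)
    # cartesian coordinates of axial hex centres, for contiguity
    hx <- pos$array_col + pos$array_row / 2
    hy <- pos$array_row * sqrt(3) / 2

    datasets <- list()
    niche_map <- list()
    prop_truth <- list()
    for (s in names(samples)) {
      cond <- samples[[s]]
      n_spots <- nrow(pos)
      seed_idx <- sample.int(n_spots, length(niches) * seeds_per_niche)
      seed_niche <- rep(niches, seeds_per_niche)
      d2 <- outer(hx, hx[seed_idx], "-")^2 + outer(hy, hy[seed_idx], "-")^2
      spot_niche <- seed_niche[apply(d2, 1, which.min)]
      alpha <- niche_archetypes[spot_niche, , drop = FALSE] * concentration
      g <- matrix(
        stats::rgamma(n_spots * length(types), shape = alpha),
        n_spots, length(types)
      )
      props <- g / rowSums(g)
      colnames(props) <- types
      mu <- depth * (props %*% celltype_profiles)   # spots x genes
      if (cond == "RT") {
        np <- intersect(neuropeptide_genes, genes)
        hit <- spot_niche == neuro_niche
        if (length(np) > 0 && any(hit)) {
          mu[hit, np] <- mu[hit, np] * neuro_fold
        }
        if (!is.null(rl_truth)) {
          for (i in seq_len(nrow(rl_truth))) {
            lig <- intersect(split_genes(rl_truth$ligand[[i]]), genes)
            rec <- intersect(split_genes(rl_truth$receptor[[i]]), genes)
            snd <- spot_niche == rl_truth$sender_niche[i]
            rcv <- spot_niche == rl_truth$receiver_niche[i]
            m <- rl_truth$multiplier[i]
            if (length(lig)) mu[snd, lig] <- mu[snd, lig] * m
            if (length(rec)) mu[rcv, rec] <- mu[rcv, rec] * m
          }
        }
      }
      counts <- matrix(rpois(length(mu), mu), nrow(mu), ncol(mu),
        dimnames = list(pos$barcode, genes)
      )
      datasets[[s]] <- spatial_dataset(counts, pos, sample_id = s, condition = cond)
      niche_map[[s]] <- tibble::tibble(
        sample_id = s, barcode = pos$barcode, niche = spot_niche
      )
      prop_truth[[s]] <- dplyr::mutate(
        tidyr::pivot_longer(
          dplyr::bind_cols(tibble::tibble(barcode = pos$barcode), tibble::as_tibble(props)),
          -"barcode",
          names_to = "cell_type", values_to = "proportion"
        ),
        sample_id = s, .before = 1
      )
    }
    list(
      datasets = datasets,
      truth = list(
        niche_map = dplyr::bind_rows(niche_map),
        proportions = dplyr::bind_rows(prop_truth),
        celltype_profiles = celltype_profiles,
        niche_archetypes = niche_archetypes,
        neuropeptide_genes = neuropeptide_genes,
        rl_truth = rl_truth
      )
    )
  })
}

split_genes <- function(x) {
  if (is.list(x)) x <- x[[1]]
  unlist(strsplit(x, ";", fixed = TRUE))
}

#' Simulate a receptor-ligand pair table
#'
#' Draws `n_pairs` ligand/receptor pairings over the given gene universe;
#' `frac_complex` of the receptors are two-subunit complexes. Ligand and
#' receptor gene sets are disjoint across roles.
#'
#' @param genes Character vector of available genes.
#' @param n_pairs Number of pairs.
#' @param frac_complex Fraction of pairs with a 2-subunit receptor.
#' @param seed Integer seed.
#' @return Tibble: `pair_id`, `ligand`, `receptor` (";"-joined subunits).
#' @export
simulate_rl_pairs <- function(genes, n_pairs = 50, frac_complex = 0.2, seed = 1) {
  with_seed(seed, {
    n_half <- length(genes) %/% 2
    lig_pool <- genes[seq_len(n_half)]
    rec_pool <- genes[(n_half + 1):length(genes)]
    lig <- sample(lig_pool, n_pairs, replace = TRUE)
    rec1 <- sample(rec_pool, n_pairs, replace = TRUE)
    cx <- runif(n_pairs) < frac_complex
    rec2 <- sample(rec_pool, n_pairs, replace = TRUE)
    receptor <- ifelse(cx & rec2 != rec1, paste(rec1, rec2, sep = ";"), rec1)
    tibble::tibble(
      pair_id = sprintf("RL%04d", seq_len(n_pairs)),
      ligand = lig,
      receptor = receptor
    )
  })
}
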