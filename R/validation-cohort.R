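#' Simulate a two-tissue validation cohort with one planted effect per module
#'
#' Builds the cross-module ground-truth test bed used by the package's own
#' validation: two 350-cell tissues over the full 299-gene panel with
#'
#' * a proximal state shift (+1.5 baseline-sd on 10 genes) in tumor cells
#'   touching T cells (both tissues),
#' * one gene in tumor cells whose mean falls linearly with distance to the
#'   nearest T cell (slope -0.33 counts/um),
#' * one gene in tumor cells rising with the number of T-cell neighbors
#'   within 15 um (slope 2 counts/neighbor),
#' * one gene tripled in T cells simultaneously proximal to tumor and B
#'   cells (triplet condition), and
#' * bacterial 16S clusters in the second tissue plus a +12 shift on one
#'   gene in cells containing bacterial transcripts.
#'
#' Planted genes are chosen (deterministically, per seed) among the most
#' expressed non-marker genes of the focal type so every effect is
#' detectable at these tissue sizes.
#'
#' @param seed Integer seed controlling the whole cohort.
#' @param n_cells Cells per tissue (default 350).
#' @return List with `samples` (two annotated `tissue_sample`s) and
#'   `planted` (named list: `proximity_genes`, `distance_gene`,
#'   `neighbor_gene`, `triplet_gene`, `bacteria_gene`, `all_genes`).
#' @export
simulate_validation_cohort <- function(seed = 1, n_cells = 350) {
  # one shared panel profile across the cohort: the same targeted panel
  # measured in two patients
  type_props <- c(tumor = 0.40, tcell = 0.20, bcell = 0.15,
                  macrophage = 0.15, endothelial = 0.10)
  profile <- withr::with_seed(seed, {
    .type_mean_profiles(names(type_props), sprintf("g%03d", 1:299),
                        170, 8, 25)
  })
  tissues <- lapply(1:2, function(i) {
    simulate_tissue(n_cells = n_cells, seed = seed + i,
                    type_props = type_props, gene_means = profile,
                    tissue_id = paste0("cohort_t", i))
  })
  markers <- attr(tissues[[1]], "markers")$gene
  rank_genes <- function(type) {
    gm <- attr(tissues[[1]], "gene_means")[type, ]
    names(sort(gm[!names(gm) %in% markers], decreasing = TRUE))
  }
  # Gene allocation decouples the modules' test families. The triplet
  # effect is multiplicative, so it gets the most expressed non-marker
  # gene; the mean-setting linear effects and the bacteria shift take the
  # next abundant slots. The proximity-shift program is sd-scaled, so it
  # works at any baseline; it goes on moderate-expression genes (baseline
  # mean near 1) that stay below the distance module's 98th-percentile
  # filter — a proximity-induced state program should not double as ten
  # distance-response discoveries.
  top_tcell <- rank_genes("tcell")
  triplet_gene <- top_tcell[1]
  rest <- setdiff(rank_genes("tumor"), triplet_gene)
  distance_gene <- rest[1]
  neighbor_gene <- rest[2]
  bacteria_gene <- rest[3]
  gm_tumor <- attr(tissues[[1]], "gene_means")["tumor", ]
  mid <- names(sort(abs(gm_tumor - 1)))
  mid <- setdiff(mid, c(markers, triplet_gene, distance_gene,
                        neighbor_gene, bacteria_gene))
  prox_genes <- mid[1:10]

  sd_prox <- mean(apply(tissues[[1]]$counts[, prox_genes, drop = FALSE],
                        2, stats::sd))
  base_effects <- list(
    list(kind = "proximity_shift", type_i = "tumor", type_ii = "tcell",
         genes = prox_genes, delta = 1.5 * sd_prox),
    list(kind = "distance_linear", type_x = "tumor", type_y = "tcell",
         gene = distance_gene, a = 14, b = -0.33),
    list(kind = "neighbor_linear", type_x = "tumor", type_y = "tcell",
         gene = neighbor_gene, a = 3, b = 2),
    list(kind = "triplet", type_a = "tcell", type_b = "tumor",
         type_c = "bcell", gene = triplet_gene, factor = 3)
  )
  samples <- lapply(seq_along(tissues), function(i) {
    plant_spatial_effects(tissues[[i]], base_effects, seed = seed + 10 + i)
  })
  # bacteria only in the second tissue
  samples[[2]] <- plant_bacteria(samples[[2]], n_clusters = 8,
                                 cluster_size = 10, cluster_scale = 1,
                                 n_noise = 10, seed = seed + 20)
  samples[[2]] <- plant_spatial_effects(
    samples[[2]],
    list(list(kind = "bacteria_shift", genes = bacteria_gene, delta = 12)),
    seed = seed + 21)
  list(
    samples = samples,
    planted = list(
      proximity_genes = prox_genes,
      distance_gene = distance_gene,
      neighbor_gene = neighbor_gene,
      triplet_gene = triplet_gene,
      bacteria_gene = bacteria_gene,
      all_genes = c(prox_genes, distance_gene, neighbor_gene,
                    triplet_gene, bacteria_gene)
    )
  )
}
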