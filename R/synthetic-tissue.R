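#' Simulate a 3D tissue with negative-binomial targeted-panel counts
#'
#' Generates a synthetic `tissue_sample` emulating targeted in-situ spatial
#' transcriptomics of a multi-cell-type 3D tissue: cell centers placed
#' uniformly in a thin slab, cell types drawn from stated proportions,
#' per-cell counts drawn gene-wise from negative binomials with per-type mean
#' profiles (a handful of strongly elevated marker genes per type on a shared
#' low baseline), transcripts scattered isotropically around each cell center
#' (nuclear transcripts tighter than cytoplasmic ones) and tiled into
#' 100 x 100 um fields of view.
#'
#' @param n_cells Number of cells (default 400).
#' @param extent Tissue extents in micrometres, length-3 (default
#'   `c(300, 300, 10)` - a thin section).
#' @param fov_size FOV tile side in micrometres (default 100).
#' @param type_props Named numeric vector of cell-type proportions (must sum
#'   to 1). Default: five types echoing a tumor microenvironment.
#' @param n_genes Panel size (default 299).
#' @param mean_total Expected transcripts per cell (default 170).
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2),
#'   default 0.3.
#' @param n_markers Markers per type (default 8), elevated `marker_fold`-fold
#'   (default 25) over the baseline.
#' @param marker_fold Fold elevation of marker genes.
#' @param cell_radius Isotropic transcript-cloud scale in micrometres
#'   (default 4).
#' @param nuclear_fraction Probability a transcript is nuclear (default 0.3).
#' @param min_transcripts QC threshold passed to [tissue_sample()]
#'   (default 50).
#' @param gene_means Optional type x gene NB mean matrix to reuse across
#'   tissues of a cohort (the same targeted panel measured in several
#'   patients); by default a fresh profile is drawn under `seed`.
#' @param tissue_id,seed Identification and reproducibility.
#' @return A `tissue_sample` (platform `"synthetic"`, boundary convention)
#'   with ground-truth `type_label`s filled in, plus attributes
#'   `gene_means` (type x gene NB mean matrix), `dispersion`, `markers`
#'   (tibble gene/cell_type) and `sim_params`.
#' @export
simulate_tissue <- function(n_cells = 400,
                            extent = c(300, 300, 10),
                            fov_size = 100,
                            type_props = c(tumor = 0.40, tcell = 0.20, bcell = 0.15,
                                           macrophage = 0.15, endothelial = 0.10),
                            n_genes = 299,
                            mean_total = 170,
                            dispersion = 0.3,
                            n_markers = 8,
                            marker_fold = 25,
                            cell_radius = 4,
                            nuclear_fraction = 0.3,
                            min_transcripts = 50,
                            gene_means = NULL,
                            tissue_id = "synthetic1",
                            seed = 1) {
  stopifnot(abs(sum(type_props) - 1) < 1e-8, all(type_props > 0),
            length(extent) == 3, n_genes >= length(type_props) * n_markers)
  withr::with_seed(seed, {
    types <- sample(names(type_props), n_cells, replace = TRUE, prob = type_props)
    centers <- cbind(
      x = stats::runif(n_cells, 0, extent[1]),
      y = stats::runif(n_cells, 0, extent[2]),
      z = stats::runif(n_cells, 0, extent[3])
    )
    genes <- sprintf("g%03d", seq_len(n_genes))
    if (is.null(gene_means)) {
      gene_means <- .type_mean_profiles(names(type_props), genes, mean_total,
                                        n_markers, marker_fold)
    }
    stopifnot(identical(rownames(gene_means), names(type_props)))
    mu <- gene_means[types, , drop = FALSE]
    counts <- matrix(
      stats::rnbinom(n_cells * n_genes, mu = as.vector(mu), size = 1 / dispersion),
      n_cells, n_genes, dimnames = list(sprintf("c%04d", seq_len(n_cells)), genes)
    )
    nf <- stats::setNames(rep(nuclear_fraction, n_genes), genes)
    tx <- .counts_to_transcripts(counts, centers, cell_radius, nf, fov_size)
    sample <- tissue_sample(tx, tissue_id = tissue_id, platform = "synthetic",
                            fov_size = fov_size, min_transcripts = min_transcripts)
    sample <- annotate_cells(
      sample,
      tibble::tibble(cell_id = rownames(counts), cell_type = types)
    )
    attr(sample, "gene_means") <- gene_means
    attr(sample, "dispersion") <- dispersion
    attr(sample, "markers") <- attr(gene_means, "markers")
    attr(sample, "sim_params") <- list(
      n_cells = n_cells, extent = extent, fov_size = fov_size,
      type_props = type_props, mean_total = mean_total,
      dispersion = dispersion, cell_radius = cell_radius,
      nuclear_fraction = nuclear_fraction, seed = seed
    )
    sample
  })
}

# Per-type NB mean profiles: a shared lognormal baseline scaled so its sum
# hits mean_total, with disjoint marker blocks elevated marker_fold-fold on
# top of it. Elevation is not renormalized away: marker-bearing types simply
# carry more transcripts, and non-marker means stay comparable across types
# (which also keeps the panel stocked with well-expressed shared genes, as a
# real targeted cancer panel is).
.type_mean_profiles <- function(type_names, genes, mean_total, n_markers,
                                marker_fold) {
  n_genes <- length(genes)
  base <- stats::rlnorm(n_genes, meanlog = 0, sdlog = 1)
  base <- base / sum(base) * mean_total
  mm <- matrix(rep(base, each = length(type_names)), length(type_names), n_genes,
               dimnames = list(type_names, genes))
  marker_tbl <- tibble::tibble(gene = character(), cell_type = character())
  for (i in seq_along(type_names)) {
    idx <- ((i - 1) * n_markers + 1):(i * n_markers)
    mm[i, idx] <- mm[i, idx] * marker_fold
    marker_tbl <- dplyr::bind_rows(
      marker_tbl,
      tibble::tibble(gene = genes[idx], cell_type = type_names[i])
    )
  }
  attr(mm, "markers") <- marker_tbl
  mm
}

# Expand a count matrix into a per-molecule transcript table around given
# cell centers. Nuclear transcripts are drawn at half the cytoplasmic scale.
.counts_to_transcripts <- function(counts, centers, cell_radius,
                                   nuclear_fraction, fov_size) {
  n_per_cell <- rowSums(counts)
  cell_ids <- rownames(counts)
  gene_idx <- lapply(seq_len(nrow(counts)), function(i) {
    rep.int(seq_len(ncol(counts)), counts[i, ])
  })
  cell_of <- rep.int(seq_len(nrow(counts)), n_per_cell)
  gi <- unlist(gene_idx)
  n <- length(gi)
  gene <- colnames(counts)[gi]
  nuc <- stats::runif(n) < nuclear_fraction[gene]
  sdv <- ifelse(nuc, cell_radius / 2, cell_radius)
  tibble::tibble(
    gene = gene,
    x = centers[cell_of, 1] + stats::rnorm(n, sd = sdv),
    y = centers[cell_of, 2] + stats::rnorm(n, sd = sdv),
    z = centers[cell_of, 3] + stats::rnorm(n, sd = sdv / 2),
    cell_id = cell_ids[cell_of],
    fov_id = paste0("fov_", floor(pmax(0, centers[cell_of, 1]) / fov_size), "_",
                    floor(pmax(0, centers[cell_of, 2]) / fov_size)),
    compartment = ifelse(nuc, "nuclear", "cytoplasmic"),
    bacterial = FALSE
  )
}

#' Plant spatial expression effects into a synthetic tissue
#'
#' Modifies the negative-binomial means of named genes as a function of the
#' tissue's *measured* spatial covariates (computed with the same machinery
#' the analysis modules use), redraws those genes' counts, and rebuilds the
#' sample. Supported effect kinds:
#'
#' * `proximity_shift`: `delta` added to the NB mean of `genes` in type-`type_i`
#'   cells proximal (boundary distance <= `threshold`, default 1 um) to
#'   `type_ii`.
#' * `distance_linear`: NB mean of `gene` in `type_x` cells set to
#'   `pmax(0, a + b * d)` where `d` is the measured minimum distance to
#'   `type_y` (same-FOV scope, as in the distance-response module); cells
#'   without a defined distance keep their baseline mean.
#' * `neighbor_linear`: NB mean set to `pmax(0, a + b * k)` where `k` is the
#'   number of `type_y` neighbors within `cutoff` (default 15 um).
#' * `triplet`: NB mean of `gene` multiplied by `factor` in `type_a` cells
#'   simultaneously proximal to `type_b` and `type_c` (condition 2).
#' * `bacteria_shift`: `delta` added to the NB mean of `genes` in cells
#'   containing planted bacterial transcripts (apply after
#'   [plant_bacteria()]).
#'
#' @param sample A synthetic `tissue_sample` from [simulate_tissue()].
#' @param effects List of effect descriptors (named lists with a `kind`
#'   field and the parameters above).
#' @param seed Integer seed for the count redraws.
#' @return The modified sample; attribute `planted` holds a ledger tibble
#'   (one row per effect x gene with its parameters).
#' @export
plant_spatial_effects <- function(sample, effects, seed = 1) {
  stopifnot(inherits(sample, "tissue_sample"))
  gene_means <- attr(sample, "gene_means")
  dispersion <- attr(sample, "dispersion")
  params <- attr(sample, "sim_params")
  if (is.null(gene_means)) stop("sample lacks simulation attributes", call. = FALSE)
  all_genes <- unlist(lapply(effects, function(e) e$genes %||% e$gene))
  if (anyDuplicated(all_genes)) {
    stop("conflicting planted effects: gene(s) ",
         paste(unique(all_genes[duplicated(all_genes)]), collapse = ", "),
         " targeted more than once", call. = FALSE)
  }
  if (!all(all_genes %in% colnames(sample$counts))) {
    stop("planted effect names gene(s) outside the panel", call. = FALSE)
  }

  cells <- sample$cells
  types <- stats::setNames(cells$type_label, cells$cell_id)
  ledger <- list()
  # per-cell x per-gene replacement means; NA = keep baseline draw
  new_mu <- matrix(NA_real_, nrow(cells), length(all_genes),
                   dimnames = list(cells$cell_id, all_genes))

  for (e in effects) {
    kind <- e$kind
    if (kind == "proximity_shift") {
      strat <- stratify_by_proximity(sample, e$type_i, e$type_ii,
                                     threshold = e$threshold %||% 1)
      for (g in e$genes) {
        base <- gene_means[types[strat$proximal_ids], g]
        new_mu[strat$proximal_ids, g] <- base + e$delta
        ledger[[length(ledger) + 1]] <- tibble::tibble(
          kind = kind, gene = g, type_x = e$type_i, type_y = e$type_ii,
          param = "delta", value = e$delta)
      }
    } else if (kind == "distance_linear") {
      ids <- cells$cell_id[!is.na(cells$type_label) & cells$type_label == e$type_x]
      d <- min_distance_to_type(sample, e$type_y, cells = ids,
                                scope = e$scope %||% "same_fov")
      ok <- !is.na(d$distance)
      new_mu[d$cell_id[ok], e$gene] <- pmax(0, e$a + e$b * d$distance[ok])
      ledger[[length(ledger) + 1]] <- tibble::tibble(
        kind = kind, gene = e$gene, type_x = e$type_x, type_y = e$type_y,
        param = "slope", value = e$b)
    } else if (kind == "neighbor_linear") {
      ids <- cells$cell_id[!is.na(cells$type_label) & cells$type_label == e$type_x]
      k <- count_neighbors(sample, e$type_y, cutoff = e$cutoff %||% 15, cells = ids)
      new_mu[k$cell_id, e$gene] <- pmax(0, e$a + e$b * k$n_neighbors)
      ledger[[length(ledger) + 1]] <- tibble::tibble(
        kind = kind, gene = e$gene, type_x = e$type_x, type_y = e$type_y,
        param = "slope", value = e$b)
    } else if (kind == "triplet") {
      thr <- e$threshold %||% 1
      ids <- cells$cell_id[!is.na(cells$type_label) & cells$type_label == e$type_a]
      db <- min_distance_to_type(sample, e$type_b, cells = ids, scope = "tissue")
      dc <- min_distance_to_type(sample, e$type_c, cells = ids, scope = "tissue")
      cond2 <- ids[!is.na(db$distance) & db$distance <= thr &
                     !is.na(dc$distance) & dc$distance <= thr]
      base <- gene_means[types[cond2], e$gene]
      new_mu[cond2, e$gene] <- base * e$factor
      ledger[[length(ledger) + 1]] <- tibble::tibble(
        kind = kind, gene = e$gene, type_x = e$type_a,
        type_y = paste(e$type_b, e$type_c, sep = "+"),
        param = "factor", value = e$factor)
    } else if (kind == "bacteria_shift") {
      # delta on cells that contain planted bacterial transcripts
      b <- sample$transcripts
      ids <- intersect(unique(b$cell_id[b$bacterial & !is.na(b$cell_id)]),
                       cells$cell_id)
      for (g in e$genes) {
        new_mu[ids, g] <- gene_means[types[ids], g] + e$delta
        ledger[[length(ledger) + 1]] <- tibble::tibble(
          kind = kind, gene = g, type_x = NA_character_,
          type_y = "bacteria", param = "delta", value = e$delta)
      }
    } else {
      stop("unknown effect kind: ", kind, call. = FALSE)
    }
  }

  out <- withr::with_seed(seed, {
    .redraw_gene_counts(sample, new_mu, gene_means, dispersion, params)
  })
  attr(out, "planted") <- dplyr::bind_rows(ledger)
  out
}

# Redraw counts for the columns of new_mu (NA entries keep the original draw),
# replace those genes' transcripts, and rebuild the sample with annotations
# and simulation attributes carried over.
.redraw_gene_counts <- function(sample, new_mu, gene_means, dispersion, params) {
  cells <- sample$cells
  types <- stats::setNames(cells$type_label, cells$cell_id)
  counts_new <- sample$counts[, colnames(new_mu), drop = FALSE]
  for (g in colnames(new_mu)) {
    mu_g <- new_mu[, g]
    redo <- !is.na(mu_g)
    if (!any(redo)) next
    counts_new[redo, g] <- stats::rnbinom(sum(redo), mu = mu_g[redo],
                                          size = 1 / dispersion)
  }
  tx <- sample$transcripts
  keep <- !(tx$gene %in% colnames(new_mu)) | is.na(tx$cell_id) | tx$bacterial
  centers <- as.matrix(cells[, c("x", "y", "z")])
  rownames(centers) <- cells$cell_id
  nf <- stats::setNames(rep(params$nuclear_fraction, ncol(counts_new)),
                        colnames(counts_new))
  tx_new <- .counts_to_transcripts(counts_new, centers, params$cell_radius,
                                   nf, params$fov_size)
  tx2 <- dplyr::bind_rows(tx[keep, , drop = FALSE], tx_new)
  out <- tissue_sample(tx2, tissue_id = sample$tissue_id,
                       platform = sample$platform, fov_size = sample$fov_size,
                       min_transcripts = sample$min_transcripts)
  out <- annotate_cells(out, tibble::tibble(cell_id = names(types),
                                            cell_type = unname(types)))
  attr(out, "gene_means") <- gene_means
  attr(out, "dispersion") <- dispersion
  attr(out, "markers") <- attr(sample, "markers")
  attr(out, "sim_params") <- params
  for (a in c("velocity_truth", "bacteria_truth")) {
    attr(out, a) <- attr(sample, a)
  }
  out
}

#' Plant steady-state / induced velocity structure
#'
#' Treats the sample's existing counts as cytoplasmic (spliced, s) and adds
#' nuclear (unspliced, u) transcripts so that for steady-state cells
#' u ~ Poisson(gamma * s) and for a fraction of induced cells
#' u ~ Poisson(induction_factor * gamma * s), giving them positive velocity
#' v = u - gamma * s under the fitted model.
#'
#' @param sample A synthetic `tissue_sample`.
#' @param gamma_per_gene Named non-negative vector of degradation rates; genes
#'   not named keep gamma 0 (no nuclear signal added).
#' @param induced_fraction Fraction of cells induced (default 0).
#' @param induction_factor Fold inflation of u in induced cells (default 3).
#' @param induced_ids Optional explicit induced cell ids (overrides
#'   `induced_fraction`).
#' @param seed Seed for the draws.
#' @return The sample with nuclear transcripts rewritten; attribute
#'   `velocity_truth` holds `gamma`, `induced_ids`.
#' @export
plant_velocity <- function(sample, gamma_per_gene, induced_fraction = 0,
                           induction_factor = 3, induced_ids = NULL, seed = 1) {
  stopifnot(inherits(sample, "tissue_sample"), all(gamma_per_gene >= 0))
  params <- attr(sample, "sim_params")
  cells <- sample$cells
  withr::with_seed(seed, {
    if (is.null(induced_ids)) {
      n_ind <- round(induced_fraction * nrow(cells))
      induced_ids <- sample(cells$cell_id, n_ind)
    }
    # existing counts become the cytoplasmic compartment
    tx <- sample$transcripts
    tx$compartment[!tx$bacterial & !is.na(tx$cell_id)] <- "cytoplasmic"
    s_counts <- sample$counts
    genes_v <- intersect(names(gamma_per_gene), colnames(s_counts))
    mu_u <- sweep(s_counts[, genes_v, drop = FALSE], 2,
                  gamma_per_gene[genes_v], `*`)
    ind <- rownames(s_counts) %in% induced_ids
    mu_u[ind, ] <- mu_u[ind, , drop = FALSE] * induction_factor
    u_counts <- matrix(stats::rpois(length(mu_u), lambda = as.vector(mu_u)),
                       nrow(mu_u), ncol(mu_u), dimnames = dimnames(mu_u))
    centers <- as.matrix(cells[, c("x", "y", "z")])
    rownames(centers) <- cells$cell_id
    nf <- stats::setNames(rep(1, ncol(u_counts)), colnames(u_counts))
    tx_u <- .counts_to_transcripts(u_counts[cells$cell_id, , drop = FALSE],
                                   centers, params$cell_radius, nf,
                                   params$fov_size)
    tx_u$compartment <- "nuclear"
    out <- tissue_sample(dplyr::bind_rows(tx, tx_u),
                         tissue_id = sample$tissue_id,
                         platform = sample$platform,
                         fov_size = sample$fov_size,
                         min_transcripts = sample$min_transcripts)
    out <- annotate_cells(out, tibble::tibble(cell_id = cells$cell_id,
                                              cell_type = cells$type_label))
    for (a in c("gene_means", "dispersion", "markers", "sim_params", "planted")) {
      attr(out, a) <- attr(sample, a)
    }
    attr(out, "velocity_truth") <- list(gamma = gamma_per_gene,
                                        induced_ids = induced_ids)
    out
  })
}

#' Plant bacterial 16S transcript clusters plus background noise
#'
#' Adds bacterial-flagged transcripts: `n_clusters` Gaussian clusters of
#' `cluster_size` points at scale `cluster_scale`, plus `n_noise` uniform
#' background points. A bacterial point is assigned to the nearest cell when
#' within `assign_radius` of its centroid (emulating "inside the segmented
#' boundary"); otherwise it stays unassigned.
#'
#' @param sample A synthetic `tissue_sample`.
#' @param n_clusters,cluster_size,cluster_scale Cluster count, points per
#'   cluster (default 8) and Gaussian sd in micrometres (default 1).
#' @param n_noise Uniform background points (default 30).
#' @param assign_radius Cell-assignment radius in micrometres (default: the
#'   generator's `cell_radius`).
#' @param seed Seed.
#' @return The sample with bacterial transcripts appended; attribute
#'   `bacteria_truth` holds cluster centers and per-point memberships.
#' @export
plant_bacteria <- function(sample, n_clusters = 5, cluster_size = 8,
                           cluster_scale = 1, n_noise = 30,
                           assign_radius = NULL, seed = 1) {
  stopifnot(inherits(sample, "tissue_sample"), cluster_scale > 0)
  params <- attr(sample, "sim_params")
  extent <- params$extent
  assign_radius <- assign_radius %||% params$cell_radius
  cells <- sample$cells
  withr::with_seed(seed, {
    centers <- NULL
    pts <- NULL
    member <- integer(0)
    if (n_clusters > 0) {
      # cluster centers sit on cell centroids so some objects fall inside cells
      anchor <- sample(seq_len(nrow(cells)), n_clusters, replace = TRUE)
      centers <- as.matrix(cells[anchor, c("x", "y", "z")])
      for (k in seq_len(n_clusters)) {
        p <- matrix(stats::rnorm(cluster_size * 3, sd = cluster_scale),
                    cluster_size, 3)
        p <- sweep(p, 2, centers[k, ], `+`)
        pts <- rbind(pts, p)
        member <- c(member, rep.int(k, cluster_size))
      }
    }
    if (n_noise > 0) {
      noise <- cbind(stats::runif(n_noise, 0, extent[1]),
                     stats::runif(n_noise, 0, extent[2]),
                     stats::runif(n_noise, 0, extent[3]))
      pts <- rbind(pts, noise)
      member <- c(member, rep.int(0L, n_noise))
    }
    if (is.null(pts)) return(sample)
    cc <- as.matrix(cells[, c("x", "y", "z")])
    cid <- vapply(seq_len(nrow(pts)), function(i) {
      d <- sqrt(colSums((t(cc) - pts[i, ])^2))
      j <- which.min(d)
      if (d[j] <= assign_radius) cells$cell_id[j] else NA_character_
    }, character(1))
    tx_b <- tibble::tibble(
      gene = "16S", x = pts[, 1], y = pts[, 2], z = pts[, 3],
      cell_id = cid,
      fov_id = paste0("fov_", floor(pmax(0, pts[, 1]) / params$fov_size), "_",
                      floor(pmax(0, pts[, 2]) / params$fov_size)),
      compartment = "unassigned", bacterial = TRUE
    )
    out <- tissue_sample(dplyr::bind_rows(sample$transcripts, tx_b),
                         tissue_id = sample$tissue_id,
                         platform = sample$platform,
                         fov_size = sample$fov_size,
                         min_transcripts = sample$min_transcripts)
    out <- annotate_cells(out, tibble::tibble(cell_id = cells$cell_id,
                                              cell_type = cells$type_label))
    for (a in c("gene_means", "dispersion", "markers", "sim_params",
                "planted", "velocity_truth")) {
      attr(out, a) <- attr(sample, a)
    }
    attr(out, "bacteria_truth") <- list(centers = centers, membership = member)
    out
  })
}
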