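#' Density-based clustering of 3D points (DBSCAN)
#'
#' Classic DBSCAN on a 3D point cloud: a core point has at least
#' `min_samples` points (itself included) within `epsilon`; clusters grow by
#' density reachability from core points; non-reachable points are noise
#' (label 0).
#'
#' @param points Numeric matrix, n x 3.
#' @param epsilon Neighborhood radius (> 0), micrometres.
#' @param min_samples Core-point threshold including self (default 3).
#' @return Integer vector of cluster labels (0 = noise, clusters numbered
#'   from 1 in order of discovery).
#' @export
dbscan_cluster <- function(points, epsilon, min_samples = 3) {
  stopifnot(epsilon > 0)
  points <- as.matrix(points)
  n <- nrow(points)
  if (n == 0) return(integer(0))
  d <- as.matrix(stats::dist(points))
  nbr <- lapply(seq_len(n), function(i) which(d[i, ] <= epsilon))
  core <- lengths(nbr) >= min_samples
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- nbr[[i]]
    while (length(queue) > 0) {
      j <- queue[1]
      queue <- queue[-1]
      if (labels[j] == 0L) {
        labels[j] <- cl
        if (core[j]) queue <- c(queue, nbr[[j]][labels[nbr[[j]]] == 0L])
      }
    }
  }
  labels
}

#' Sum of pairwise distances within a point set
#'
#' The spatial-compactness statistic of a candidate bacterial object:
#' smaller sums mean tighter clusters.
#'
#' @param points Numeric matrix, n x 3.
#' @return Non-negative scalar (micrometres).
#' @export
cluster_compactness <- function(points) {
  if (nrow(points) < 2) return(0)
  sum(stats::dist(points))
}

#' Compactness significance of one cluster against a host-gene null
#'
#' Repeatedly samples size-matched random sets from the host reference
#' points, computes their compactness, and reports a lower-tail
#' normal-approximation p-value (smaller sum = more compact than chance).
#'
#' @param cluster_points Matrix of the cluster's transcript positions.
#' @param reference_points Matrix of host-gene transcript positions (must
#'   contain at least as many points as the cluster).
#' @param n_perm Resamples (default 10000).
#' @param seed Integer seed.
#' @return A `permutation_test` (lower tail) on the compactness.
#' @export
object_significance <- function(cluster_points, reference_points,
                                n_perm = 10000, seed = 1) {
  k <- nrow(cluster_points)
  if (nrow(reference_points) < k) {
    stop("reference has fewer points than the cluster", call. = FALSE)
  }
  obs <- cluster_compactness(cluster_points)
  null_c <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(nrow(reference_points), k)
      cluster_compactness(reference_points[idx, , drop = FALSE])
    }, numeric(1))
  })
  normal_approx_p(obs, null_c, tail = "lower", n_permutations = n_perm,
                  seed = seed)
}

# Reference positions for one FOV: transcripts of the most frequent host
# gene in that FOV; falls back to the whole-tissue most frequent host gene
# when the FOV reference is smaller than the cluster.
.host_reference <- function(sample, fov, k) {
  tx <- sample$transcripts
  host <- tx[!tx$bacterial, , drop = FALSE]
  in_fov <- host[host$fov_id == fov, , drop = FALSE]
  pick <- function(df) {
    if (nrow(df) == 0) return(NULL)
    g <- names(sort(table(df$gene), decreasing = TRUE))[1]
    m <- df[df$gene == g, c("x", "y", "z")]
    as.matrix(m)
  }
  ref <- pick(in_fov)
  if (is.null(ref) || nrow(ref) < k) ref <- pick(host)
  ref
}

#' Detect significant bacterial transcript objects
#'
#' DBSCAN-clusters the bacterial transcripts of each FOV at the given
#' epsilon, then tests each cluster's spatial compactness against
#' size-matched random draws from the FOV's most frequent host gene
#' ([object_significance()]).
#'
#' @param sample A `tissue_sample` with bacterial-flagged transcripts.
#' @param epsilon DBSCAN radius in micrometres.
#' @param min_samples Core threshold (default 3).
#' @param n_perm Null resamples per cluster (default 10000).
#' @param seed Integer seed.
#' @param alpha Significance threshold on p (default 0.05).
#' @return Tibble of objects: `object_id`, `fov_id`, `n_transcripts`,
#'   `compactness`, `p`, `significant`, `transcript_rows` (list-column of
#'   row indices into `sample$transcripts`).
#' @export
detect_bacterial_objects <- function(sample, epsilon, min_samples = 3,
                                     n_perm = 10000, seed = 1, alpha = 0.05) {
  tx <- sample$transcripts
  b_idx <- which(tx$bacterial)
  if (length(b_idx) == 0) return(tibble::tibble())
  rows <- list()
  oid <- 0L
  for (fov in unique(tx$fov_id[b_idx])) {
    idx <- b_idx[tx$fov_id[b_idx] == fov]
    pts <- cbind(tx$x[idx], tx$y[idx], tx$z[idx])
    labels <- dbscan_cluster(pts, epsilon, min_samples)
    for (cl in setdiff(unique(labels), 0L)) {
      oid <- oid + 1L
      members <- idx[labels == cl]
      cp <- pts[labels == cl, , drop = FALSE]
      ref <- .host_reference(sample, fov, nrow(cp))
      if (is.null(ref) || nrow(ref) < nrow(cp)) {
        rows[[oid]] <- tibble::tibble(
          object_id = oid, fov_id = fov, n_transcripts = nrow(cp),
          compactness = cluster_compactness(cp), p = NA_real_,
          significant = FALSE, transcript_rows = list(members))
        next
      }
      pt <- object_significance(cp, ref, n_perm = n_perm, seed = seed + oid)
      rows[[oid]] <- tibble::tibble(
        object_id = oid, fov_id = fov, n_transcripts = nrow(cp),
        compactness = cluster_compactness(cp), p = pt$p,
        significant = !is.na(pt$p) && pt$p <= alpha,
        transcript_rows = list(members))
    }
  }
  if (length(rows) == 0) return(tibble::tibble())
  dplyr::bind_rows(rows)
}

#' Epsilon sweep with F1-based selection
#'
#' Clusters the bacterial transcripts at every epsilon on the grid,
#' evaluates cluster significance, and summarizes precision (significant /
#' all clusters), recall (clustered transcripts / all bacterial
#' transcripts) and their harmonic mean F1. The selected epsilon maximizes
#' F1 (ties broken toward the smallest epsilon).
#'
#' @inheritParams detect_bacterial_objects
#' @param eps_grid Numeric vector of radii to sweep (micrometres).
#' @return List with `sweep` (tibble per epsilon: `epsilon`,
#'   `n_clustered_transcripts`, `recall`, `n_clusters`, `n_significant`,
#'   `precision`, `f1`) and `selected_epsilon`.
#' @export
epsilon_sweep <- function(sample, eps_grid, min_samples = 3, n_perm = 1000,
                          seed = 1, alpha = 0.05) {
  stopifnot(length(eps_grid) > 0)
  total_b <- sum(sample$transcripts$bacterial)
  sweep_rows <- purrr::map_dfr(sort(eps_grid), function(eps) {
    obj <- detect_bacterial_objects(sample, eps, min_samples = min_samples,
                                    n_perm = n_perm, seed = seed,
                                    alpha = alpha)
    nc <- nrow(obj)
    n_clustered <- if (nc > 0) sum(obj$n_transcripts) else 0L
    n_sig <- if (nc > 0) sum(obj$significant) else 0L
    precision <- if (nc > 0) n_sig / nc else 0
    recall <- if (total_b > 0) n_clustered / total_b else 0
    f1 <- if (precision + recall > 0) {
      2 * precision * recall / (precision + recall)
    } else 0
    tibble::tibble(epsilon = eps, n_clustered_transcripts = n_clustered,
                   recall = recall, n_clusters = nc, n_significant = n_sig,
                   precision = precision, f1 = f1)
  })
  best <- sweep_rows$epsilon[which.max(sweep_rows$f1)]
  list(sweep = sweep_rows, selected_epsilon = best)
}

#' Classify host cells relative to significant bacterial transcripts
#'
#' Counts, per cell, the significant bacterial transcripts lying within the
#' cell (assigned to it) and the minimum 3D distance from any of the cell's
#' transcripts to the nearest significant bacterial transcript outside it.
#' Classes: `include` (>= 1 internal), `proximal` (none internal, external
#' distance <= `threshold`), `distant` otherwise.
#'
#' @param sample A `tissue_sample`.
#' @param objects Tibble from [detect_bacterial_objects()].
#' @param threshold Proximity threshold in micrometres (default 1).
#' @return Tibble: `cell_id`, `class`, `n_internal_bacterial`,
#'   `min_external_distance`.
#' @export
classify_cells_by_bacteria <- function(sample, objects, threshold = 1) {
  tx <- sample$transcripts
  cells <- sample$cells$cell_id
  sig_rows <- if (nrow(objects) > 0) {
    unlist(objects$transcript_rows[objects$significant])
  } else integer(0)
  n_int <- stats::setNames(integer(length(cells)), cells)
  if (length(sig_rows) > 0) {
    assigned <- tx$cell_id[sig_rows]
    tb <- table(assigned[!is.na(assigned)])
    n_int[names(tb)[names(tb) %in% cells]] <-
      as.integer(tb[names(tb) %in% cells])
  }
  min_ext <- rep(NA_real_, length(cells))
  if (length(sig_rows) > 0) {
    B <- cbind(tx$x[sig_rows], tx$y[sig_rows], tx$z[sig_rows])
    b_cell <- tx$cell_id[sig_rows]
    host <- tx[!tx$bacterial & !is.na(tx$cell_id), , drop = FALSE]
    coords <- split.data.frame(cbind(host$x, host$y, host$z),
                               factor(host$cell_id, levels = cells))
    for (i in seq_along(cells)) {
      ext <- is.na(b_cell) | b_cell != cells[i]
      if (!any(ext)) next
      m <- coords[[cells[i]]]
      if (is.null(m) || nrow(m) == 0) next
      min_ext[i] <- .cross_min_dist(m, B[ext, , drop = FALSE])
    }
  }
  class <- dplyr::case_when(
    n_int >= 1 ~ "include",
    !is.na(min_ext) & min_ext <= threshold ~ "proximal",
    .default = "distant"
  )
  tibble::tibble(cell_id = cells, class = class,
                 n_internal_bacterial = unname(n_int),
                 min_external_distance = min_ext)
}

#' Differential expression of bacteria-including versus distant cells
#'
#' Builds include-versus-distant labels from
#' [classify_cells_by_bacteria()] (optionally within one cell type) and
#' runs the shared permutation-wrapped NB engine.
#'
#' @param sample An annotated `tissue_sample`.
#' @param classes Tibble from [classify_cells_by_bacteria()].
#' @param cell_type Optional cell type to restrict to.
#' @inheritParams permutation_de
#' @return DE tibble from [permutation_de()], or `NULL` when either group
#'   has fewer than 2 cells.
#' @export
bacteria_de <- function(sample, classes, cell_type = NULL, n_perm = 1000,
                        seed = 1, lfc_threshold = 1) {
  keep <- classes$class %in% c("include", "distant")
  ids <- classes$cell_id[keep]
  if (!is.null(cell_type)) {
    ct <- sample$cells
    ids <- intersect(ids, ct$cell_id[!is.na(ct$type_label) &
                                       ct$type_label == cell_type])
  }
  lab <- classes$class[match(ids, classes$cell_id)]
  if (sum(lab == "include") < 2 || sum(lab == "distant") < 2) return(NULL)
  permutation_de(sample$counts[ids, , drop = FALSE],
                 factor(lab, levels = c("distant", "include")),
                 n_perm = n_perm, seed = seed, lfc_threshold = lfc_threshold)
}
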