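#' Extract a marker table from reference differential-expression results
#'
#' Filters per-type gene statistics from a matched single-cell reference to
#' strong markers (`avg_log2FC > lfc_min` and adjusted p at most `p_zero`,
#' the operational meaning of "adjusted p approximately 0"), then resolves
#' genes marking more than one type: if exactly one holder reaches `p_zero`
#' the gene is kept for that type only; any other duplication drops the
#' gene. Canonical markers are appended by union (they never override a
#' reference-derived mapping).
#'
#' @param reference_de Tibble with `gene`, `cell_type`, `avg_log2FC`,
#'   `adjusted_p`.
#' @param canonical Optional tibble `gene`, `cell_type` of canonical
#'   markers.
#' @param lfc_min Log2 fold-change threshold (default 5).
#' @param p_zero "p approximately zero" threshold (default 1e-200).
#' @return Tibble `gene`, `cell_type`, `provenance`; each gene maps to at
#'   most one type.
#' @export
extract_markers <- function(reference_de, canonical = NULL, lfc_min = 5,
                            p_zero = 1e-200) {
  need <- c("gene", "cell_type", "avg_log2FC", "adjusted_p")
  if (!all(need %in% names(reference_de))) {
    stop("reference_de must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  cand <- reference_de |>
    dplyr::filter(.data$avg_log2FC > lfc_min, .data$adjusted_p <= p_zero) |>
    dplyr::distinct(.data$gene, .data$cell_type, .keep_all = TRUE)
  resolved <- cand |>
    dplyr::group_by(.data$gene) |>
    dplyr::group_modify(function(df, key) {
      if (nrow(df) == 1) return(df[, c("cell_type"), drop = FALSE])
      # the filter already enforces p <= p_zero for all rows, so any
      # duplication across types is ambiguous: drop the gene
      df[0, c("cell_type"), drop = FALSE]
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(provenance = "tissue_matched")
  if (!is.null(canonical)) {
    extra <- canonical |>
      dplyr::filter(!.data$gene %in% resolved$gene) |>
      dplyr::distinct(.data$gene, .keep_all = TRUE) |>
      dplyr::select("gene", "cell_type") |>
      dplyr::mutate(provenance = "canonical")
    resolved <- dplyr::bind_rows(resolved, extra)
  }
  resolved[, c("gene", "cell_type", "provenance")]
}

# normalize -> log1p -> per-gene scale -> PCA -> kNN graph -> Louvain
.cluster_once <- function(counts, n_pcs, resolution, k_nn = 20, seed = 1) {
  n <- nrow(counts)
  if (n <= n_pcs) return(NULL)
  tot <- rowSums(counts)
  norm <- counts / pmax(tot, 1) * stats::median(tot)
  lg <- log1p(norm)
  sds <- apply(lg, 2, stats::sd)
  z <- scale(lg[, sds > 0, drop = FALSE])
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  k_use <- min(n_pcs, ncol(pc$x))
  sc <- pc$x[, seq_len(k_use), drop = FALSE]
  d <- as.matrix(stats::dist(sc))
  k_nn <- min(k_nn, n - 1)
  edges <- integer(0)
  for (i in seq_len(n)) {
    nb <- order(d[i, ])[2:(k_nn + 1)]
    edges <- c(edges, rbind(i, nb))
  }
  g <- igraph::simplify(igraph::make_graph(edges, n = n, directed = FALSE))
  memb <- withr::with_seed(seed, {
    igraph::membership(igraph::cluster_louvain(g, resolution = resolution))
  })
  stats::setNames(as.integer(memb), rownames(counts))
}

#' Cluster a count matrix across a parameter grid
#'
#' For every combination of principal-component count and clustering
#' resolution: per-cell depth normalization, log transform, per-gene
#' scaling, PCA, a k-nearest-neighbor graph and Louvain modularity
#' communities at the given resolution. Combinations with more PCs than
#' cells are skipped.
#'
#' @param counts Integer matrix, cells x genes (QC filtered).
#' @param pcs_grid,resolution_grid Parameter grids (defaults
#'   `seq(6, 30, 2)` and `seq(0.2, 2, 0.2)`).
#' @param k_nn Graph neighbors (default 20).
#' @param seed Integer seed (clustering is deterministic given it).
#' @return List of solutions, each `list(n_pcs, resolution, cluster_of)`.
#' @export
cluster_parameter_grid <- function(counts, pcs_grid = seq(6, 30, 2),
                                   resolution_grid = seq(0.2, 2, 0.2),
                                   k_nn = 20, seed = 1) {
  stopifnot(length(pcs_grid) > 0, length(resolution_grid) > 0)
  out <- list()
  i <- 0L
  for (np in pcs_grid) for (res in resolution_grid) {
    i <- i + 1L
    cl <- .cluster_once(counts, np, res, k_nn = k_nn, seed = seed + i)
    if (is.null(cl)) next
    out[[length(out) + 1]] <- list(n_pcs = np, resolution = res,
                                   cluster_of = cl)
  }
  out
}

#' Resolve a cluster's cell-type assignment from candidate marker q-values
#'
#' Pure rule application on the (cell_type, q) table of the cluster's
#' candidate markers (one-vs-rest overexpression q-values):
#' * no candidate reaching `q_max` - unassigned;
#' * a single candidate with q <= `q_max` - assigned;
#' * several candidates, all one type - assigned when the best q <= `q_max`;
#' * candidates of different types - assigned when exactly one reaches
#'   "q approximately 0" (`q_zero`), or when the leader satisfies
#'   `log10(q1/q2) < 0.3 * log10(q2)` with `q1 <= q_max`; two different
#'   types both at q approximately 0 stay unassigned.
#'
#' @param candidates Tibble with `cell_type` and `q` (one row per marker).
#' @param q_max Assignment threshold (default 1e-9).
#' @param q_zero "q approximately 0" threshold (default 1e-200).
#' @return Cell-type string or `NA_character_`.
#' @export
resolve_cluster_assignment <- function(candidates, q_max = 1e-9,
                                       q_zero = 1e-200) {
  if (nrow(candidates) == 0) return(NA_character_)
  cand <- candidates[candidates$q <= q_max, , drop = FALSE]
  if (nrow(cand) == 0) return(NA_character_)
  cand <- cand[order(cand$q), , drop = FALSE]
  if (nrow(cand) == 1) return(cand$cell_type[1])
  if (length(unique(cand$cell_type)) == 1) return(cand$cell_type[1])
  near_zero <- cand$q <= q_zero
  zero_types <- unique(cand$cell_type[near_zero])
  if (length(zero_types) >= 2) return(NA_character_)
  if (sum(near_zero) >= 1 && length(zero_types) == 1) {
    others <- cand$cell_type != zero_types
    if (!any(cand$q[others] <= q_zero)) return(zero_types)
  }
  # leading candidate vs the best marker of a different type
  q1 <- cand$q[1]
  other <- cand[cand$cell_type != cand$cell_type[1], , drop = FALSE]
  q2 <- other$q[1]
  lq1 <- log10(pmax(q1, 1e-300))
  lq2 <- log10(pmax(q2, 1e-300))
  if ((lq1 - lq2) < 0.3 * lq2 && q1 <= q_max) return(cand$cell_type[1])
  NA_character_
}

#' Assign cell types to the clusters of one solution
#'
#' One-vs-rest Wilcoxon rank-sum overexpression tests of every marker gene
#' per cluster, BH-corrected across all marker x cluster tests of the
#' solution, then [resolve_cluster_assignment()] per cluster.
#'
#' @param solution A solution from [cluster_parameter_grid()].
#' @param markers Marker table from [extract_markers()].
#' @param counts The count matrix the solution was fitted on.
#' @param q_max,q_zero Thresholds passed to the rule.
#' @return Named character vector: cluster id -> cell type (or `NA`).
#' @export
assign_cluster_types <- function(solution, markers, counts, q_max = 1e-9,
                                 q_zero = 1e-200) {
  cl <- solution$cluster_of
  clusters <- sort(unique(cl))
  mk <- markers[markers$gene %in% colnames(counts), , drop = FALSE]
  if (nrow(mk) == 0) {
    return(stats::setNames(rep(NA_character_, length(clusters)), clusters))
  }
  tests <- list()
  for (cid in clusters) {
    inside <- cl == cid
    if (sum(inside) < 2 || sum(!inside) < 2) next
    for (j in seq_len(nrow(mk))) {
      g <- mk$gene[j]
      p <- suppressWarnings(stats::wilcox.test(
        counts[inside, g], counts[!inside, g],
        alternative = "greater")$p.value)
      tests[[length(tests) + 1]] <- tibble::tibble(
        cluster = cid, gene = g, cell_type = mk$cell_type[j], p = p)
    }
  }
  if (length(tests) == 0) {
    return(stats::setNames(rep(NA_character_, length(clusters)), clusters))
  }
  tt <- dplyr::bind_rows(tests)
  tt$q <- bh_adjust(tt$p)
  assign <- vapply(clusters, function(cid) {
    resolve_cluster_assignment(tt[tt$cluster == cid, c("cell_type", "q")],
                               q_max = q_max, q_zero = q_zero)
  }, character(1))
  stats::setNames(assign, clusters)
}

#' Consensus labels over retained clustering solutions
#'
#' Solutions with more than `min_types` inferred cell types are retained;
#' each cell's final label is its most frequent assignment across retained
#' solutions, provided it appears in at least `support_frac` of them and in
#' at least `min_support` solutions. Ties break to unassigned.
#'
#' @param labeled_solutions List of per-solution label vectors
#'   (cell -> cell type or `NA`), e.g. built by applying
#'   [assign_cluster_types()] to each solution.
#' @param min_types Retention threshold on inferred type count (default 3,
#'   i.e. more than three types required).
#' @param support_frac Minimum support fraction (default 0.20).
#' @param min_support Minimum supporting solutions (default 10).
#' @return Tibble: `cell_id`, `label` (`NA` for unassigned),
#'   `support_count`, `support_fraction`, plus attribute `n_retained`.
#' @export
consensus_labels <- function(labeled_solutions, min_types = 3,
                             support_frac = 0.20, min_support = 10) {
  n_types <- vapply(labeled_solutions, function(l) {
    length(unique(stats::na.omit(l)))
  }, integer(1))
  retained <- labeled_solutions[n_types > min_types]
  cells <- unique(unlist(lapply(labeled_solutions, names)))
  if (length(retained) == 0) {
    warning("no clustering solution retained; all cells unassigned",
            call. = FALSE)
    out <- tibble::tibble(cell_id = cells, label = NA_character_,
                          support_count = 0L, support_fraction = 0)
    attr(out, "n_retained") <- 0L
    return(out)
  }
  n_ret <- length(retained)
  lab_mat <- vapply(retained, function(l) l[cells], character(length(cells)))
  res <- purrr::map_dfr(seq_along(cells), function(i) {
    labs <- stats::na.omit(lab_mat[i, ])
    if (length(labs) == 0) {
      return(tibble::tibble(cell_id = cells[i], label = NA_character_,
                            support_count = 0L, support_fraction = 0))
    }
    tb <- sort(table(labs), decreasing = TRUE)
    top <- as.integer(tb[1])
    tied <- sum(tb == top) > 1
    lab <- names(tb)[1]
    frac <- top / n_ret
    ok <- !tied && frac >= support_frac && top >= min_support
    tibble::tibble(cell_id = cells[i],
                   label = if (ok) lab else NA_character_,
                   support_count = top, support_fraction = frac)
  })
  attr(res, "n_retained") <- n_ret
  res
}

#' Full marker-driven consensus cell-typing pipeline
#'
#' Grid clustering, per-solution marker assignment and consensus labeling
#' in one call.
#'
#' @inheritParams cluster_parameter_grid
#' @param markers Marker table from [extract_markers()].
#' @param min_support Consensus support minimum; defaults to
#'   `min(10, #solutions)` so small grids stay usable.
#' @param ... Passed to [consensus_labels()].
#' @return The [consensus_labels()] tibble.
#' @export
cell_type_pipeline <- function(counts, markers, pcs_grid = seq(6, 30, 2),
                               resolution_grid = seq(0.2, 2, 0.2),
                               k_nn = 20, seed = 1, min_support = NULL, ...) {
  sols <- cluster_parameter_grid(counts, pcs_grid, resolution_grid,
                                 k_nn = k_nn, seed = seed)
  labeled <- lapply(sols, function(s) {
    a <- assign_cluster_types(s, markers, counts)
    stats::setNames(unname(a[as.character(s$cluster_of)]),
                    names(s$cluster_of))
  })
  min_support <- min_support %||% min(10L, length(sols))
  consensus_labels(labeled, min_support = min_support, ...)
}

#' Permutation validation of the cell-typing pipeline
#'
#' Shuffles transcript counts across cells within each gene (preserving
#' every gene's count distribution while destroying co-expression),
#' re-runs the full pipeline per permutation, and tests whether the real
#' data yield more validly labeled cells than the null via the upper-tail
#' normal approximation.
#'
#' @inheritParams cell_type_pipeline
#' @param n_perm Number of permutations (default 20).
#' @return List with `observed` (labeled-cell count), `null_counts`, and
#'   `test` (a `permutation_test`).
#' @export
permutation_validate_typing <- function(counts, markers,
                                        pcs_grid = seq(6, 30, 2),
                                        resolution_grid = seq(0.2, 2, 0.2),
                                        k_nn = 20, n_perm = 20, seed = 1,
                                        min_support = NULL, ...) {
  run <- function(m, sd) {
    res <- suppressWarnings(cell_type_pipeline(
      m, markers, pcs_grid, resolution_grid, k_nn = k_nn, seed = sd,
      min_support = min_support, ...))
    sum(!is.na(res$label))
  }
  observed <- run(counts, seed)
  null_counts <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      perm <- apply(counts, 2, sample)
      rownames(perm) <- rownames(counts)
      run(perm, seed + b)
    }, numeric(1))
  })
  test <- normal_approx_p(observed, null_counts, tail = "upper",
                          n_permutations = n_perm, seed = seed)
  list(observed = observed, null_counts = null_counts, test = test)
}
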