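#' Per-cell expression and nearest-neighbor distance for a cell-type pair
#'
#' For boundary-convention platforms the nearest `type_y` distance is
#' computed within each cell's FOV and cells with no same-FOV neighbor of
#' the other type are dropped. Centroid-convention platforms use
#' whole-tissue centroid distances with the sample's cap (145 um by
#' default), dropping cells whose nearest neighbor lies beyond it.
#'
#' @param sample An annotated `tissue_sample`.
#' @param type_x Primary cell type whose expression is modeled.
#' @param type_y Neighbor type providing the distances.
#' @return List with `cells` (tibble `cell_id`, `distance`) and `counts`
#'   (expression submatrix of the retained X cells), or `NULL` when no X
#'   cell has a defined distance.
#' @export
prepare_distance_table <- function(sample, type_x, type_y) {
  ct <- sample$cells
  ids <- ct$cell_id[!is.na(ct$type_label) & ct$type_label == type_x]
  if (length(ids) == 0 || !(type_y %in% cell_types(sample))) return(NULL)
  scope <- if (sample$distance_convention == "boundary") "same_fov" else "tissue"
  d <- min_distance_to_type(sample, type_y, cells = ids, scope = scope)
  d <- d[!is.na(d$distance), , drop = FALSE]
  if (nrow(d) == 0) return(NULL)
  list(cells = d, counts = sample$counts[d$cell_id, , drop = FALSE])
}

#' Distance-response gene filter
#'
#' Genes are excluded when their 98th expression percentile is at most 10
#' counts, or when they are detected (count > 0) in at most 20 cells; a gene
#' is retained only when it fails both exclusion criteria.
#'
#' @param counts Integer matrix, cells x genes.
#' @param p98_max Exclusion cutoff on the 98th percentile (default 10).
#' @param min_detected Exclusion cutoff on the number of detecting cells
#'   (default 20).
#' @return Character vector of retained gene names.
#' @export
filter_distance_genes <- function(counts, p98_max = 10, min_detected = 20) {
  p98 <- apply(counts, 2, stats::quantile, probs = 0.98)
  ndet <- colSums(counts > 0)
  colnames(counts)[p98 > p98_max & ndet > min_detected]
}

#' Linear regression of one gene's expression on nearest-neighbor distance
#'
#' Ordinary least squares of raw counts on distance, with the coefficient
#' t-test p-value, plus the mean R-squared over `n_perm` distance shuffles
#' as a noise floor.
#'
#' @param expression Numeric vector of per-cell counts.
#' @param distances Matching vector of minimum distances (um).
#' @param n_perm Distance shuffles (default 100).
#' @param seed Integer seed.
#' @return One-row tibble: `slope`, `intercept`, `r2`, `mean_perm_r2`, `p`,
#'   `n_cells`, `p98_expression`, `p98_distance`. `NULL` when the distances
#'   are degenerate.
#' @export
distance_regression <- function(expression, distances, n_perm = 100, seed = 1) {
  stopifnot(length(expression) == length(distances))
  n <- length(expression)
  if (n < 3 || stats::sd(distances) == 0) return(NULL)
  if (stats::sd(expression) == 0) {
    return(tibble::tibble(slope = 0, intercept = expression[1], r2 = 0,
                          mean_perm_r2 = 0, p = 1, n_cells = n,
                          p98_expression = stats::quantile(expression, 0.98),
                          p98_distance = stats::quantile(distances, 0.98)))
  }
  fit <- stats::lm(expression ~ distances)
  sm <- summary(fit)
  perm_r2 <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      stats::cor(expression, sample(distances))^2
    }, numeric(1))
  })
  tibble::tibble(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r2 = sm$r.squared,
    mean_perm_r2 = mean(perm_r2),
    p = sm$coefficients[2, 4],
    n_cells = n,
    p98_expression = unname(stats::quantile(expression, 0.98)),
    p98_distance = unname(stats::quantile(distances, 0.98))
  )
}

#' Gaussian-smoothing robustness filter
#'
#' Sorts cells by distance, applies a 1D Gaussian filter (sigma in
#' sorted-rank units) to the expression vector, and re-regresses the
#' smoothed values on distance. Associations whose smoothed R-squared falls
#' below the threshold are flagged for exclusion.
#'
#' @param expression,distances Per-cell vectors.
#' @param sigma Gaussian sd in rank units (default 5).
#' @return `gaussian_r2` (scalar; `NA` for n < 3).
#' @export
gaussian_smooth_r2 <- function(expression, distances, sigma = 5) {
  n <- length(expression)
  if (n < 3 || stats::sd(distances) == 0) return(NA_real_)
  ord <- order(distances)
  y <- expression[ord]
  x <- distances[ord]
  w <- stats::dnorm(outer(seq_len(n), seq_len(n), `-`) / sigma)
  ys <- as.vector(w %*% y) / rowSums(w)
  if (stats::sd(ys) < 1e-10 * (1 + mean(abs(ys)))) return(0)
  summary(stats::lm(ys ~ x))$r.squared
}

#' Scan tissues for distance-dependent gene expression
#'
#' For every ordered pair of distinct cell types in each sample:
#' nearest-distance table ([prepare_distance_table()]), gene filtering
#' ([filter_distance_genes()]), per-gene OLS with permuted-R-squared floor
#' ([distance_regression()]), a global BH correction across all gene x pair
#' x tissue tests, the Gaussian-smoothing filter on significant hits, and
#' composite ranking ([composite_score()]).
#'
#' @param samples A `tissue_sample` or list of annotated samples.
#' @param n_perm Distance shuffles per gene (default 100).
#' @param sigma Gaussian smoothing sd in rank units (default 5).
#' @param gaussian_r2_min Smoothed-fit threshold (default 0.5; 0.3 is the
#'   relaxed alternative for centroid-convention platforms).
#' @param alpha Significance threshold on the global q (default 0.05).
#' @param seed Integer seed.
#' @param min_cells Minimum X cells per pair (default 10).
#' @return Tibble of all records with `q`, `significant`, `gaussian_r2`,
#'   `reported` (significant and passing the smoothing filter) and
#'   `composite_score` (reported records only).
#' @export
distance_response_scan <- function(samples, n_perm = 100, sigma = 5,
                                   gaussian_r2_min = 0.5, alpha = 0.05,
                                   seed = 1, min_cells = 10) {
  if (inherits(samples, "tissue_sample")) samples <- list(samples)
  rows <- list()
  sctx <- list()
  for (s in samples) {
    tys <- cell_types(s)
    for (tx in tys) for (ty in setdiff(tys, tx)) {
      tab <- prepare_distance_table(s, tx, ty)
      if (is.null(tab) || nrow(tab$cells) < min_cells) next
      genes <- filter_distance_genes(tab$counts)
      for (g in genes) {
        rec <- distance_regression(tab$counts[, g], tab$cells$distance,
                                   n_perm = n_perm,
                                   seed = seed + length(rows))
        if (is.null(rec)) next
        rows[[length(rows) + 1]] <- dplyr::mutate(
          rec, tissue_id = s$tissue_id, type_x = tx, type_y = ty, gene = g,
          .before = 1)
        sctx[[length(rows)]] <- list(e = tab$counts[, g],
                                     d = tab$cells$distance)
      }
    }
  }
  if (length(rows) == 0) return(tibble::tibble())
  out <- dplyr::bind_rows(rows) |>
    dplyr::mutate(q = bh_adjust(.data$p),
                  significant = .data$q < alpha,
                  gaussian_r2 = NA_real_)
  for (i in which(out$significant)) {
    out$gaussian_r2[i] <- gaussian_smooth_r2(sctx[[i]]$e, sctx[[i]]$d,
                                             sigma = sigma)
  }
  out$reported <- out$significant & !is.na(out$gaussian_r2) &
    out$gaussian_r2 >= gaussian_r2_min
  out$composite_score <- NA_real_
  if (sum(out$reported) >= 2) {
    out$composite_score[out$reported] <-
      composite_score(out[out$reported, , drop = FALSE])$composite_score
  }
  dplyr::arrange(out, dplyr::desc(.data$reported), .data$q)
}

#' Composite ranking of distance-response records
#'
#' Eight features are ranked across records; desirability is descending for
#' `|slope|`, `r2`, `gaussian_r2`, `n_cells`, `p98_expression` and
#' `p98_distance` and ascending for `mean_perm_r2` and `q`. Each rank
#' (1 = best, ties averaged) is reversed to `n - rank` and the composite
#' score is the sum of reversed ranks, so scores span \[0, 8(n-1)\].
#'
#' @param records Tibble with the eight feature columns.
#' @return The records with a `composite_score` column, sorted descending.
#' @export
composite_score <- function(records) {
  stopifnot(nrow(records) >= 2)
  n <- nrow(records)
  desc_feats <- list(abs(records$slope), records$r2, records$gaussian_r2,
                     records$n_cells, records$p98_expression,
                     records$p98_distance)
  asc_feats <- list(records$mean_perm_r2, records$q)
  rev_rank <- function(v, best_high) {
    r <- if (best_high) rank(-v, ties.method = "average")
         else rank(v, ties.method = "average")
    n - r
  }
  score <- Reduce(`+`, c(lapply(desc_feats, rev_rank, best_high = TRUE),
                         lapply(asc_feats, rev_rank, best_high = FALSE)))
  records$composite_score <- score
  dplyr::arrange(records, dplyr::desc(.data$composite_score))
}
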