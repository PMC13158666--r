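#' Neighbor-count bins and gene set for a cell-type pair
#'
#' Counts `type_y` neighbors of each `type_x` cell within `cutoff`
#' micrometres (boundary convention; same-type pairs exclude the cell
#' itself), drops neighbor-count bins holding fewer than `min_bin` cells,
#' and declares the pair valid only with at least `min_bins` surviving bins.
#' Genes with no expression in any X cell are removed, then only the top
#' `top_var_frac` most variable genes are kept.
#'
#' @param sample An annotated `tissue_sample`.
#' @param type_x,type_y Primary and neighbor cell types (may be equal).
#' @param cutoff Distance cutoff in micrometres (default 15).
#' @param min_bin Minimum cells per neighbor-count bin (default 10).
#' @param min_bins Minimum number of valid bins (default 4).
#' @param top_var_frac Variance-filter fraction (default 0.2).
#' @return List with `cells` (tibble `cell_id`, `n_neighbors`, restricted to
#'   valid bins), `counts` (filtered expression submatrix), `bins` (tibble of
#'   retained bins) and `valid`; `NULL` when the pair has no X cells.
#' @export
prepare_neighbor_bins <- function(sample, type_x, type_y, cutoff = 15,
                                  min_bin = 10, min_bins = 4,
                                  top_var_frac = 0.2) {
  ct <- sample$cells
  ids <- ct$cell_id[!is.na(ct$type_label) & ct$type_label == type_x]
  if (length(ids) == 0 || !(type_y %in% cell_types(sample))) return(NULL)
  nb <- count_neighbors(sample, type_y, cutoff = cutoff, cells = ids)
  tab <- table(nb$n_neighbors)
  keep_bins <- as.integer(names(tab)[tab >= min_bin])
  valid <- length(keep_bins) >= min_bins
  cells <- nb[nb$n_neighbors %in% keep_bins, , drop = FALSE]
  counts <- sample$counts[cells$cell_id, , drop = FALSE]
  counts <- counts[, colSums(counts) > 0, drop = FALSE]
  if (ncol(counts) > 0) {
    v <- apply(counts, 2, stats::var)
    keep <- v >= stats::quantile(v, 1 - top_var_frac)
    counts <- counts[, keep, drop = FALSE]
  }
  list(cells = cells, counts = counts,
       bins = tibble::tibble(n_neighbors = keep_bins,
                             n_cells = as.integer(tab[as.character(keep_bins)])),
       valid = valid, cutoff = cutoff)
}

#' Iterative balanced-sampling regression of expression on neighbor count
#'
#' Corrects neighbor-count imbalance by running `n_iter` OLS fits, each on a
#' balanced sample of `per_bin` cells drawn from every valid neighbor-count
#' bin. The reported slope is the mean of the iteration slopes; the intercept
#' is refit to the original data (`mean(y) - slope * mean(x)`); the p-value
#' is the median of the per-iteration coefficient p-values (the standard
#' all-cells OLS p is kept alongside for audit).
#'
#' @param expression Per-cell counts of one gene.
#' @param neighbor_counts Matching neighbor counts.
#' @param n_iter Balanced resampling iterations (default 1000).
#' @param per_bin Cells sampled per bin (default 10).
#' @param seed Integer seed.
#' @return One-row tibble: `slope`, `intercept`, `p`, `p_standard`,
#'   `slope_standard`, `method = "iterative"`.
#' @export
iterative_sampling_regression <- function(expression, neighbor_counts,
                                          n_iter = 1000, per_bin = 10,
                                          seed = 1) {
  stopifnot(length(expression) == length(neighbor_counts))
  bins <- split(seq_along(expression), neighbor_counts)
  stopifnot(all(lengths(bins) >= per_bin), length(bins) >= 2)
  res <- withr::with_seed(seed, {
    vapply(seq_len(n_iter), function(i) {
      idx <- unlist(lapply(bins, sample, size = per_bin))
      f <- stats::lm(expression[idx] ~ neighbor_counts[idx])
      co <- summary(f)$coefficients
      if (nrow(co) < 2) c(0, 1) else c(co[2, 1], co[2, 4])
    }, numeric(2))
  })
  slope <- mean(res[1, ])
  std <- summary(stats::lm(expression ~ neighbor_counts))$coefficients
  tibble::tibble(
    slope = slope,
    intercept = mean(expression) - slope * mean(neighbor_counts),
    p = stats::median(res[2, ]),
    p_standard = std[2, 4],
    slope_standard = std[2, 1],
    method = "iterative"
  )
}

#' Alternative neighbor-count regressions
#'
#' * `standard`: plain OLS on all cells.
#' * `wls_raw`: weighted least squares with inverse bin-frequency weights.
#' * `wls_norm`: the same weights normalized to sum to one (estimates and
#'   t-statistics are identical to `wls_raw` - weights are scale-invariant).
#' * `line_agg`: the `n_iter` balanced-sample regression lines are evaluated
#'   at every observed neighbor-count value, the points pooled, and a single
#'   OLS fitted through them.
#'
#' @inheritParams iterative_sampling_regression
#' @param method One of `"standard"`, `"wls_raw"`, `"wls_norm"`,
#'   `"line_agg"`.
#' @return One-row tibble: `slope`, `intercept`, `p`, `method`.
#' @export
alternative_regression <- function(expression, neighbor_counts,
                                   method = c("standard", "wls_raw",
                                              "wls_norm", "line_agg"),
                                   n_iter = 1000, per_bin = 10, seed = 1) {
  method <- match.arg(method)
  x <- neighbor_counts
  if (method == "standard") {
    co <- summary(stats::lm(expression ~ x))$coefficients
    return(tibble::tibble(slope = co[2, 1], intercept = co[1, 1],
                          p = co[2, 4], method = method))
  }
  if (method %in% c("wls_raw", "wls_norm")) {
    freq <- table(x)
    w <- 1 / as.numeric(freq[as.character(x)])
    if (method == "wls_norm") w <- w / sum(w)
    co <- summary(stats::lm(expression ~ x, weights = w))$coefficients
    return(tibble::tibble(slope = co[2, 1], intercept = co[1, 1],
                          p = co[2, 4], method = method))
  }
  # line_agg
  bins <- split(seq_along(expression), x)
  stopifnot(all(lengths(bins) >= per_bin))
  lines <- withr::with_seed(seed, {
    vapply(seq_len(n_iter), function(i) {
      idx <- unlist(lapply(bins, sample, size = per_bin))
      stats::coef(stats::lm(expression[idx] ~ x[idx]))
    }, numeric(2))
  })
  grid <- sort(unique(x))
  xs <- rep(grid, times = n_iter)
  ys <- as.vector(vapply(seq_len(n_iter),
                         function(i) lines[1, i] + lines[2, i] * grid,
                         numeric(length(grid))))
  co <- summary(stats::lm(ys ~ xs))$coefficients
  tibble::tibble(slope = co[2, 1], intercept = co[1, 1], p = co[2, 4],
                 method = method)
}

#' Scan tissues for neighbor-count-dependent gene expression
#'
#' For every ordered cell-type pair (including same-type pairs when
#' `include_same_type`), prepares neighbor bins, runs the chosen regression
#' methods per retained gene, and BH-adjusts p-values per method across all
#' gene x pair x tissue tests.
#'
#' @param samples A `tissue_sample` or list of annotated samples.
#' @param cutoff Distance cutoff in micrometres (default 15).
#' @param methods Subset of `"iterative"`, `"standard"`, `"wls_raw"`,
#'   `"wls_norm"`, `"line_agg"` (default `"iterative"`).
#' @param n_iter Balanced-sampling iterations (default 1000).
#' @param include_same_type Also analyze Y = X pairs (default FALSE).
#' @param seed Integer seed.
#' @return Tibble of records with `q` (BH across the genes of each
#'   method x tissue x pair family).
#' @export
neighbor_response_scan <- function(samples, cutoff = 15,
                                   methods = "iterative", n_iter = 1000,
                                   include_same_type = FALSE, seed = 1) {
  if (inherits(samples, "tissue_sample")) samples <- list(samples)
  rows <- list()
  for (s in samples) {
    tys <- cell_types(s)
    for (tx in tys) {
      ys <- if (include_same_type) tys else setdiff(tys, tx)
      for (ty in ys) {
        prep <- prepare_neighbor_bins(s, tx, ty, cutoff = cutoff)
        if (is.null(prep) || !prep$valid || ncol(prep$counts) == 0) next
        for (g in colnames(prep$counts)) {
          e <- prep$counts[, g]
          k <- prep$cells$n_neighbors
          for (m in methods) {
            rec <- if (m == "iterative") {
              iterative_sampling_regression(e, k, n_iter = n_iter,
                                            seed = seed + length(rows))
            } else {
              alternative_regression(e, k, method = m, n_iter = n_iter,
                                     seed = seed + length(rows))
            }
            rows[[length(rows) + 1]] <- dplyr::mutate(
              rec, tissue_id = s$tissue_id, type_x = tx, type_y = ty,
              gene = g, cutoff_um = cutoff, .before = 1)
          }
        }
      }
    }
  }
  if (length(rows) == 0) return(tibble::tibble())
  dplyr::bind_rows(rows) |>
    dplyr::group_by(.data$method, .data$tissue_id, .data$type_x,
                    .data$type_y) |>
    dplyr::mutate(q = bh_adjust(.data$p)) |>
    dplyr::ungroup()
}

#' Consensus neighbor-response gene set
#'
#' Intersects the significant (q < `alpha`) gene x pair sets across every
#' method and distance cutoff present in `records`, then applies an optional
#' reference-detection filter (genes detected in fewer than
#' `min_detect_frac` of reference cells of the primary type are removed).
#'
#' @param records Output of [neighbor_response_scan()] runs bound together
#'   (multiple methods and/or cutoffs).
#' @param alpha Significance threshold (default 0.05).
#' @param reference_detection Optional tibble `cell_type`, `gene`,
#'   `detect_frac` from matched single-cell data.
#' @param min_detect_frac Detection threshold (default 0.10).
#' @return Tibble of consensus `type_x`, `type_y`, `gene` combinations.
#' @export
consensus_neighbor_set <- function(records, alpha = 0.05,
                                   reference_detection = NULL,
                                   min_detect_frac = 0.10) {
  if (nrow(records) == 0) return(tibble::tibble())
  combos <- records |>
    dplyr::distinct(.data$method, .data$cutoff_um)
  sig_sets <- purrr::pmap(combos, function(method, cutoff_um) {
    records |>
      dplyr::filter(.data$method == !!method, .data$cutoff_um == !!cutoff_um,
                    .data$q < alpha) |>
      dplyr::distinct(.data$type_x, .data$type_y, .data$gene)
  })
  consensus <- Reduce(function(a, b) dplyr::inner_join(
    a, b, by = c("type_x", "type_y", "gene")), sig_sets)
  if (!is.null(reference_detection) && nrow(consensus) > 0) {
    consensus <- consensus |>
      dplyr::left_join(reference_detection,
                       by = c("type_x" = "cell_type", "gene")) |>
      dplyr::filter(is.na(.data$detect_frac) |
                      .data$detect_frac >= min_detect_frac) |>
      dplyr::select(-"detect_frac")
  }
  consensus
}
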