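#' Dispersion statistics of a proximal subset in PC1-PC2 space
#'
#' The overall centroid is the mean of *all* type-i cells. The proximal
#' dispersion is the sum of Euclidean distances from proximal cells to that
#' centroid; total dispersion sums over every cell; centroid separation is
#' the Euclidean distance between the proximal-subset and distant-subset
#' means.
#'
#' @param scores Numeric matrix (cells x 2), PC1-PC2 embedding of the
#'   z-scored expression of one cell type.
#' @param proximal Logical vector marking proximal rows.
#' @return Named list `dispersion_proximal`, `dispersion_total`,
#'   `centroid_separation`, `variance_contribution`.
#' @export
dispersion_statistics <- function(scores, proximal) {
  scores <- as.matrix(scores)[, 1:2, drop = FALSE]
  stopifnot(nrow(scores) == length(proximal), any(proximal), any(!proximal))
  ctr <- colMeans(scores)
  d <- sqrt(rowSums(sweep(scores, 2, ctr)^2))
  dp <- sum(d[proximal])
  dt <- sum(d)
  sep <- sqrt(sum((colMeans(scores[proximal, , drop = FALSE]) -
                     colMeans(scores[!proximal, , drop = FALSE]))^2))
  list(dispersion_proximal = dp, dispersion_total = dt,
       centroid_separation = sep,
       variance_contribution = if (dt > 0) dp / dt else NA_real_)
}

#' Combined proximity-dispersion permutation test for one cell-type pair
#'
#' Embeds the z-scored counts of type-i cells with [standardize_and_embed()]
#' (PC1-PC2), stratifies them by boundary-distance proximity to type ii, and
#' tests whether the proximal subset is unusually dispersed or displaced.
#' Proximal/distant labels are shuffled `n_perm` times preserving the
#' proximal subset size; both the proximal-dispersion and the
#' centroid-separation statistics are z-scored against their permutation
#' nulls and combined as `z_max = max(z_single, z_two)`. The one-sided
#' p-value of the observed `z_max` comes from the normal approximation to
#' the permuted `z_max` distribution (each permutation's pair of statistics
#' is z-scored against the full permuted distributions and the max taken).
#'
#' @param sample An annotated `tissue_sample`.
#' @param type_i,type_ii Stratified and reference cell types.
#' @param threshold Proximity threshold in micrometres (default 1).
#' @param n_perm Label shuffles (default 10000).
#' @param seed Integer seed.
#' @param exclude_genes Optional genes dropped before embedding (e.g. the
#'   reference type's markers, as a segmentation-artifact sensitivity check).
#' @return One-row tibble: counts, statistics, `z_single`, `z_two`, `z_max`,
#'   `p`, `variance_contribution`; or `NULL` when the pair is unanalyzable
#'   (needs >= 1 proximal, >= 1 distant and >= 3 cells in total).
#' @export
combined_proximity_test <- function(sample, type_i, type_ii, threshold = 1,
                                    n_perm = 10000, seed = 1,
                                    exclude_genes = NULL) {
  strat <- stratify_by_proximity(sample, type_i, type_ii, threshold)
  ids <- c(strat$proximal_ids, strat$distant_ids)
  if (!strat$analyzable || length(ids) < 3) return(NULL)
  counts <- sample$counts[ids, , drop = FALSE]
  if (!is.null(exclude_genes)) {
    counts <- counts[, setdiff(colnames(counts), exclude_genes), drop = FALSE]
  }
  emb <- suppressWarnings(standardize_and_embed(counts, n_components = 2))
  proximal <- ids %in% strat$proximal_ids
  .dispersion_perm_test(emb$scores, proximal, n_perm, seed) |>
    dplyr::mutate(tissue_id = sample$tissue_id, type_i = type_i,
                  type_ii = type_ii, .before = 1)
}

# core permutation machinery, shared with the shuffled control
.dispersion_perm_test <- function(scores, proximal, n_perm, seed) {
  obs <- dispersion_statistics(scores, proximal)
  n <- length(proximal)
  k <- sum(proximal)
  ctr <- colMeans(scores[, 1:2, drop = FALSE])
  d <- sqrt(rowSums(sweep(scores[, 1:2, drop = FALSE], 2, ctr)^2))
  s <- scores[, 1:2, drop = FALSE]
  cs_all <- colSums(s)
  perm <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      sel <- sample.int(n, k)
      cp <- colSums(s[sel, , drop = FALSE])
      sep <- sqrt(sum((cp / k - (cs_all - cp) / (n - k))^2))
      c(sum(d[sel]), sep)
    }, numeric(2))
  })
  m1 <- mean(perm[1, ]); s1 <- stats::sd(perm[1, ])
  m2 <- mean(perm[2, ]); s2 <- stats::sd(perm[2, ])
  z_single <- if (s1 > 0) (obs$dispersion_proximal - m1) / s1 else 0
  z_two <- if (s2 > 0) (obs$centroid_separation - m2) / s2 else 0
  z_max <- max(z_single, z_two)
  zperm <- pmax(if (s1 > 0) (perm[1, ] - m1) / s1 else rep(0, n_perm),
                if (s2 > 0) (perm[2, ] - m2) / s2 else rep(0, n_perm))
  pt <- normal_approx_p(z_max, zperm, tail = "upper",
                        n_permutations = n_perm, seed = seed)
  tibble::tibble(
    n_proximal = k, n_distant = n - k,
    dispersion_proximal = obs$dispersion_proximal,
    dispersion_total = obs$dispersion_total,
    centroid_separation = obs$centroid_separation,
    variance_contribution = obs$variance_contribution,
    z_single = z_single, z_two = z_two, z_max = z_max, p = pt$p
  )
}

#' Scan all cell-type pairs of one or more tissues for proximity dispersion
#'
#' Runs [combined_proximity_test()] for every ordered pair of distinct cell
#' types in each sample and BH-adjusts the p-values across the whole family
#' of analyzable tissue x pair combinations.
#'
#' @param samples A `tissue_sample` or list of them.
#' @inheritParams combined_proximity_test
#' @return Tibble of per-pair results with a `q` column, sorted by `q`.
#' @export
proximity_dispersion_scan <- function(samples, threshold = 1, n_perm = 10000,
                                      seed = 1) {
  if (inherits(samples, "tissue_sample")) samples <- list(samples)
  rows <- list()
  for (s in samples) {
    tys <- cell_types(s)
    for (ti in tys) for (tii in setdiff(tys, ti)) {
      seed_i <- seed + length(rows)
      r <- combined_proximity_test(s, ti, tii, threshold = threshold,
                                   n_perm = n_perm, seed = seed_i)
      if (!is.null(r)) rows[[length(rows) + 1]] <- r
    }
  }
  if (length(rows) == 0) return(tibble::tibble())
  dplyr::bind_rows(rows) |>
    dplyr::mutate(q = bh_adjust(.data$p)) |>
    dplyr::arrange(.data$q)
}

#' Binomial enrichment of significant pairs over a shuffled chance rate
#'
#' Given the number of significant tissue x cell-type-pair combinations in
#' the real data and in a label-shuffled control, tests whether the observed
#' count exceeds the chance rate: exact upper binomial tail
#' P(X >= observed) with X ~ Binomial(n_tested, shuffled/n_tested).
#' A shuffled count of zero is floored at a chance rate of 0.5/n_tested,
#' with a warning.
#'
#' @param observed_significant,n_tested,shuffled_significant Integer counts.
#' @return List with `p`, `log10_p`, `chance_rate`.
#' @export
significance_enrichment <- function(observed_significant, n_tested,
                                    shuffled_significant) {
  stopifnot(observed_significant <= n_tested,
            shuffled_significant <= n_tested)
  rate <- shuffled_significant / n_tested
  if (shuffled_significant == 0) {
    warning("shuffled control had zero significant pairs; ",
            "chance rate floored at 0.5/n", call. = FALSE)
    rate <- 0.5 / n_tested
  }
  list(p = binomial_tail(observed_significant, n_tested, rate),
       log10_p = binomial_tail(observed_significant, n_tested, rate,
                               log10_out = TRUE),
       chance_rate = rate)
}

#' Label-shuffled control for the dispersion scan
#'
#' Re-runs the full per-pair dispersion analysis with proximal/distant labels
#' randomly permuted (preserving subset sizes) and reports how many pairs
#' reach q <= `alpha` by chance.
#'
#' @inheritParams proximity_dispersion_scan
#' @param alpha Significance threshold on q (default 0.05).
#' @return List with `n_significant`, `n_tested` and the control scan tibble.
#' @export
shuffled_dispersion_control <- function(samples, threshold = 1, n_perm = 10000,
                                        seed = 1, alpha = 0.05) {
  if (inherits(samples, "tissue_sample")) samples <- list(samples)
  rows <- list()
  ctr <- 0L
  for (s in samples) {
    tys <- cell_types(s)
    for (ti in tys) for (tii in setdiff(tys, ti)) {
      ctr <- ctr + 1L
      strat <- stratify_by_proximity(s, ti, tii, threshold)
      ids <- c(strat$proximal_ids, strat$distant_ids)
      if (!strat$analyzable || length(ids) < 3) next
      counts <- s$counts[ids, , drop = FALSE]
      emb <- suppressWarnings(standardize_and_embed(counts, n_components = 2))
      k <- length(strat$proximal_ids)
      shuffled <- withr::with_seed(seed + ctr, {
        sel <- sample.int(length(ids), k)
        seq_along(ids) %in% sel
      })
      r <- .dispersion_perm_test(emb$scores, shuffled, n_perm, seed + 10000L + ctr)
      rows[[length(rows) + 1]] <- dplyr::mutate(
        r, tissue_id = s$tissue_id, type_i = ti, type_ii = tii, .before = 1)
    }
  }
  scan <- if (length(rows) > 0) {
    dplyr::bind_rows(rows) |> dplyr::mutate(q = bh_adjust(.data$p))
  } else tibble::tibble()
  list(n_significant = if (nrow(scan) > 0) sum(scan$q <= alpha) else 0L,
       n_tested = nrow(scan), scan = scan)
}
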