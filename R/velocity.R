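#' Nuclear / cytoplasmic count matrices from a tissue sample
#'
#' Splits a sample's transcripts by subcellular compartment into an
#' unspliced (nuclear, u) and a spliced (cytoplasmic, s) cell-by-gene count
#' matrix, plus the depth-normalized cytoplasmic matrix: each cell's
#' cytoplasmic counts are divided by the cell's total cytoplasmic count and
#' multiplied by the mean total across all cells.
#'
#' @param sample A `tissue_sample` with compartment-annotated transcripts.
#' @return List with `u`, `s`, `s_norm` (matrices over the same cells and
#'   genes) and `mean_total_s`.
#' @export
compartment_counts <- function(sample) {
  tx <- sample$transcripts
  tx <- tx[!tx$bacterial & !is.na(tx$cell_id) &
             tx$cell_id %in% sample$cells$cell_id, , drop = FALSE]
  cells <- sample$cells$cell_id
  genes <- colnames(sample$counts)
  tab <- function(sel) {
    m <- table(factor(tx$cell_id[sel], levels = cells),
               factor(tx$gene[sel], levels = genes))
    matrix(as.integer(m), length(cells), length(genes),
           dimnames = list(cells, genes))
  }
  u <- tab(tx$compartment == "nuclear")
  s <- tab(tx$compartment == "cytoplasmic")
  tot <- rowSums(s)
  mean_tot <- mean(tot)
  s_norm <- s / pmax(tot, 1) * mean_tot
  list(u = u, s = s, s_norm = s_norm, mean_total_s = mean_tot)
}

#' Expression-space kNN smoothing of compartment counts
#'
#' Replaces each cell's nuclear and cytoplasmic counts by the mean over the
#' cell and its K nearest neighbors in gene-expression space. Neighbors are
#' defined by Euclidean distance in the first three principal components of
#' the depth-normalized cytoplasmic matrix. `K = 0` is the identity.
#'
#' @param cc Output of [compartment_counts()].
#' @param K Neighbor count (default 30); reduced with a warning when fewer
#'   than `K + 1` cells are available.
#' @return `cc` with `u` and `s` replaced by their smoothed versions (and
#'   `s_norm` recomputed from the smoothed s).
#' @export
normalize_and_smooth <- function(cc, K = 30) {
  n <- nrow(cc$s)
  if (K >= n) {
    warning("fewer than K + 1 cells; K reduced to ", n - 1, call. = FALSE)
    K <- n - 1
  }
  if (K == 0) return(cc)
  emb <- suppressWarnings(standardize_and_embed(cc$s_norm, n_components = 3))
  sc <- emb$scores
  d2 <- as.matrix(stats::dist(sc))^2
  u_s <- cc$u; s_s <- cc$s
  for (i in seq_len(n)) {
    nb <- order(d2[i, ])[seq_len(K + 1)]      # includes self (distance 0)
    u_s[i, ] <- colMeans(cc$u[nb, , drop = FALSE])
    s_s[i, ] <- colMeans(cc$s[nb, , drop = FALSE])
  }
  tot <- rowSums(s_s)
  cc$u <- u_s
  cc$s <- s_s
  cc$s_norm <- s_s / pmax(tot, 1e-12) * mean(tot)
  cc
}

#' Steady-state degradation rates from extreme-quantile cells
#'
#' For each gene, cells in the top and bottom `quantile_fraction` of total
#' (u + s) expression are selected and gamma is fitted as the least-squares
#' slope of u on s through the origin over that subset, consistent with the
#' steady-state velocity model v = u - gamma * s. A gene is flagged reliable
#' when its maximum normalized nuclear or cytoplasmic expression (per-cell
#' depth normalization, scaled to \[0, 1\] by the global maximum) reaches
#' `expression_cutoff`.
#'
#' @param cc (Smoothed) output of [compartment_counts()].
#' @param quantile_fraction Extreme-quantile fraction per side
#'   (default 0.075).
#' @param expression_cutoff Reliability threshold on max normalized
#'   expression (default 0.038).
#' @return A `velocity_model`: list with `gamma` (named vector), `reliable`
#'   (named logical), `quantile_fraction`, `expression_cutoff`.
#' @export
fit_gamma <- function(cc, quantile_fraction = 0.075,
                      expression_cutoff = 0.038) {
  u <- cc$u; s <- cc$s
  genes <- colnames(s)
  total <- u + s
  gamma <- stats::setNames(numeric(length(genes)), genes)
  for (g in genes) {
    tg <- total[, g]
    if (all(tg == 0)) next
    qs <- stats::quantile(tg, c(quantile_fraction, 1 - quantile_fraction))
    sel <- tg <= qs[1] | tg >= qs[2]
    ss <- s[sel, g]; uu <- u[sel, g]
    if (sum(ss^2) == 0) next
    gamma[g] <- max(0, sum(uu * ss) / sum(ss^2))
  }
  # normalized expression on [0,1]: per-cell depth normalization of each
  # compartment, scaled by the global maximum
  norm01 <- function(m) {
    mn <- m / pmax(rowSums(m), 1)
    mx <- max(mn)
    if (mx == 0) mn else mn / mx
  }
  max_expr <- pmax(apply(norm01(u), 2, max), apply(norm01(s), 2, max))
  reliable <- max_expr >= expression_cutoff & colSums(total) > 0
  structure(
    list(gamma = gamma, reliable = reliable,
         max_normalized_expression = max_expr,
         quantile_fraction = quantile_fraction,
         expression_cutoff = expression_cutoff),
    class = "velocity_model"
  )
}

#' @export
print.velocity_model <- function(x, ...) {
  cat("<velocity_model> ", length(x$gamma), " genes, ",
      sum(x$reliable), " reliable (cutoff ", x$expression_cutoff, ")\n",
      sep = "")
  invisible(x)
}

#' @export
tidy.velocity_model <- function(x, ...) {
  tibble::tibble(gene = names(x$gamma), gamma = unname(x$gamma),
                 reliable = unname(x$reliable[names(x$gamma)]),
                 max_normalized_expression =
                   unname(x$max_normalized_expression[names(x$gamma)]))
}

#' Project future cell states and summarize state changes
#'
#' Velocities v = u - gamma * s are computed per reliable gene; the future
#' spliced state is S(T) = S(0) + v T, floored at zero. Cells whose total
#' future expression deviates by more than 10% from the current total are
#' counted and reported (an error is raised when every cell violates the
#' constraint). Future states are depth-scaled by the mean total, a PCA is
#' fitted on the normalized *current* states, and both current and future
#' states are projected into those fixed axes. Per cell, the magnitude of
#' change (PC1-PC2 distance between S(0) and S(T) projections), the
#' magnitude of the current state (distance from the origin) and the phase
#' (displacement angle, in (-pi, pi], 0 = +PC1) are returned.
#'
#' @param cc (Smoothed) output of [compartment_counts()].
#' @param model A `velocity_model` from [fit_gamma()].
#' @param T_step Time step (default 3). `T_step = 0` gives zero magnitudes.
#' @return List with `state_changes` (tibble `cell_id`,
#'   `magnitude_future`, `magnitude_current`, `phase`), `velocities`
#'   (cells x reliable genes), `scores_current`, `scores_future`,
#'   `n_total_violations`.
#' @export
compute_future_states <- function(cc, model, T_step = 3) {
  genes <- names(model$gamma)[model$reliable[names(model$gamma)]]
  if (length(genes) < 2) stop("fewer than 2 reliable genes", call. = FALSE)
  u <- cc$u[, genes, drop = FALSE]
  s <- cc$s[, genes, drop = FALSE]
  v <- u - sweep(s, 2, model$gamma[genes], `*`)
  sT <- pmax(s + v * T_step, 0)
  tot0 <- rowSums(s)
  totT <- rowSums(sT)
  viol <- sum(abs(totT - tot0) > 0.10 * pmax(tot0, 1e-12))
  if (viol == nrow(s) && T_step > 0) {
    stop("every cell violates the 10% total-expression constraint; ",
         "use a smaller T_step", call. = FALSE)
  }
  norm_s <- s / pmax(rowSums(s), 1e-12) * mean(rowSums(s))
  norm_sT <- sT / pmax(rowSums(sT), 1e-12) * mean(rowSums(sT))
  emb <- suppressWarnings(standardize_and_embed(norm_s, n_components = 2))
  kept <- colnames(emb$standardized)
  ctr <- colMeans(norm_s[, kept, drop = FALSE])
  sdv <- apply(norm_s[, kept, drop = FALSE], 2, stats::sd)
  zT <- sweep(sweep(norm_sT[, kept, drop = FALSE], 2, ctr), 2, sdv, `/`)
  p0 <- emb$scores
  pT <- zT %*% emb$loadings
  disp <- pT - p0
  tibble_out <- tibble::tibble(
    cell_id = rownames(s),
    magnitude_future = sqrt(rowSums(disp^2)),
    magnitude_current = sqrt(rowSums(p0^2)),
    phase = atan2(disp[, 2], disp[, 1])
  )
  list(state_changes = tibble_out, velocities = v,
       scores_current = p0, scores_future = pT,
       n_total_violations = viol)
}

#' Distance correlations of state-change magnitude and phase
#'
#' For a primary / neighbor cell-type pair, correlates each primary cell's
#' minimum boundary distance to the neighbor type with (i) the magnitude of
#' its predicted state change, (ii) the magnitude of its current state
#' (Pearson, permutation p via distance shuffles), and (iii) the phase of
#' the change (circular-linear correlation with the same permutation null,
#' upper tail).
#'
#' @param state_changes Tibble from [compute_future_states()].
#' @param sample The annotated `tissue_sample` the states came from.
#' @param primary_type,neighbor_type Cell types (distinct).
#' @param n_perm Distance shuffles (default 10000).
#' @param seed Integer seed.
#' @return Tibble with one row per response (`magnitude_future`,
#'   `magnitude_current`, `phase`): `r`, `p`, `n_cells`; or `NULL` when
#'   fewer than 3 primary cells have a defined distance.
#' @export
distance_state_correlations <- function(state_changes, sample, primary_type,
                                        neighbor_type, n_perm = 10000,
                                        seed = 1) {
  ct <- sample$cells
  ids <- intersect(
    state_changes$cell_id,
    ct$cell_id[!is.na(ct$type_label) & ct$type_label == primary_type])
  d <- min_distance_to_type(sample, neighbor_type, cells = ids,
                            scope = "tissue")
  ok <- !is.na(d$distance)
  if (sum(ok) < 3) return(NULL)
  dist_v <- d$distance[ok]
  sc <- state_changes[match(d$cell_id[ok], state_changes$cell_id), ]
  rows <- list()
  for (resp in c("magnitude_future", "magnitude_current")) {
    y <- sc[[resp]]
    ct_res <- correlation_with_permutation(dist_v, y, n_perm = n_perm,
                                           seed = seed)
    rows[[resp]] <- tibble::tibble(
      response = resp,
      r = ct_res$r,
      p = if (is.null(ct_res$test)) NA_real_ else ct_res$test$p,
      n_cells = sum(ok))
  }
  # phase: circular-linear association, permutation upper tail
  if (stats::sd(dist_v) > 0 && stats::sd(sc$phase) > 0) {
    r_obs <- .circ_lin_cor(sc$phase, dist_v)
    null_r <- withr::with_seed(seed + 1L, {
      vapply(seq_len(n_perm), function(i) {
        .circ_lin_cor(sc$phase, sample(dist_v))
      }, numeric(1))
    })
    pt <- normal_approx_p(r_obs, null_r, tail = "upper",
                          n_permutations = n_perm, seed = seed + 1L)
    rows$phase <- tibble::tibble(response = "phase", r = r_obs, p = pt$p,
                                 n_cells = sum(ok))
  }
  dplyr::bind_rows(rows) |>
    dplyr::mutate(primary_type = primary_type,
                  neighbor_type = neighbor_type, .before = 1)
}

#' Gene-level velocity-distance correlations
#'
#' Pearson correlation of each reliable gene's velocity across primary cells
#' with the minimum distance to the neighbor type; BH adjustment within the
#' pair. Genes detected in fewer than `min_detect_frac` of matched
#' single-cell reference cells of the primary type are removed, except genes
#' named in `keep_exceptions`. Constant-velocity genes are dropped with a
#' flag.
#'
#' @param velocities Cells x genes velocity matrix
#'   (from [compute_future_states()]).
#' @param distances Tibble `cell_id`, `distance` (e.g. from
#'   [min_distance_to_type()]).
#' @param reference_detection Optional tibble `gene`, `detect_frac`.
#' @param min_detect_frac Reference detection threshold (default 0.20).
#' @param keep_exceptions Genes exempt from the reference filter.
#' @return Tibble: `gene`, `r`, `p`, `q`, `n_cells`, `dropped_constant`.
#' @export
gene_velocity_correlations <- function(velocities, distances,
                                       reference_detection = NULL,
                                       min_detect_frac = 0.20,
                                       keep_exceptions = character()) {
  ok <- !is.na(distances$distance) &
    distances$cell_id %in% rownames(velocities)
  d <- distances[ok, ]
  v <- velocities[d$cell_id, , drop = FALSE]
  genes <- colnames(v)
  if (!is.null(reference_detection)) {
    low <- reference_detection$gene[
      reference_detection$detect_frac < min_detect_frac]
    genes <- setdiff(genes, setdiff(low, keep_exceptions))
  }
  rows <- purrr::map(genes, function(g) {
    vg <- v[, g]
    if (stats::sd(vg) == 0 || stats::sd(d$distance) == 0) {
      return(tibble::tibble(gene = g, r = NA_real_, p = NA_real_,
                            n_cells = nrow(d), dropped_constant = TRUE))
    }
    ct <- stats::cor.test(d$distance, vg)
    tibble::tibble(gene = g, r = unname(ct$estimate), p = ct$p.value,
                   n_cells = nrow(d), dropped_constant = FALSE)
  })
  out <- dplyr::bind_rows(rows)
  out$q <- NA_real_
  keep <- !out$dropped_constant
  out$q[keep] <- bh_adjust(out$p[keep])
  out
}
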