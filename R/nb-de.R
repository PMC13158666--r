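#' Median-of-ratios size factors
#'
#' Per-cell size factors computed against a geometric-mean pseudo-reference,
#' using genes with all-positive counts. If no gene is positive in every
#' cell (common in sparse panels, where the median-of-ratios estimator has
#' no stable reference), total-count scaling is used instead.
#'
#' @param counts Integer matrix, cells x genes.
#' @return Numeric vector of positive size factors, one per cell, scaled to
#'   geometric mean 1.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  lg <- log(counts)
  loggeo <- colMeans(lg)                       # -Inf for genes with any zero
  # the ratio median needs a reasonably sized reference set; with almost
  # every panel gene hitting zeros, fall back to total-count scaling
  if (sum(is.finite(loggeo)) < 10) {
    tot <- rowSums(counts)
    if (any(tot == 0)) stop("a cell has zero total counts", call. = FALSE)
    return(tot / exp(mean(log(tot))))
  }
  sf <- apply(counts, 1, function(row) {
    r <- (log(row) - loggeo)
    r <- r[is.finite(loggeo) & is.finite(r) & row > 0]
    if (length(r) == 0) return(NA_real_)
    exp(stats::median(r))
  })
  if (anyNA(sf)) stop("a cell has zero counts on every reference gene",
                      call. = FALSE)
  sf / exp(mean(log(sf)))
}

# Gene-wise method-of-moments NB dispersions shrunk toward a fitted
# mean-dispersion trend a0 + a1/mu (log-scale midpoint between the gene-wise
# estimate and the trend). When group labels are supplied, moments are taken
# within groups (pooled with df weights) so true between-group differences
# do not inflate the dispersion. Estimated once from the observed labels and
# reused across permutation reruns.
.trended_dispersions <- function(counts, sf, groups = NULL) {
  q <- sweep(counts, 1, sf, `/`)
  mu <- colMeans(q)
  if (is.null(groups)) {
    v <- apply(q, 2, stats::var)
    xim <- mean(1 / sf)
    disp_raw <- (v - xim * mu) / mu^2
  } else {
    groups <- as.factor(groups)
    num <- 0; den <- 0
    for (g in levels(groups)) {
      sel <- groups == g
      if (sum(sel) < 2) next
      mu_g <- colMeans(q[sel, , drop = FALSE])
      v_g <- apply(q[sel, , drop = FALSE], 2, stats::var)
      xim_g <- mean(1 / sf[sel])
      w <- sum(sel) - 1
      num <- num + w * (v_g - xim_g * mu_g) / pmax(mu_g, 1e-8)^2
      den <- den + w
    }
    disp_raw <- num / den
  }
  disp_raw[!is.finite(disp_raw)] <- NA
  ok <- !is.na(disp_raw) & disp_raw > 1e-6 & mu > 0
  if (sum(ok) >= 3) {
    fit <- stats::lm(disp_raw[ok] ~ I(1 / mu[ok]))
    co <- stats::coef(fit)
    trend <- pmax(1e-6, co[1] + co[2] / mu)
  } else {
    trend <- rep(stats::median(disp_raw[ok], na.rm = TRUE) %||% 0.1,
                 length(mu))
    trend[!is.finite(trend)] <- 0.1
  }
  disp <- ifelse(ok, exp((log(pmax(disp_raw, 1e-8)) + log(trend)) / 2), trend)
  pmin(pmax(disp, 1e-8), 10)
}

# Vectorised Newton solve (over genes) for the NB log-mean of one group with
# per-cell exposure sf and per-gene dispersion alpha: root of
# sum_i (y_i - mu_i) / (1 + alpha mu_i), mu_i = sf_i exp(eta).
.nb_group_means <- function(counts, sf, alpha) {
  tot <- colSums(counts)
  eta <- log(pmax(tot, 0.5) / sum(sf))
  for (it in 1:50) {
    mu <- outer(sf, exp(eta))                  # cells x genes
    denom <- 1 + sweep(mu, 2, alpha, `*`)
    f <- colSums((counts - mu) / denom)
    fp <- -colSums(mu * (1 + sweep(counts, 2, alpha, `*`)) / denom^2)
    step <- f / fp
    step[!is.finite(step)] <- 0
    step <- pmax(pmin(step, 2), -2)
    eta <- eta - step
    if (max(abs(step)) < 1e-10) break
  }
  eta[tot == 0] <- log(1e-8)
  eta
}

#' Negative-binomial Wald differential expression between two cell groups
#'
#' A compact NB differential-expression engine for targeted panels:
#' median-of-ratios size factors, gene-wise method-of-moments dispersions
#' (pooled within the condition groups, so genuine between-group
#' differences do not masquerade as overdispersion) shrunk toward a
#' mean-dispersion trend, and a Wald test on the two-level
#' condition coefficient of a log-link NB model (group log-means fitted by
#' Newton iteration with size-factor exposures; the Wald standard error comes
#' from the observed Fisher information). Genes with zero counts everywhere
#' are excluded and recorded in the `excluded` attribute.
#'
#' @param counts Integer matrix, cells x genes.
#' @param labels Binary vector/factor over cells; the contrast is
#'   level2 - level1 on the log2 scale.
#' @return Tibble: `gene`, `base_mean`, `log2FC`, `stat`, `p_nominal`,
#'   `q_nominal`. Attribute `dispersions` holds the fitted dispersions.
#' @export
nb_de <- function(counts, labels) {
  counts <- as.matrix(counts)
  labels <- as.factor(labels)
  stopifnot(nlevels(labels) == 2, length(labels) == nrow(counts))
  g1 <- labels == levels(labels)[1]
  g2 <- !g1
  if (sum(g1) < 2 || sum(g2) < 2) stop("need >= 2 cells per group", call. = FALSE)
  if (sum(counts[g1, ]) == 0 || sum(counts[g2, ]) == 0) {
    stop("a group has zero total counts", call. = FALSE)
  }
  all_zero <- colSums(counts) == 0
  kept <- counts[, !all_zero, drop = FALSE]
  sf <- size_factors(kept)
  alpha <- .trended_dispersions(kept, sf, groups = labels)
  res <- .nb_wald(kept, g1, g2, sf, alpha)
  res$q_nominal <- bh_adjust(res$p_nominal)
  attr(res, "dispersions") <- alpha
  attr(res, "excluded") <- colnames(counts)[all_zero]
  attr(res, "size_factors") <- sf
  res
}

.nb_wald <- function(counts, g1, g2, sf, alpha) {
  eta1 <- .nb_group_means(counts[g1, , drop = FALSE], sf[g1], alpha)
  eta2 <- .nb_group_means(counts[g2, , drop = FALSE], sf[g2], alpha)
  info <- function(gsel, eta) {
    mu <- outer(sf[gsel], exp(eta))
    colSums(mu / (1 + sweep(mu, 2, alpha, `*`)))
  }
  se <- sqrt(1 / info(g1, eta1) + 1 / info(g2, eta2))
  beta <- eta2 - eta1
  stat <- beta / se
  stat[!is.finite(stat)] <- 0
  q <- sweep(counts, 1, sf, `/`)
  tibble::tibble(
    gene = colnames(counts),
    base_mean = colMeans(q),
    log2FC = beta / log(2),
    stat = stat,
    p_nominal = 2 * stats::pnorm(abs(stat), lower.tail = FALSE)
  )
}

#' Label-permutation wrapper around the NB DE engine
#'
#' Runs [nb_de()] on the real labels, then re-runs the Wald fit on `n_perm`
#' random label shuffles (dispersions and size factors are label-free and
#' reused). The per-gene empirical p-value is
#' `(1 + #permutations with |stat| >= |observed|) / (n_perm + 1)`; both the
#' nominal and the permutation p-values are BH-adjusted. Genes also receive a
#' `passes_lfc` flag for `|log2FC| >= lfc_threshold`.
#'
#' @inheritParams nb_de
#' @param n_perm Number of label shuffles (default 1000).
#' @param seed Integer seed.
#' @param lfc_threshold Absolute log2 fold-change report filter (default 1).
#' @return Tibble as [nb_de()] plus `p_perm`, `q_perm`, `passes_lfc`.
#' @export
permutation_de <- function(counts, labels, n_perm = 1000, seed = 1,
                           lfc_threshold = 1) {
  counts <- as.matrix(counts)
  labels <- as.factor(labels)
  obs <- nb_de(counts, labels)
  kept <- counts[, colSums(counts) > 0, drop = FALSE]
  sf <- attr(obs, "size_factors")
  alpha <- attr(obs, "dispersions")
  n1 <- sum(labels == levels(labels)[1])
  exceed <- integer(nrow(obs))
  withr::with_seed(seed, {
    for (b in seq_len(n_perm)) {
      idx <- sample.int(length(labels), n1)
      p1 <- seq_along(labels) %in% idx
      st <- .nb_wald(kept, p1, !p1, sf, alpha)$stat
      exceed <- exceed + (abs(st) >= abs(obs$stat))
    }
  })
  obs$p_perm <- (1 + exceed) / (n_perm + 1)
  obs$q_perm <- bh_adjust(obs$p_perm)
  obs$passes_lfc <- abs(obs$log2FC) >= lfc_threshold
  obs
}

#' Permutation test for overlap of two gene sets against a background
#'
#' Samples random gene sets of the two observed sizes from the background
#' `n_perm` times, recomputes the intersection, and reports the add-one
#' smoothed upper-tail p-value for the observed intersection size.
#'
#' @param set_a,set_b Character vectors (subsets of `background`).
#' @param background Character vector of all eligible genes.
#' @param n_perm Number of resamples (default 100000).
#' @param seed Integer seed.
#' @return Tibble: `n_a`, `n_b`, `intersection_size`, `intersection`
#'   (list-column), `p`.
#' @export
cross_tissue_overlap <- function(set_a, set_b, background, n_perm = 1e5,
                                 seed = 1) {
  if (length(background) == 0) stop("empty background", call. = FALSE)
  stopifnot(all(set_a %in% background), all(set_b %in% background))
  obs <- length(intersect(set_a, set_b))
  n <- length(background)
  na <- length(set_a); nb <- length(set_b)
  hits <- withr::with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      a <- sample.int(n, na)
      b <- sample.int(n, nb)
      sum(a %in% b) >= obs
    }, logical(1)))
  })
  tibble::tibble(
    n_a = na, n_b = nb, intersection_size = obs,
    intersection = list(intersect(set_a, set_b)),
    p = (1 + hits) / (n_perm + 1)
  )
}

#' Build a triplet contrast: focal cells near one versus two neighbor types
#'
#' Pools annotated samples and splits focal type-`type_a` cells into
#' condition 1 (proximal to at least one `type_b` cell and to no `type_c`
#' cell) and condition 2 (proximal to both types), using boundary-distance
#' proximity at `threshold`. The contrast is valid only with at least
#' `min_cells` cells in each condition.
#'
#' @param samples A `tissue_sample` or list of annotated samples.
#' @param type_a,type_b,type_c Focal and neighbor cell types.
#' @param threshold Proximity threshold in micrometres (default 1).
#' @param min_cells Minimum cells per condition (default 5).
#' @return List of class `triplet_contrast` with pooled `counts`, `labels`
#'   (`"B_only"` / `"B_and_C"`), the id sets, and `valid`.
#' @export
build_triplet_contrast <- function(samples, type_a, type_b, type_c,
                                   threshold = 1, min_cells = 5) {
  if (inherits(samples, "tissue_sample")) samples <- list(samples)
  cond1 <- list(); cond2 <- list()
  for (s in samples) {
    if (!all(c(type_a, type_b, type_c) %in% cell_types(s))) next
    ct <- s$cells
    ids <- ct$cell_id[!is.na(ct$type_label) & ct$type_label == type_a]
    if (length(ids) == 0) next
    db <- min_distance_to_type(s, type_b, cells = ids, scope = "tissue")
    dc <- min_distance_to_type(s, type_c, cells = ids, scope = "tissue")
    near_b <- !is.na(db$distance) & db$distance <= threshold
    near_c <- !is.na(dc$distance) & dc$distance <= threshold
    c1 <- ids[near_b & !near_c]
    c2 <- ids[near_b & near_c]
    if (length(c1) > 0) cond1[[length(cond1) + 1]] <- s$counts[c1, , drop = FALSE]
    if (length(c2) > 0) cond2[[length(cond2) + 1]] <- s$counts[c2, , drop = FALSE]
  }
  n1 <- sum(vapply(cond1, nrow, integer(1)))
  n2 <- sum(vapply(cond2, nrow, integer(1)))
  valid <- n1 >= min_cells && n2 >= min_cells
  counts <- NULL; labels <- NULL
  if (valid) {
    genes <- Reduce(intersect, lapply(c(cond1, cond2), colnames))
    counts <- do.call(rbind, c(lapply(cond1, function(m) m[, genes, drop = FALSE]),
                               lapply(cond2, function(m) m[, genes, drop = FALSE])))
    labels <- factor(rep(c("B_only", "B_and_C"), c(n1, n2)),
                     levels = c("B_only", "B_and_C"))
  }
  structure(
    list(type_a = type_a, type_b = type_b, type_c = type_c,
         threshold = threshold, n_condition1 = n1, n_condition2 = n2,
         counts = counts, labels = labels, valid = valid),
    class = "triplet_contrast"
  )
}

#' @export
print.triplet_contrast <- function(x, ...) {
  cat("<triplet_contrast> ", x$type_a, " near ", x$type_b, " only (n=",
      x$n_condition1, ") vs near ", x$type_b, "+", x$type_c, " (n=",
      x$n_condition2, ")", if (!x$valid) "  [invalid]", "\n", sep = "")
  invisible(x)
}

#' Differential expression for a triplet contrast
#'
#' Runs [permutation_de()] on a valid [build_triplet_contrast()] result.
#'
#' @param contrast A `triplet_contrast`.
#' @inheritParams permutation_de
#' @return DE tibble, or `NULL` (with a message) for an invalid contrast.
#' @export
triplet_de <- function(contrast, n_perm = 1000, seed = 1, lfc_threshold = 1) {
  stopifnot(inherits(contrast, "triplet_contrast"))
  if (!contrast$valid) {
    message("triplet contrast invalid (needs >= 5 cells per condition); skipped")
    return(NULL)
  }
  permutation_de(contrast$counts, contrast$labels, n_perm = n_perm,
                 seed = seed, lfc_threshold = lfc_threshold)
}
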