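#' Standardized -log10(p) program matrix across tissue profiles
#'
#' Builds the profiles-by-genes matrix used for cross-tissue program
#' comparison: genes are restricted to those expressed in every profile,
#' exact zero p-values are replaced by 0.8 x the global minimum nonzero
#' p-value, p-values are transformed to -log10, and each gene (column) is
#' z-scored across profiles.
#'
#' @param de_tbl Tibble with columns `profile_id`, `gene`, `p` and optional
#'   logical `expressed` (default: `!is.na(p)`). One row per profile x gene.
#' @return Numeric matrix (profiles x genes), z-scored per gene. Attribute
#'   `zero_replacement` records the value substituted for exact zeros (NA
#'   when none occurred).
#' @export
build_program_matrix <- function(de_tbl) {
  stopifnot(all(c("profile_id", "gene", "p") %in% names(de_tbl)))
  if (!"expressed" %in% names(de_tbl)) de_tbl$expressed <- !is.na(de_tbl$p)
  n_prof <- dplyr::n_distinct(de_tbl$profile_id)
  if (n_prof < 3) stop("need at least 3 profiles", call. = FALSE)
  common <- de_tbl |>
    dplyr::filter(.data$expressed) |>
    dplyr::count(.data$gene) |>
    dplyr::filter(.data$n == n_prof) |>
    dplyr::pull(.data$gene)
  if (length(common) == 0) {
    stop("no gene is expressed in every profile", call. = FALSE)
  }
  sub <- dplyr::filter(de_tbl, .data$gene %in% common)
  zr <- NA_real_
  if (any(sub$p == 0)) {
    zr <- 0.8 * min(sub$p[sub$p > 0])
    sub$p[sub$p == 0] <- zr
  }
  wide <- sub |>
    dplyr::mutate(nlp = -log10(.data$p)) |>
    dplyr::select("profile_id", "gene", "nlp") |>
    tidyr::pivot_wider(names_from = "gene", values_from = "nlp")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$profile_id
  sds <- apply(m, 2, stats::sd)
  m <- m[, sds > 0, drop = FALSE]
  z <- scale(m)
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  attr(z, "zero_replacement") <- zr
  z
}

# PCA of an already per-gene standardized matrix, with the deterministic
# largest-loading-positive sign convention.
.program_pca <- function(z, k = 2) {
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  k <- min(k, ncol(pc$rotation))
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  flip <- vapply(seq_len(k), function(j) {
    v <- rot[, j]; s <- sign(v[which.max(abs(v))]); if (s == 0) 1 else s
  }, numeric(1))
  rot <- sweep(rot, 2, flip, `*`)
  ev <- pc$sdev^2
  list(scores = z %*% rot, explained = (ev / sum(ev))[seq_len(k)])
}

# shuffle each column independently across rows
.shuffle_columns <- function(z) {
  apply(z, 2, sample)
}

#' Permutation significance of program-matrix principal components
#'
#' Shuffles values within each gene across profiles `n_perm` times,
#' recomputes the PCA each time, and reports a normal-approximation
#' upper-tail p-value on each component's explained-variance fraction.
#'
#' @param z Matrix from [build_program_matrix()].
#' @param n_components Components to test (default 2).
#' @param n_perm Shuffles (default 10000).
#' @param seed Integer seed.
#' @return Tibble: `component`, `explained`, `p`.
#' @export
embedding_significance <- function(z, n_components = 2, n_perm = 10000,
                                   seed = 1) {
  obs <- .program_pca(z, k = n_components)
  k <- length(obs$explained)
  perm <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      .program_pca(.shuffle_columns(z), k = k)$explained
    }, numeric(k))
  })
  perm <- matrix(perm, nrow = k)
  purrr::map_dfr(seq_len(k), function(j) {
    pt <- normal_approx_p(obs$explained[j], perm[j, ], tail = "upper",
                          n_permutations = n_perm, seed = seed)
    tibble::tibble(component = j, explained = obs$explained[j], p = pt$p)
  })
}

# affine map of each permuted PC axis [min,max] onto the observed [min,max]
.rescale_axes <- function(perm_scores, obs_scores) {
  for (j in seq_len(ncol(perm_scores))) {
    pr <- range(perm_scores[, j]); ob <- range(obs_scores[, j])
    if (diff(pr) == 0) {
      perm_scores[, j] <- mean(ob)
    } else {
      perm_scores[, j] <- (perm_scores[, j] - pr[1]) / diff(pr) *
        diff(ob) + ob[1]
    }
  }
  perm_scores
}

#' Paired or group distance permutation test in program PC1-PC2 space
#'
#' Tests whether named profiles sit closer in PC1-PC2 space than expected
#' under gene-wise shuffling. The statistic is the mean Euclidean distance
#' over the given pairs (`pairs` mode, e.g. the same tissue measured on two
#' platforms) or the mean pairwise distance among the group members
#' (`group` mode, e.g. tissues sharing a receptor status). Each permutation
#' shuffles every gene across profiles, re-standardizes, recomputes the
#' PCA, affinely rescales each permuted PC axis to the observed axis range,
#' and recomputes the statistic; the p-value is the lower normal tail
#' (closer than chance).
#'
#' @param z Matrix from [build_program_matrix()].
#' @param pairs Two-column data frame of profile-id pairs (pairs mode).
#' @param group Character vector of profile ids (group mode; >= 2).
#' @param n_perm Shuffles (default 10000).
#' @param seed Integer seed.
#' @return A `permutation_test` (lower tail) with the observed mean
#'   distance as the statistic.
#' @export
program_distance_test <- function(z, pairs = NULL, group = NULL,
                                  n_perm = 10000, seed = 1) {
  stopifnot(xor(is.null(pairs), is.null(group)))
  ids <- rownames(z)
  if (!is.null(pairs)) {
    pairs <- as.data.frame(pairs)
    bad <- setdiff(unique(c(pairs[[1]], pairs[[2]])), ids)
    if (length(bad) > 0) {
      stop("unmatched profile id(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    stat_fun <- function(sc) {
      mean(vapply(seq_len(nrow(pairs)), function(i) {
        sqrt(sum((sc[pairs[i, 1], ] - sc[pairs[i, 2], ])^2))
      }, numeric(1)))
    }
  } else {
    stopifnot(length(group) >= 2, all(group %in% ids))
    stat_fun <- function(sc) {
      g <- sc[group, , drop = FALSE]
      mean(stats::dist(g))
    }
  }
  obs_pca <- .program_pca(z, k = 2)
  obs_stat <- stat_fun(obs_pca$scores)
  null_stats <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      zp <- .shuffle_columns(z)
      rownames(zp) <- ids
      # per-gene shuffling preserves each column's mean/sd, so the matrix
      # stays standardized; re-PCA and rescale axes to the observed scale
      pp <- .program_pca(zp, k = 2)
      sc <- .rescale_axes(pp$scores, obs_pca$scores)
      rownames(sc) <- ids
      stat_fun(sc)
    }, numeric(1))
  })
  normal_approx_p(obs_stat, null_stats, tail = "lower",
                  n_permutations = n_perm, seed = seed)
}
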