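#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment. Thin wrapper over
#' [stats::p.adjust()] kept as the single adjustment point for the whole
#' package, so every consumer shares one definition of `q`.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  stopifnot(is.numeric(p), all(is.finite(p)), all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "BH")
}

#' Normal-approximation permutation p-value
#'
#' Fits a normal distribution to a vector of permutation-null statistics and
#' returns the tail probability of the observed statistic under that fit.
#' With a degenerate null (`sd = 0`) the p-value is 0.5 at the mean and 0/1
#' beyond it (by tail side), with a warning.
#'
#' @param observed Observed statistic (finite scalar).
#' @param null_samples Numeric vector of permuted statistics (length >= 2).
#' @param tail `"upper"` (P of an equal-or-greater value) or `"lower"`.
#' @param n_permutations,seed Optional bookkeeping recorded in the result.
#' @return A `permutation_test` object: list with `observed`, `null_mean`,
#'   `null_sd`, `z`, `p`, `tail`, `n_permutations`, `seed`.
#' @export
normal_approx_p <- function(observed, null_samples, tail = c("upper", "lower"),
                            n_permutations = length(null_samples), seed = NA_integer_) {
  tail <- match.arg(tail)
  stopifnot(is.finite(observed), length(null_samples) >= 2)
  m <- mean(null_samples)
  s <- stats::sd(null_samples)
  if (s == 0) {
    warning("degenerate permutation null (sd = 0)", call. = FALSE)
    z <- if (observed == m) 0 else sign(observed - m) * Inf
    p <- if (observed == m) 0.5 else {
      hi <- observed > m
      if ((tail == "upper") == hi) 0 else 1
    }
  } else {
    z <- (observed - m) / s
    p <- stats::pnorm(z, lower.tail = (tail == "lower"))
  }
  structure(
    list(observed = observed, null_mean = m, null_sd = s, z = z, p = p,
         tail = tail, n_permutations = n_permutations, seed = seed),
    class = "permutation_test"
  )
}

#' @export
print.permutation_test <- function(x, ...) {
  cat("<permutation_test> observed = ", signif(x$observed, 4),
      ", null ", signif(x$null_mean, 4), " +/- ", signif(x$null_sd, 4),
      ", z = ", signif(x$z, 3), ", p(", x$tail, ") = ",
      format(x$p, digits = 3), "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.permutation_test <- function(x, ...) {
  tibble::tibble(observed = x$observed, null_mean = x$null_mean,
                 null_sd = x$null_sd, z = x$z, p = x$p, tail = x$tail,
                 n_permutations = x$n_permutations)
}

#' @export
glance.permutation_test <- function(x, ...) tidy(x)

#' Exact upper binomial tail
#'
#' P(X >= k) for X ~ Binomial(n, p0), evaluated in log space so that
#' astronomically small tails (e.g. 1e-73) do not underflow.
#'
#' @param k,n Integers with 0 <= k <= n.
#' @param p0 Success probability in \[0, 1\].
#' @param log10_out If `TRUE`, return log10 of the tail probability.
#' @return The tail probability (or its log10).
#' @export
binomial_tail <- function(k, n, p0, log10_out = FALSE) {
  stopifnot(k >= 0, k <= n, p0 >= 0, p0 <= 1)
  if (k == 0) return(if (log10_out) 0 else 1)
  lp <- stats::pbinom(k - 1, n, p0, lower.tail = FALSE, log.p = TRUE)
  if (log10_out) lp / log(10) else exp(lp)
}

#' Per-feature z-scoring followed by PCA
#'
#' Columns (features) are standardized to mean 0 / sd 1 across rows (samples),
#' then projected by principal component analysis. Zero-variance features are
#' dropped with a warning. Each component's loading vector is sign-flipped so
#' that its largest-magnitude entry is positive, making scores reproducible.
#'
#' @param x Numeric matrix, rows = samples, columns = features.
#' @param n_components Number of components to keep (default
#'   `min(dim(x)) - 1` capped at the feature count).
#' @return A list of class `pc_embedding`: `scores` (samples x components),
#'   `loadings`, `explained` (variance fractions, non-increasing),
#'   `standardized` (the z-scored matrix).
#' @export
standardize_and_embed <- function(x, n_components = NULL) {
  x <- as.matrix(x)
  stopifnot(nrow(x) >= 2)
  sds <- apply(x, 2, stats::sd)
  if (all(sds == 0)) stop("all features are constant", call. = FALSE)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance feature(s) dropped", call. = FALSE)
    x <- x[, sds > 0, drop = FALSE]
  }
  z <- scale(x)
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  k_max <- min(nrow(z) - 1, ncol(z))
  k <- min(n_components %||% k_max, k_max)
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  flip <- vapply(seq_len(k), function(j) {
    v <- rot[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  rot <- sweep(rot, 2, flip, `*`)
  scores <- z %*% rot
  ev <- pc$sdev^2
  structure(
    list(scores = scores, loadings = rot,
         explained = (ev / sum(ev))[seq_len(k)], standardized = z),
    class = "pc_embedding"
  )
}

#' Pearson correlation with a shuffle-based permutation null
#'
#' Computes Pearson's r between `x` and `y` and a permutation p-value from
#' `n_perm` random shuffles of `x`, using the normal approximation to the
#' permuted r distribution.
#'
#' @param x,y Equal-length finite numeric vectors (length >= 3). `x` is the
#'   variable that gets shuffled (e.g. the spatial distances).
#' @param n_perm Number of shuffles (default 1000).
#' @param seed Integer seed for the shuffles.
#' @param tail `"two_sided"` (default, via |z|), `"upper"` or `"lower"`.
#' @return List with `r` and `test` (a `permutation_test` on r; for the
#'   two-sided case `p` is the two-tailed normal probability of `|z|`).
#' @export
correlation_with_permutation <- function(x, y, n_perm = 1000, seed = 1,
                                         tail = c("two_sided", "upper", "lower")) {
  tail <- match.arg(tail)
  stopifnot(length(x) == length(y), length(x) >= 3,
            all(is.finite(x)), all(is.finite(y)))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, test = NULL, degenerate = TRUE))
  }
  r <- stats::cor(x, y)
  null_r <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) stats::cor(sample(x), y), numeric(1))
  })
  if (tail == "two_sided") {
    t1 <- normal_approx_p(r, null_r, tail = "upper",
                          n_permutations = n_perm, seed = seed)
    t1$p <- 2 * stats::pnorm(abs(t1$z), lower.tail = FALSE)
    t1$tail <- "two_sided"
    list(r = r, test = t1, degenerate = FALSE)
  } else {
    list(r = r,
         test = normal_approx_p(r, null_r, tail = tail,
                                n_permutations = n_perm, seed = seed),
         degenerate = FALSE)
  }
}

# circular-linear correlation (Mardia): used for phase-vs-distance tests
.circ_lin_cor <- function(theta, x) {
  rxc <- stats::cor(x, cos(theta))
  rxs <- stats::cor(x, sin(theta))
  rcs <- stats::cor(cos(theta), sin(theta))
  num <- rxc^2 + rxs^2 - 2 * rxc * rxs * rcs
  sqrt(max(0, num / (1 - rcs^2)))
}
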