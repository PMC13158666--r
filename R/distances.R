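#' @keywords internal
#' Squared-distance free cross minimum: smallest Euclidean distance between
#' any row of A and any row of B (n x 3, m x 3 matrices).
.cross_min_dist <- function(A, B) {
  d2 <- matrix(rowSums(A^2), nrow(A), nrow(B)) +
    matrix(rowSums(B^2), nrow(A), nrow(B), byrow = TRUE) -
    2 * tcrossprod(A, B)
  sqrt(max(0, min(d2)))
}

# Per-cell transcript coordinate matrices (host + bacterial alike; the cell
# boundary is implied by everything assigned to the cell).
.cell_coord_list <- function(sample, ids) {
  tx <- sample$transcripts
  tx <- tx[!is.na(tx$cell_id) & tx$cell_id %in% ids, , drop = FALSE]
  m <- cbind(tx$x, tx$y, tx$z)
  split.data.frame(m, factor(tx$cell_id, levels = ids))
}

#' Distance between two cells
#'
#' Boundary convention: minimal 3D Euclidean distance between any transcript
#' of one cell and any transcript of the other. Centroid convention: distance
#' between the two cell centroids.
#'
#' @param sample A `tissue_sample`.
#' @param a,b Cell ids (must differ; both must carry at least one transcript).
#' @param convention `"boundary"` or `"centroid"`; defaults to the sample's.
#' @return Distance in micrometres (non-negative scalar).
#' @export
pair_distance <- function(sample, a, b, convention = NULL) {
  stopifnot(inherits(sample, "tissue_sample"), a != b)
  convention <- (convention %||% sample$distance_convention)
  convention <- match.arg(convention, c("boundary", "centroid"))
  if (convention == "centroid") {
    ca <- sample$cells[sample$cells$cell_id == a, c("x", "y", "z")]
    cb <- sample$cells[sample$cells$cell_id == b, c("x", "y", "z")]
    if (nrow(ca) == 0 || nrow(cb) == 0) stop("unknown cell id", call. = FALSE)
    return(sqrt(sum((as.numeric(ca) - as.numeric(cb))^2)))
  }
  coords <- .cell_coord_list(sample, c(a, b))
  if (nrow(coords[[1]]) == 0 || nrow(coords[[2]]) == 0) {
    stop("both cells must have at least one transcript", call. = FALSE)
  }
  .cross_min_dist(coords[[1]], coords[[2]])
}

# Vectorised nearest-of-type distances. Returns a tibble cell_id/distance with
# NA where no eligible target exists (or nearest exceeds `cap`). `scope`
# restricts candidate targets to the query cell's FOV.
#
# Boundary convention uses a branch-and-bound over candidate target cells:
# the true boundary distance is bounded below by
# centroid distance - r_query - r_target (r = max transcript radius), so
# candidates are visited in lower-bound order and the scan stops as soon as
# the bound passes the current best.
.nearest_type_distance <- function(sample, target_type, cells = NULL,
                                   scope = c("tissue", "same_fov"),
                                   cap = NULL, exclude_self = TRUE) {
  scope <- match.arg(scope)
  cap <- cap %||% sample$distance_cap
  ct <- sample$cells
  known <- cell_types(sample)
  if (!target_type %in% known) {
    stop("unknown cell type '", target_type, "'; known types: ",
         paste(known, collapse = ", "), call. = FALSE)
  }
  query_ids <- cells %||% ct$cell_id
  targets <- ct[!is.na(ct$type_label) & ct$type_label == target_type, , drop = FALSE]

  if (sample$distance_convention == "centroid") {
    qi <- match(query_ids, ct$cell_id)
    Q <- cbind(ct$x, ct$y, ct$z)[qi, , drop = FALSE]
    Tm <- cbind(targets$x, targets$y, targets$z)
    out <- rep(NA_real_, length(query_ids))
    for (i in seq_along(query_ids)) {
      cand <- targets
      ok <- rep(TRUE, nrow(cand))
      if (scope == "same_fov") ok <- cand$fov_id == ct$fov_id[qi[i]]
      if (exclude_self) ok <- ok & cand$cell_id != query_ids[i]
      if (!any(ok)) next
      d <- sqrt(colSums((t(Tm[ok, , drop = FALSE]) - Q[i, ])^2))
      out[i] <- min(d)
    }
    if (!is.na(cap)) out[!is.na(out) & out > cap] <- NA_real_
    return(tibble::tibble(cell_id = query_ids, distance = out))
  }

  # boundary convention
  all_ids <- union(query_ids, targets$cell_id)
  coords <- .cell_coord_list(sample, all_ids)
  radius <- vapply(all_ids, function(id) {
    m <- coords[[id]]
    if (nrow(m) == 0) return(0)
    ctr <- colMeans(m)
    sqrt(max(rowSums((m - matrix(ctr, nrow(m), 3, byrow = TRUE))^2)))
  }, numeric(1))
  names(radius) <- all_ids
  ci <- match(all_ids, ct$cell_id)
  ctrm <- cbind(ct$x, ct$y, ct$z)[ci, , drop = FALSE]
  rownames(ctrm) <- all_ids

  out <- rep(NA_real_, length(query_ids))
  for (i in seq_along(query_ids)) {
    qid <- query_ids[i]
    tids <- targets$cell_id
    if (scope == "same_fov") {
      tids <- tids[targets$fov_id == ct$fov_id[ct$cell_id == qid]]
    }
    if (exclude_self) tids <- setdiff(tids, qid)
    if (length(tids) == 0) next
    cd <- sqrt(colSums((t(ctrm[tids, , drop = FALSE]) - ctrm[qid, ])^2))
    lb <- pmax(0, cd - radius[qid] - radius[tids])
    ord <- order(lb)
    best <- Inf
    for (j in ord) {
      if (lb[j] >= best) break
      d <- .cross_min_dist(coords[[qid]], coords[[tids[j]]])
      if (d < best) best <- d
    }
    if (is.finite(best)) out[i] <- best
  }
  if (!is.null(cap) && !is.na(cap)) out[!is.na(out) & out > cap] <- NA_real_
  tibble::tibble(cell_id = query_ids, distance = out)
}

#' Minimum distance from cells to the nearest cell of a target type
#'
#' For each query cell, the smallest [pair_distance()] to any annotated cell
#' of `target_type`, under the sample's distance convention. Centroid-based
#' platforms apply the sample's distance cap (145 um by default): a nearest
#' neighbor beyond the cap yields `NA`, as does the absence of any eligible
#' target in scope.
#'
#' @param sample An annotated `tissue_sample`.
#' @param target_type Cell-type label to search for.
#' @param cells Optional character vector of query cell ids (default: all).
#' @param scope `"tissue"` (default) or `"same_fov"`.
#' @param cap Optional distance cap in micrometres overriding the sample's.
#' @return Tibble with `cell_id` and `distance` (um, `NA` when undefined).
#' @export
min_distance_to_type <- function(sample, target_type, cells = NULL,
                                 scope = c("tissue", "same_fov"), cap = NULL) {
  .nearest_type_distance(sample, target_type, cells = cells,
                         scope = match.arg(scope), cap = cap)
}

#' Stratify one cell type by proximity to another
#'
#' Type-i cells whose boundary distance to the nearest type-ii cell is at most
#' `threshold` (inclusive) are proximal; all others are distant. Every type-i
#' cell lands in exactly one of the two sets.
#'
#' @param sample An annotated `tissue_sample`.
#' @param type_i,type_ii Cell-type labels (the stratified and the reference
#'   type).
#' @param threshold Proximity threshold in micrometres (default 1).
#' @return A list of class `proximity_stratification` with `proximal_ids`,
#'   `distant_ids`, `type_i`, `type_ii`, `threshold` and `analyzable` (TRUE
#'   when both sets are non-empty).
#' @export
stratify_by_proximity <- function(sample, type_i, type_ii, threshold = 1) {
  ct <- sample$cells
  ids_i <- ct$cell_id[!is.na(ct$type_label) & ct$type_label == type_i]
  if (length(ids_i) == 0 || !(type_ii %in% cell_types(sample))) {
    res <- structure(list(type_i = type_i, type_ii = type_ii,
                          threshold = threshold, proximal_ids = character(),
                          distant_ids = ids_i, analyzable = FALSE),
                     class = "proximity_stratification")
    return(res)
  }
  d <- .nearest_type_distance(sample, type_ii, cells = ids_i,
                              scope = "tissue", cap = NA_real_)
  prox <- !is.na(d$distance) & d$distance <= threshold
  structure(
    list(type_i = type_i, type_ii = type_ii, threshold = threshold,
         proximal_ids = d$cell_id[prox], distant_ids = d$cell_id[!prox],
         analyzable = any(prox) && any(!prox)),
    class = "proximity_stratification"
  )
}

#' @export
print.proximity_stratification <- function(x, ...) {
  cat("<proximity_stratification> ", x$type_i, " vs ", x$type_ii,
      " (<= ", x$threshold, " um)\n", sep = "")
  cat("  proximal: ", length(x$proximal_ids),
      "  distant: ", length(x$distant_ids),
      if (!x$analyzable) "  [not analyzable]" else "", "\n", sep = "")
  invisible(x)
}

#' Count neighbors of a target type within a distance cutoff
#'
#' Number of annotated `target_type` cells whose [pair_distance()] to each
#' query cell is at most `cutoff` (inclusive). When counting same-type
#' neighbors the query cell itself is excluded.
#'
#' @param sample An annotated `tissue_sample`.
#' @param target_type Cell-type label of the neighbors.
#' @param cutoff Distance cutoff in micrometres (> 0); default 15.
#' @param cells Optional query cell ids (default: all cells).
#' @return Tibble with `cell_id` and `n_neighbors`.
#' @export
count_neighbors <- function(sample, target_type, cutoff = 15, cells = NULL) {
  stopifnot(cutoff > 0)
  ct <- sample$cells
  known <- cell_types(sample)
  if (!target_type %in% known) {
    stop("unknown cell type '", target_type, "'; known types: ",
         paste(known, collapse = ", "), call. = FALSE)
  }
  query_ids <- cells %||% ct$cell_id
  targets <- ct[!is.na(ct$type_label) & ct$type_label == target_type, , drop = FALSE]

  if (sample$distance_convention == "centroid") {
    qi <- match(query_ids, ct$cell_id)
    Q <- cbind(ct$x, ct$y, ct$z)[qi, , drop = FALSE]
    Tm <- cbind(targets$x, targets$y, targets$z)
    n <- vapply(seq_along(query_ids), function(i) {
      d <- sqrt(colSums((t(Tm) - Q[i, ])^2))
      sum(d <= cutoff & targets$cell_id != query_ids[i])
    }, integer(1))
    return(tibble::tibble(cell_id = query_ids, n_neighbors = n))
  }

  all_ids <- union(query_ids, targets$cell_id)
  coords <- .cell_coord_list(sample, all_ids)
  radius <- vapply(all_ids, function(id) {
    m <- coords[[id]]
    if (nrow(m) == 0) return(0)
    ctr <- colMeans(m)
    sqrt(max(rowSums((m - matrix(ctr, nrow(m), 3, byrow = TRUE))^2)))
  }, numeric(1))
  names(radius) <- all_ids
  ci <- match(all_ids, ct$cell_id)
  ctrm <- cbind(ct$x, ct$y, ct$z)[ci, , drop = FALSE]
  rownames(ctrm) <- all_ids

  n <- integer(length(query_ids))
  for (i in seq_along(query_ids)) {
    qid <- query_ids[i]
    tids <- setdiff(targets$cell_id, qid)
    if (length(tids) == 0) next
    cd <- sqrt(colSums((t(ctrm[tids, , drop = FALSE]) - ctrm[qid, ])^2))
    lb <- pmax(0, cd - radius[qid] - radius[tids])
    cand <- tids[lb <= cutoff]
    n[i] <- sum(vapply(cand, function(tid) {
      .cross_min_dist(coords[[qid]], coords[[tid]]) <= cutoff
    }, logical(1)))
  }
  tibble::tibble(cell_id = query_ids, n_neighbors = n)
}
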