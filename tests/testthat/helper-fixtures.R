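# Shared in-code fixtures. Everything is generated; nothing is read from disk.

# A hand-built transcript table: 2 cells x 3 transcripts plus one unassigned
# molecule, with known geometry.
tiny_transcript_table <- function() {
  tibble::tibble(
    gene    = c("gA", "gA", "gB", "gB", "gB", "gA", "gC"),
    x       = c(0, 1, 2, 10, 11, 12, 50),
    y       = c(0, 0, 0, 0, 0, 0, 50),
    z       = c(0, 0, 0, 0, 0, 0, 0),
    cell_id = c("c1", "c1", "c1", "c2", "c2", "c2", NA),
    fov_id  = "f0"
  )
}

# Small tissue reused across tests (memoised per test run).
small_tissue <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_tissue(n_cells = 200, n_genes = 80, mean_total = 90,
                                seed = 101)
    }
    cache
  }
})

# A tissue tiny enough for repeated-replicate calibration loops.
null_mini_tissue <- function(seed) {
  simulate_tissue(n_cells = 60, n_genes = 30, mean_total = 60,
                  type_props = c(a = 0.5, b = 0.5), n_markers = 4,
                  min_transcripts = 0, extent = c(150, 150, 10), seed = seed)
}

# Brute-force step-up BH definition, independent of stats::p.adjust.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Brute-force DBSCAN oracle: core points from exhaustive neighborhoods,
# clusters = connected components of the core-core epsilon graph; border
# points attach to any adjacent core's cluster; the rest is noise.
dbscan_oracle <- function(points, eps, min_pts) {
  n <- nrow(points)
  d <- as.matrix(stats::dist(points))
  core <- vapply(seq_len(n), function(i) sum(d[i, ] <= eps) >= min_pts,
                 logical(1))
  comp <- integer(n)
  cl <- 0L
  for (i in which(core)) {
    if (comp[i] != 0L) next
    cl <- cl + 1L
    stack <- i
    while (length(stack) > 0) {
      j <- stack[1]; stack <- stack[-1]
      if (comp[j] != 0L) next
      comp[j] <- cl
      stack <- c(stack, which(core & comp == 0L & d[j, ] <= eps))
    }
  }
  list(core = core, core_comp = comp, d = d)
}

# Checks a dbscan_cluster() labeling against the oracle: identical partition
# of core points (up to renaming), border points attached to an adjacent
# core component, noise exactly where no core is in range.
check_dbscan_against_oracle <- function(points, eps, min_pts) {
  labels <- dbscan_cluster(points, eps, min_pts)
  oc <- dbscan_oracle(points, eps, min_pts)
  n <- nrow(points)
  for (i in seq_len(n)) {
    near_core <- which(oc$core & oc$d[i, ] <= eps)
    if (oc$core[i]) {
      if (labels[i] == 0L) return(FALSE)
    } else if (length(near_core) == 0) {
      if (labels[i] != 0L) return(FALSE)           # must be noise
    } else {
      if (!labels[i] %in% labels[near_core]) return(FALSE)
    }
  }
  # core partition must match exactly up to label renaming
  core_idx <- which(oc$core)
  if (length(core_idx) > 0) {
    a <- labels[core_idx]; b <- oc$core_comp[core_idx]
    if (length(unique(a)) != length(unique(b))) return(FALSE)
    if (any(tapply(b, a, function(v) length(unique(v))) != 1)) return(FALSE)
  }
  TRUE
}
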