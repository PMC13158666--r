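test_that("compartment splitting and depth normalization follow the formula", {
  tab <- tibble::tibble(
    gene = c("gA", "gA", "gB", "gA", "gB", "gB"),
    x = c(0, 0, 0, 10, 10, 10), y = 0, z = 0,
    cell_id = c("c1", "c1", "c1", "c2", "c2", "c2"),
    fov_id = "f",
    compartment = c("nuclear", "cytoplasmic", "cytoplasmic",
                    "cytoplasmic", "nuclear", "nuclear"))
  s <- tissue_sample(tab, min_transcripts = 1)
  cc <- compartment_counts(s)
  expect_equal(unname(cc$u["c1", "gA"]), 1L)
  expect_equal(unname(cc$s["c1", c("gA", "gB")]), c(1L, 1L))
  # cytoplasmic totals 2 and 1 -> mean 1.5; c1 scaled x0.75, c2 x1.5
  expect_equal(unname(cc$s_norm["c1", "gA"]), 1 / 2 * 1.5)
  expect_equal(unname(cc$s_norm["c2", "gA"]), 1 / 1 * 1.5)
})

test_that("kNN smoothing is identity at K = 0 and reduces variance", {
  s <- plant_velocity(small_tissue(), setNames(rep(1, 10), paste0("g0", 10:19)),
                      seed = 2)
  cc <- compartment_counts(s)
  expect_identical(normalize_and_smooth(cc, K = 0), cc)
  sm <- normalize_and_smooth(cc, K = 15)
  v_raw <- apply(cc$s, 2, var)
  v_sm <- apply(sm$s, 2, var)
  keep <- v_raw > 0
  expect_lt(mean(v_sm[keep] / v_raw[keep]), 1)
  expect_warning(normalize_and_smooth(cc, K = nrow(cc$s) + 5), "K reduced")
})

test_that("gamma fitting is exact on noiseless data and scale-equivariant", {
  withr::with_seed(3, {
    s_counts <- matrix(rpois(200 * 5, 40), 200, 5,
                       dimnames = list(paste0("c", 1:200), paste0("g", 1:5)))
  })
  cc <- list(u = 2 * s_counts, s = s_counts,
             s_norm = s_counts, mean_total_s = mean(rowSums(s_counts)))
  m <- fit_gamma(cc)
  expect_equal(unname(m$gamma), rep(2, 5), tolerance = 1e-12)
  # scaling u by c scales gamma by c (origin-constrained fit)
  cc2 <- cc; cc2$u <- 3 * cc$u
  m2 <- fit_gamma(cc2)
  expect_equal(m2$gamma, 3 * m$gamma, tolerance = 1e-12)
  # low-expression gene flagged unreliable at the 0.038 cutoff
  expect_true(all(m$reliable))
  cc3 <- cc
  cc3$u <- cbind(cc$u, low = 0L)
  cc3$s <- cbind(cc$s, low = rep(c(0L, 1L), 100))
  m3 <- fit_gamma(cc3)
  expect_false(m3$reliable["low"])
})

test_that("planted gamma values are recovered from noisy tissues", {
  s <- simulate_tissue(n_cells = 600, n_genes = 60, mean_total = 150,
                       seed = 5, min_transcripts = 20)
  genes <- colnames(s$counts)[order(-colMeans(s$counts))][1:12]
  gam <- setNames(rep(c(0.5, 1, 2), each = 4), genes)
  sv <- plant_velocity(s, gam, seed = 6)
  cc <- normalize_and_smooth(compartment_counts(sv), K = 30)
  m <- fit_gamma(cc)
  est <- m$gamma[genes]
  expect_true(all(m$reliable[genes]))
  expect_lt(max(abs(est - gam) / gam), 0.12)
})

test_that("future-state projection honors T, floors, and phase conventions", {
  withr::with_seed(7, {
    s_counts <- matrix(rpois(300, 40) + 1, 60, 5,
                       dimnames = list(paste0("c", 1:60), paste0("g", 1:5)))
  })
  # steady state u = gamma s exactly -> zero velocity, no state change
  cc <- list(u = s_counts, s = s_counts, s_norm = s_counts,
             mean_total_s = mean(rowSums(s_counts)))
  m <- fit_gamma(cc)
  fut <- compute_future_states(cc, m, T_step = 3)
  expect_equal(max(fut$state_changes$magnitude_future), 0, tolerance = 1e-8)
  expect_equal(fut$scores_current, fut$scores_future, tolerance = 1e-8)
  # T = 0 is the identity regardless of velocities
  cc2 <- cc; cc2$u <- cc$u * 2
  m2 <- fit_gamma(cc)
  fut0 <- compute_future_states(cc2, m2, T_step = 0)
  expect_equal(max(fut0$state_changes$magnitude_future), 0, tolerance = 1e-8)
  # phase lies in (-pi, pi] and displacement along +PC1 gives phase 0
  disp <- c(1, 0)
  expect_equal(atan2(disp[2], disp[1]), 0)
  expect_true(all(fut$state_changes$phase > -pi - 1e-9 &
                    fut$state_changes$phase <= pi + 1e-9))
})

test_that("induced cells carry positive mean velocity under the fitted model", {
  s <- simulate_tissue(n_cells = 300, seed = 9)
  genes <- colnames(s$counts)[order(-colMeans(s$counts))][1:10]
  gam <- setNames(rep(1, 10), genes)
  sv <- plant_velocity(s, gam, induced_fraction = 0.10,
                       induction_factor = 2, seed = 10)
  induced <- attr(sv, "velocity_truth")$induced_ids
  cc <- normalize_and_smooth(compartment_counts(sv), K = 0)
  m <- fit_gamma(cc)
  fut <- compute_future_states(cc, m, T_step = 3)
  v <- fut$velocities[, intersect(genes, colnames(fut$velocities)),
                      drop = FALSE]
  ind <- rownames(v) %in% induced
  expect_gt(mean(rowMeans(v[ind, ])), 0)
  expect_gt(mean(rowMeans(v[ind, ])), mean(rowMeans(v[!ind, ])))
  # induced cells show larger predicted state changes
  sc <- fut$state_changes
  expect_gt(mean(sc$magnitude_future[sc$cell_id %in% induced]),
            mean(sc$magnitude_future[!sc$cell_id %in% induced]))
})

test_that("distance-state correlations detect a planted linear rule", {
  s <- simulate_tissue(n_cells = 300, seed = 9)
  ct <- s$cells
  ids <- ct$cell_id[!is.na(ct$type_label) & ct$type_label == "tumor"]
  d <- min_distance_to_type(s, "tcell", cells = ids, scope = "tissue")
  ok <- !is.na(d$distance)
  withr::with_seed(13, {
    sc <- tibble::tibble(
      cell_id = d$cell_id[ok],
      magnitude_future = pmax(0, 5 - 0.1 * d$distance[ok] + rnorm(sum(ok))),
      magnitude_current = pmax(0, 3 - 0.05 * d$distance[ok] + rnorm(sum(ok))),
      phase = runif(sum(ok), -pi, pi))
  })
  res <- distance_state_correlations(sc, s, "tumor", "tcell",
                                     n_perm = 1000, seed = 11)
  mag <- res[res$response == "magnitude_future", ]
  expect_lt(mag$r, 0)                        # closer -> larger change
  expect_lt(mag$p, 0.05)
  expect_gt(res$p[res$response == "phase"], 0.01)  # no planted phase rule
  # calibration: magnitudes independent of distance -> uniform p
  withr::with_seed(12, {
    ps <- vapply(1:100, function(i) {
      correlation_with_permutation(rnorm(80), rnorm(80), n_perm = 300,
                                   seed = 100 + i)$test$p
    }, numeric(1))
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("gene-level velocity correlations apply reference filters", {
  withr::with_seed(13, {
    v <- matrix(rnorm(200), 50, 4,
                dimnames = list(paste0("c", 1:50), paste0("g", 1:4)))
    d <- tibble::tibble(cell_id = paste0("c", 1:50),
                        distance = runif(50, 0, 30))
  })
  v[, "g1"] <- 10 - 0.3 * d$distance + rnorm(50, sd = 0.3)  # planted slope
  v[, "g4"] <- 5                                            # constant
  ref <- tibble::tibble(gene = paste0("g", 1:4),
                        detect_frac = c(0.9, 0.15, 0.5, 0.9))
  res <- gene_velocity_correlations(v, d, reference_detection = ref)
  expect_false("g2" %in% res$gene)           # 15% < 20% detection
  expect_true(res$dropped_constant[res$gene == "g4"])
  expect_lt(res$q[res$gene == "g1"], 0.05)
  expect_lt(res$r[res$gene == "g1"], 0)
  # exception list retains an otherwise-filtered gene
  res2 <- gene_velocity_correlations(v, d, reference_detection = ref,
                                     keep_exceptions = "g2")
  expect_true("g2" %in% res2$gene)
})
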