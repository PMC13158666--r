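test_that("extract_markers applies thresholds and duplicate rules", {
  ref <- tibble::tibble(
    gene       = c("m1", "m2", "m2", "m3", "m3", "m4"),
    cell_type  = c("A",  "A",  "B",  "A",  "B",  "B"),
    avg_log2FC = c(6,    7,    6,    8,    6,    4),
    adjusted_p = c(1e-250, 1e-250, 1e-150, 0, 0, 1e-250))
  mk <- extract_markers(ref)
  # m1: clean marker; m2: kept for A only (sole p<=1e-200 holder);
  # m3: p ~ 0 in two types -> dropped; m4: log2FC 4 < 5 -> dropped
  expect_setequal(mk$gene, c("m1", "m2"))
  expect_equal(mk$cell_type[mk$gene == "m2"], "A")
  # canonical union never overrides a reference mapping
  mk2 <- extract_markers(ref, canonical = tibble::tibble(
    gene = c("m1", "m9"), cell_type = c("B", "C")))
  expect_equal(mk2$cell_type[mk2$gene == "m1"], "A")
  expect_true("m9" %in% mk2$gene)
  expect_error(extract_markers(tibble::tibble(gene = "x")), "columns")
})

test_that("cluster assignment rules cover every branch", {
  one <- tibble::tibble(cell_type = "A", q = 1e-12)
  expect_equal(resolve_cluster_assignment(one), "A")
  # below threshold -> unassigned
  expect_true(is.na(resolve_cluster_assignment(
    tibble::tibble(cell_type = "A", q = 1e-6))))
  # several markers, same type, best passes
  same <- tibble::tibble(cell_type = c("A", "A"), q = c(1e-12, 1e-3))
  expect_equal(resolve_cluster_assignment(same), "A")
  # different types, exactly one at q ~ 0
  mixed <- tibble::tibble(cell_type = c("A", "B"), q = c(1e-250, 1e-150))
  expect_equal(resolve_cluster_assignment(mixed), "A")
  # different types, both q ~ 0 -> unassigned
  both0 <- tibble::tibble(cell_type = c("A", "B"), q = c(0, 1e-250))
  expect_true(is.na(resolve_cluster_assignment(both0)))
  # log-ratio rule: log10(q1/q2) = -16 < 0.3*log10(q2) = -1.2, q1 <= 1e-9
  lr <- tibble::tibble(cell_type = c("A", "B"), q = c(1e-20, 1e-4))
  expect_equal(resolve_cluster_assignment(lr), "A")
  # log-ratio rule failing: q1 and q2 too close
  expect_true(is.na(resolve_cluster_assignment(
    tibble::tibble(cell_type = c("A", "B"), q = c(1e-10, 10^-9.5)))))
  expect_true(is.na(resolve_cluster_assignment(one[0, ])))
})

test_that("consensus labeling enforces both support thresholds", {
  cells <- paste0("c", 1:3)
  mk_solution <- function(lab) setNames(lab, cells)
  # 200 retained solutions (each with 4 inferred types via extra cells)
  base <- c("A", "B", "C", "D")
  sols <- lapply(1:200, function(i) {
    l <- setNames(c("A", "B", "C", "D"), paste0("x", 1:4))   # keeps 4 types
    c(l, mk_solution(c(
      if (i <= 80) "A" else NA,          # c1: 80/200 = 40% support
      if (i <= 30) "B" else NA,          # c2: 30/200 = 15% < 20%
      NA)))
  })
  res <- consensus_labels(sols)
  expect_equal(res$label[res$cell_id == "c1"], "A")
  expect_true(is.na(res$label[res$cell_id == "c2"]))   # fraction too low
  # support count threshold: 5 supporting solutions of 20 retained is 25%
  sols2 <- lapply(1:20, function(i) {
    l <- setNames(base, paste0("x", 1:4))
    c(l, mk_solution(c(if (i <= 5) "A" else NA, NA, NA)))
  })
  res2 <- consensus_labels(sols2)
  expect_true(is.na(res2$label[res2$cell_id == "c1"]))  # count 5 < 10
  # solutions with only 3 inferred types are excluded before counting
  sols3 <- lapply(1:30, function(i) {
    setNames(c("A", "B", "C", "A"), c(paste0("x", 1:3), "c1"))
  })
  expect_warning(res3 <- consensus_labels(sols3), "no clustering solution")
  expect_true(all(is.na(res3$label)))
  # invariance to solution ordering
  res4 <- consensus_labels(rev(sols))
  expect_equal(dplyr::arrange(res, cell_id), dplyr::arrange(res4, cell_id))
})

test_that("grid clustering is deterministic and recovers planted types", {
  s <- small_tissue()
  sols <- cluster_parameter_grid(s$counts, pcs_grid = c(6, 10),
                                 resolution_grid = c(0.5, 1.0), seed = 3)
  expect_length(sols, 4)
  sols_again <- cluster_parameter_grid(s$counts, pcs_grid = c(6, 10),
                                       resolution_grid = c(0.5, 1.0), seed = 3)
  expect_identical(sols, sols_again)
  # adjusted-Rand-style check: at least one combo recovers the 5 planted
  # types almost perfectly (pairwise co-clustering agreement >= 0.9)
  truth <- setNames(s$cells$type_label, s$cells$cell_id)
  agree <- vapply(sols, function(sl) {
    cl <- sl$cluster_of[names(truth)]
    tab <- table(cl, truth)
    # Rand index
    n <- sum(tab)
    a <- sum(choose(tab, 2))
    b <- sum(choose(rowSums(tab), 2)) - a
    c_ <- sum(choose(colSums(tab), 2)) - a
    d <- choose(n, 2) - a - b - c_
    (a + d) / choose(n, 2)
  }, numeric(1))
  expect_gte(max(agree), 0.9)
})

test_that("full pipeline labels a structured tissue accurately", {
  s <- small_tissue()
  markers <- attr(s, "markers")
  res <- cell_type_pipeline(s$counts, markers, pcs_grid = c(6, 10),
                            resolution_grid = c(0.5, 1.0), seed = 3)
  truth <- setNames(s$cells$type_label, s$cells$cell_id)
  ok <- !is.na(res$label)
  expect_gt(mean(ok), 0.5)
  expect_gte(mean(res$label[ok] == truth[res$cell_id[ok]]), 0.9)
})

test_that("permutation validation separates structure from shuffled noise", {
  s <- small_tissue()
  markers <- attr(s, "markers")
  pv <- suppressWarnings(permutation_validate_typing(
    s$counts, markers, pcs_grid = c(6, 10), resolution_grid = c(0.5, 1.0),
    n_perm = 6, seed = 5))
  # shuffling within gene preserves each gene's count multiset
  perm <- withr::with_seed(5, apply(s$counts, 2, sample))
  expect_equal(apply(perm, 2, sort), apply(s$counts, 2, sort),
               ignore_attr = TRUE)
  expect_gt(pv$observed, max(pv$null_counts))
  expect_lt(pv$test$p, 0.01)
})
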