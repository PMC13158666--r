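test_that("size factors recover proportionality constants", {
  withr::with_seed(2, {
    base <- rpois(50, 20) + 1
    m <- rbind(base, 2 * base, 4 * base, base, 3 * base)
  })
  sf <- size_factors(m)
  expected <- c(1, 2, 4, 1, 3)
  expect_equal(unname(sf / sf[1]), expected / expected[1], tolerance = 1e-12)
  expect_equal(exp(mean(log(sf))), 1, tolerance = 1e-12)
})

test_that("identical groups give zero fold changes and a label-swap flips signs", {
  withr::with_seed(3, {
    block <- matrix(rnbinom(40 * 30, mu = 5, size = 2), 40, 30,
                    dimnames = list(NULL, paste0("g", 1:30)))
  })
  dup <- rbind(block, block)
  lab <- rep(c("a", "b"), each = 40)
  de <- nb_de(dup, lab)
  expect_equal(max(abs(de$log2FC)), 0, tolerance = 1e-8)
  # sign flip under label swap
  withr::with_seed(4, {
    c2 <- matrix(rnbinom(60 * 25, mu = 6, size = 3), 60, 25,
                 dimnames = list(NULL, paste0("g", 1:25)))
  })
  l2 <- rep(c("a", "b"), each = 30)
  d1 <- nb_de(c2, factor(l2, levels = c("a", "b")))
  d2 <- nb_de(c2, factor(l2, levels = c("b", "a")))
  expect_equal(d1$log2FC, -d2$log2FC, tolerance = 1e-8)
  expect_equal(d1$p_nominal, d2$p_nominal, tolerance = 1e-8)
})

test_that("a planted 4-fold gene is estimated near log2FC 2 and q < 0.05", {
  withr::with_seed(5, {
    n <- 200
    mu <- matrix(5, 2 * n, 50)
    mu[(n + 1):(2 * n), 1] <- 20          # 4-fold in group 2, gene 1
    counts <- matrix(rnbinom(length(mu), mu = as.vector(mu), size = 10),
                     nrow(mu), ncol(mu),
                     dimnames = list(NULL, paste0("g", 1:50)))
  })
  lab <- rep(c("a", "b"), each = 200)
  de <- nb_de(counts, lab)
  expect_gt(de$log2FC[1], 1.7)
  expect_lt(de$log2FC[1], 2.3)
  expect_lt(de$q_nominal[1], 0.05)
})

test_that("the Wald test calibrates under a global null", {
  withr::with_seed(6, {
    counts <- matrix(rnbinom(100 * 2000, mu = 8, size = 5), 100, 2000,
                     dimnames = list(NULL, paste0("g", 1:2000)))
  })
  lab <- rep(c("a", "b"), each = 50)
  de <- nb_de(counts, lab)
  frac <- mean(de$p_nominal < 0.05)
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.07)
})

test_that("nb_de agrees with an established NB DE implementation", {
  skip_if_not_installed("DESeq2")
  withr::with_seed(7, {
    mu <- matrix(8, 80, 40)
    mu[41:80, 1:4] <- 32
    counts <- matrix(rnbinom(length(mu), mu = as.vector(mu), size = 4),
                     nrow(mu), ncol(mu),
                     dimnames = list(paste0("c", 1:80), paste0("g", 1:40)))
  })
  lab <- factor(rep(c("a", "b"), each = 40))
  mine <- nb_de(counts, lab)
  dds <- suppressMessages(DESeq2::DESeqDataSetFromMatrix(
    countData = t(counts), colData = data.frame(condition = lab),
    design = ~condition))
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  ref <- as.data.frame(DESeq2::results(dds))
  # strong planted genes agree in direction and roughly in magnitude
  expect_equal(mine$log2FC[1:4], unname(ref$log2FoldChange[1:4]),
               tolerance = 0.2, ignore_attr = TRUE)
  # rank agreement of the evidence across the panel
  expect_gt(cor(-log10(mine$p_nominal), -log10(ref$pvalue),
                use = "complete.obs", method = "spearman"), 0.8)
})

test_that("permutation p-values behave at the boundaries and track nominal p", {
  withr::with_seed(8, {
    mu <- matrix(6, 60, 40)
    mu[31:60, 1] <- 60                      # very strong planted effect
    counts <- matrix(rnbinom(length(mu), mu = as.vector(mu), size = 10),
                     nrow(mu), ncol(mu),
                     dimnames = list(NULL, paste0("g", 1:40)))
  })
  lab <- rep(c("a", "b"), each = 30)
  de <- permutation_de(counts, lab, n_perm = 200, seed = 1)
  expect_equal(unname(de$p_perm[de$gene == "g1"]), 1 / 201)  # attainable floor
  keep <- de$gene != "g1"
  expect_gt(cor(rank(de$p_perm[keep]), rank(de$p_nominal[keep])), 0.8)
  # identical cells: every statistic is 0 in every permutation, so the
  # add-one rule pins p_perm at 1
  flat <- matrix(3L, 20, 5, dimnames = list(NULL, paste0("f", 1:5)))
  de_flat <- permutation_de(flat, rep(c("a", "b"), each = 10), n_perm = 50,
                            seed = 2)
  expect_true(all(de_flat$p_perm == 1))
})

test_that("cross-tissue overlap p matches the hypergeometric tail", {
  bg <- paste0("g", 1:10)
  r <- cross_tissue_overlap(c("g1", "g2"), c("g1", "g2"), bg, n_perm = 20000,
                            seed = 2)
  expect_equal(r$intersection_size, 2)
  # P(both of B's 2 draws hit A's 2 genes) = 1/C(10,2) = 1/45
  expect_equal(r$p, 1 / 45, tolerance = 3 * sqrt((1 / 45) / 20000) * 45)
  r2 <- cross_tissue_overlap(c("g1", "g2"), c("g3", "g4"), bg, n_perm = 2000,
                             seed = 3)
  expect_equal(r2$intersection_size, 0)
  expect_gt(r2$p, 0.95)
  # random sets: permutation tail within 3 Monte-Carlo sd of phyper
  withr::with_seed(9, {
    bg2 <- paste0("g", 1:60)
    for (i in 1:5) {
      a <- sample(bg2, 12); b <- sample(bg2, 15)
      obs <- length(intersect(a, b))
      r3 <- cross_tissue_overlap(a, b, bg2, n_perm = 4000, seed = i)
      ph <- phyper(obs - 1, 12, 48, 15, lower.tail = FALSE)
      mc_sd <- sqrt(ph * (1 - ph) / 4000)
      expect_lt(abs(r3$p - ph), 3 * mc_sd + 2 / 4000)
    }
  })
  expect_error(cross_tissue_overlap("g1", "g1", character(0)), "background")
})

test_that("triplet contrasts partition focal cells and enforce minimum sizes", {
  # geometric toy: A cells near B only, near B and C, near C only
  tab <- tibble::tibble(
    gene = "g",
    x = c(0, 0.5, 20, 20.5, 21, 40, 40.5),
    y = 0, z = 0,
    cell_id = c("a1", "b1", "a2", "b2", "c2", "a3", "c3"),
    fov_id = "f")
  s <- tissue_sample(tab, min_transcripts = 1)
  s <- annotate_cells(s, tibble::tibble(
    cell_id = c("a1", "a2", "a3", "b1", "b2", "c2", "c3"),
    cell_type = c("A", "A", "A", "B", "B", "C", "C")))
  tc <- build_triplet_contrast(s, "A", "B", "C", threshold = 1)
  expect_equal(tc$n_condition1, 1)   # a1 near B only
  expect_equal(tc$n_condition2, 1)   # a2 near B and C; a3 (C only) excluded
  expect_false(tc$valid)             # below the 5-cell minimum
  expect_message(expect_null(triplet_de(tc)), "skipped")
})

test_that("a planted triplet effect is detected via the shared engine", {
  # three tissues pooled, as the triplet analysis itself prescribes
  cohort <- lapply(1:3, function(i) {
    simulate_tissue(n_cells = 350, seed = 16 + i,
                    tissue_id = paste0("t", i))
  })
  # plant on a gene well expressed in the focal type of every tissue
  gm <- do.call(pmin, lapply(cohort, function(s) {
    attr(s, "gene_means")["tumor", ]
  }))
  gm <- gm[!names(gm) %in% attr(cohort[[1]], "markers")$gene]
  target <- names(which.max(gm))
  eff <- list(list(kind = "triplet", type_a = "tumor", type_b = "tcell",
                   type_c = "bcell", gene = target, factor = 3))
  planted <- lapply(seq_along(cohort), function(i) {
    plant_spatial_effects(cohort[[i]], eff, seed = 20 + i)
  })
  tc <- build_triplet_contrast(planted, "tumor", "tcell", "bcell",
                               threshold = 1)
  expect_true(tc$valid)
  de <- triplet_de(tc, n_perm = 300, seed = 19)
  row <- de[de$gene == target, ]
  expect_lt(row$q_nominal, 0.05)
  expect_gt(row$log2FC, 0.8)
})
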