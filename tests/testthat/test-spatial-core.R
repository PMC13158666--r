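test_that("ingest builds cells, counts and rescaled coordinates", {
  tab <- tiny_transcript_table()
  s <- tissue_sample(tab, min_transcripts = 1)
  expect_equal(nrow(s$cells), 2)
  expect_equal(sum(s$counts), 6)           # the unassigned molecule is excluded
  expect_equal(unname(s$counts["c1", c("gA", "gB")]), c(2L, 1L))

  s4 <- tissue_sample(tab, expansion_factor = 4, min_transcripts = 1)
  expect_equal(s4$transcripts$x, tab$x / 4)
  expect_equal(s4$counts, s$counts)        # counts unaffected by rescaling

  expect_error(tissue_sample(tab[, -2], min_transcripts = 1), "missing required")
  bad <- tab
  bad$x <- as.character(bad$x)
  bad$x[3] <- "oops"
  expect_error(tissue_sample(bad, min_transcripts = 1), "row 3")
})

test_that("write/read round-trip reproduces the sample", {
  s <- small_tissue()
  path <- withr::local_tempfile(fileext = ".csv")
  write_transcripts(s, path)
  s2 <- read_transcripts(path, tissue_id = s$tissue_id, platform = "synthetic",
                         min_transcripts = s$min_transcripts)
  expect_equal(s2$counts, s$counts)
  expect_equal(s2$cells$fov_id, s$cells$fov_id)
  expect_lt(max(abs(s2$transcripts$x - s$transcripts$x)), 1e-9)
  expect_lt(max(abs(s2$transcripts$z - s$transcripts$z)), 1e-9)
})

test_that("pair_distance matches hand geometry and the exhaustive oracle", {
  tab <- tibble::tibble(
    gene = "g", x = c(0, 3), y = c(0, 4), z = c(0, 0),
    cell_id = c("a", "b"), fov_id = "f")
  s <- tissue_sample(tab, min_transcripts = 1)
  expect_equal(pair_distance(s, "a", "b"), 5)   # 3-4-5 triangle
  expect_equal(pair_distance(s, "a", "b"), pair_distance(s, "b", "a"))

  # shared coordinate -> zero
  tab2 <- dplyr::bind_rows(tab, tibble::tibble(
    gene = "g", x = 0, y = 0, z = 0, cell_id = "b", fov_id = "f"))
  s2 <- tissue_sample(tab2, min_transcripts = 1)
  expect_equal(pair_distance(s2, "a", "b"), 0)

  # random 20x20 clouds vs brute force over all 400 pairs
  withr::with_seed(99, {
    for (rep in 1:5) {
      A <- matrix(runif(60, 0, 20), 20, 3)
      B <- matrix(runif(60, 10, 30), 20, 3)
      tab3 <- tibble::tibble(
        gene = "g", x = c(A[, 1], B[, 1]), y = c(A[, 2], B[, 2]),
        z = c(A[, 3], B[, 3]),
        cell_id = rep(c("a", "b"), each = 20), fov_id = "f")
      s3 <- tissue_sample(tab3, min_transcripts = 1)
      brute <- min(apply(A, 1, function(p) {
        min(sqrt(colSums((t(B) - p)^2)))
      }))
      expect_equal(pair_distance(s3, "a", "b"), brute, tolerance = 1e-12)
    }
  })
})

test_that("min_distance_to_type honors scope, caps and missing targets", {
  tab <- tibble::tibble(
    gene = "g",
    x = c(0, 7, 200), y = c(0, 0, 0), z = c(0, 0, 0),
    cell_id = c("q", "t1", "t2"),
    fov_id = c("f1", "f1", "f2"))
  s <- tissue_sample(tab, min_transcripts = 1)
  s <- annotate_cells(s, tibble::tibble(cell_id = c("q", "t1", "t2"),
                                        cell_type = c("X", "Y", "Y")))
  d <- min_distance_to_type(s, "Y", cells = "q", scope = "same_fov")
  expect_equal(d$distance, 7)
  # no in-FOV target
  d2 <- min_distance_to_type(s, "Y", cells = "t2", scope = "same_fov")
  expect_true(is.na(d2$distance))
  expect_error(min_distance_to_type(s, "nosuch"), "known types")

  # centroid convention with the 145 um cap
  sc <- tissue_sample(tab, platform = "MERFISH", min_transcripts = 1)
  sc <- annotate_cells(sc, tibble::tibble(cell_id = c("q", "t1", "t2"),
                                          cell_type = c("X", "Y", "Y")))
  d3 <- min_distance_to_type(sc, "Y", cells = "t2", scope = "tissue")
  expect_true(is.na(d3$distance))            # nearest at 193 um > 145 cap
  d4 <- min_distance_to_type(sc, "Y", cells = "t2", scope = "tissue", cap = 500)
  expect_equal(d4$distance, 193)
})

test_that("proximity stratification is an inclusive-threshold partition", {
  tab <- tibble::tibble(
    gene = "g",
    x = c(0, 1.0, 10, 11.01, 30), y = 0, z = 0,
    cell_id = c("i1", "ii1", "i2", "ii2", "i3"), fov_id = "f")
  s <- tissue_sample(tab, min_transcripts = 1)
  s <- annotate_cells(s, tibble::tibble(
    cell_id = c("i1", "i2", "i3", "ii1", "ii2"),
    cell_type = c("I", "I", "I", "II", "II")))
  st <- stratify_by_proximity(s, "I", "II", threshold = 1)
  expect_setequal(st$proximal_ids, "i1")       # exactly 1.0 um is proximal
  expect_setequal(st$distant_ids, c("i2", "i3"))  # 1.01 um is distant
  expect_true(st$analyzable)
  # partition invariant on a simulated tissue
  s2 <- small_tissue()
  st2 <- stratify_by_proximity(s2, "tumor", "tcell")
  n_type <- sum(s2$cells$type_label == "tumor", na.rm = TRUE)
  expect_equal(length(st2$proximal_ids) + length(st2$distant_ids), n_type)
  expect_length(intersect(st2$proximal_ids, st2$distant_ids), 0)
  # all far -> unanalyzable flag
  st3 <- stratify_by_proximity(s, "I", "II", threshold = 1e-6)
  expect_false(st3$analyzable)
  expect_length(st3$proximal_ids, 0)
})

test_that("count_neighbors matches brute force and is monotone in cutoff", {
  tab <- tibble::tibble(
    gene = "g", x = c(0, 10, 14), y = 0, z = 0,
    cell_id = c("q", "y1", "y2"), fov_id = "f")
  s <- tissue_sample(tab, min_transcripts = 1)
  s <- annotate_cells(s, tibble::tibble(cell_id = c("q", "y1", "y2"),
                                        cell_type = c("X", "Y", "Y")))
  expect_equal(count_neighbors(s, "Y", 15, cells = "q")$n_neighbors, 2L)
  expect_equal(count_neighbors(s, "Y", 10, cells = "q")$n_neighbors, 1L)

  s2 <- small_tissue()
  ids <- s2$cells$cell_id[which(s2$cells$type_label == "tumor")[1:15]]
  cuts <- c(5, 10, 15, 25)
  mats <- sapply(cuts, function(cu) {
    count_neighbors(s2, "tcell", cutoff = cu, cells = ids)$n_neighbors
  })
  expect_true(all(diff(t(mats)) >= 0))       # monotone non-decreasing
  # brute force at one cutoff
  brute <- vapply(ids, function(q) {
    tg <- s2$cells$cell_id[!is.na(s2$cells$type_label) &
                             s2$cells$type_label == "tcell"]
    sum(vapply(setdiff(tg, q), function(t2) {
      pair_distance(s2, q, t2) <= 15
    }, logical(1)))
  }, integer(1))
  expect_equal(count_neighbors(s2, "tcell", 15, cells = ids)$n_neighbors,
               unname(brute))
})

test_that("same-type neighbor counting excludes the cell itself", {
  s <- small_tissue()
  ids <- s$cells$cell_id[which(s$cells$type_label == "tumor")[1:10]]
  n_same <- count_neighbors(s, "tumor", cutoff = 20, cells = ids)
  brute <- vapply(ids, function(q) {
    tg <- setdiff(s$cells$cell_id[!is.na(s$cells$type_label) &
                                    s$cells$type_label == "tumor"], q)
    sum(vapply(tg, function(t2) pair_distance(s, q, t2) <= 20, logical(1)))
  }, integer(1))
  expect_equal(n_same$n_neighbors, unname(brute))
})
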