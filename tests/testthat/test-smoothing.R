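eps8 <- function(cs) cs * sqrt(2) + 1e-6

test_that("find_components equals grid flood fill under the 8-connectivity eps", {
  m <- matrix(NA_integer_, 10, 10)
  m[3:6, 3:6] <- 0L
  lr <- label_raster(m, cell_size = 5)
  fc <- find_components(lr, 0L, eps8(5), min_pts = 1)
  expect_length(fc$components, 1)
  expect_length(fc$outliers, 0)
  expect_identical(sort(fc$components[[1]]), which(!is.na(m)))

  # two 3x3 blocks 50 m apart
  m <- matrix(NA_integer_, 20, 20)
  m[1:3, 1:3] <- 1L
  m[15:17, 15:17] <- 1L
  lr <- label_raster(m, cell_size = 5)
  fc <- find_components(lr, 1L, eps8(5), min_pts = 3)
  expect_length(fc$components, 2)

  # random map: components match the flood-fill oracle exactly
  set.seed(18)
  m <- matrix(sample(0:2, 400, replace = TRUE), 20, 20)
  lr <- label_raster(m, cell_size = 5)
  for (lab in 0:2) {
    fc <- find_components(lr, lab, eps8(5), min_pts = 1)
    orc <- flood_fill_components(m, lab)
    got <- lapply(fc$components, sort)
    expect_setequal(lapply(got, paste, collapse = ","),
                    lapply(orc, paste, collapse = ","))
  }
})

test_that("outlier reassignment takes the nearest label with low-label ties", {
  m <- matrix(2L, 10, 10)
  m[1, 10] <- 5L          # stray cell far from nothing else
  lr <- label_raster(m, cell_size = 5)
  out <- reassign_outliers(lr, which(m == 5L))
  expect_equal(out$values[1, 10], 2L)

  # equidistant between labels 1 and 3 -> 1
  m <- matrix(NA_integer_, 1, 3)
  m[1, 1] <- 3L; m[1, 2] <- 0L; m[1, 3] <- 1L
  lr <- label_raster(m, cell_size = 5)
  out <- reassign_outliers(lr, 1L + (2L - 1L) * 1L)  # middle cell index (r1,c2)
  expect_equal(out$values[1, 2], 1L)

  # 20 strays against a brute-force scan
  set.seed(19)
  m <- matrix(sample(0:3, 900, replace = TRUE), 30, 30)
  lr <- label_raster(m, cell_size = 5)
  strays <- sample(900, 20)
  out <- reassign_outliers(lr, strays)
  ctr <- cell_centers(lr)
  pool <- setdiff(1:900, strays)
  for (s in strays) {
    d2 <- (ctr[pool, 1] - ctr[s, 1])^2 + (ctr[pool, 2] - ctr[s, 2])^2
    near <- pool[d2 <= min(d2) + 1e-9]
    expect_equal(out$values[s], min(m[near]))
  }
})

test_that("island relabeling follows the edge-neighbor majority with tie rule", {
  # 2-cell island of label 1 surrounded by label 0
  m <- matrix(0L, 8, 8)
  m[4, 4:5] <- 1L
  lr <- label_raster(m, cell_size = 5)
  res <- relabel_island(lr, which(m == 1L), eps8(5))
  expect_true(all(res$labels$values == 0L))
  expect_equal(res$record$assigned_label, 0L)
  expect_equal(res$record$size, 2L)

  # island bordered by label 0 on 5 neighbor cells and label 2 on 3
  m <- matrix(NA_integer_, 3, 5)
  m[2, 2:3] <- 1L                     # the island
  m[1, 1:3] <- 0L; m[2, 1] <- 0L; m[3, 1] <- 0L   # five 0-neighbors
  m[1, 4] <- 2L; m[2, 4] <- 2L; m[3, 4] <- 2L     # three 2-neighbors
  lr <- label_raster(m, cell_size = 5)
  res <- relabel_island(lr, which(!is.na(m) & m == 1L), eps8(5))
  expect_equal(res$record$assigned_label, 0L)

  # exact vote tie {0: 2, 2: 2} -> lowest label wins
  m <- matrix(NA_integer_, 2, 3)
  m[1, 2] <- 1L                        # single-cell island
  m[1, 1] <- 2L; m[2, 1] <- 2L         # two 2-votes (side + diagonal)
  m[1, 3] <- 0L; m[2, 3] <- 0L         # two 0-votes
  lr <- label_raster(m, cell_size = 5)
  res <- relabel_island(lr, which(!is.na(m) & m == 1L), eps8(5))
  expect_equal(res$record$assigned_label, 0L)

  # island spanning the whole field is left alone with a warning
  m <- matrix(3L, 2, 2)
  lr <- label_raster(m, cell_size = 5)
  expect_warning(res <- relabel_island(lr, 1:4, eps8(5)), "no outside")
  expect_true(all(res$labels$values == 3L))
})

test_that("smoothing certifies the planted-island fixture", {
  lr <- planted_island_map()
  before <- lr$values
  spec <- smoothing_spec(island_size = 5, cell_size = 5)
  res <- smooth_labels(lr, spec)
  expect_true(res$converged)
  # flood-fill certificate: no component smaller than island_size survives
  expect_gte(min_component_size(res$labels), 5)
  # at least 94% of cells keep their label
  expect_gte(mean(res$labels$values == before), 0.94)
  # the size-3 islands are majority-relabeled; sizes 1-2 fall below the
  # density threshold and are absorbed by outlier reassignment instead
  expect_true(all(res$audit$size < 5))
  expect_equal(sum(res$audit$size) + length(res$outlier_cells), 12)
})

test_that("smoothing is idempotent, monotone, and honors fixed points", {
  # a map with no sub-threshold component comes back unchanged
  m <- matrix(rep(rep(0:1, each = 10), 20), nrow = 20)
  lr <- label_raster(m, cell_size = 5)
  spec <- smoothing_spec(island_size = 5, cell_size = 5)
  res <- smooth_labels(lr, spec)
  expect_identical(res$labels$values, m)
  expect_equal(nrow(res$audit), 0)
  expect_equal(res$passes, 1)

  # idempotence at the fixed point & component-count monotonicity
  lr <- planted_island_map()
  n_comp <- function(v) sum(vapply(sort(unique(as.vector(v))), function(l)
    length(flood_fill_components(v, l)), numeric(1)))
  res1 <- smooth_labels(lr, spec)
  res2 <- smooth_labels(res1$labels, spec)
  expect_identical(res2$labels$values, res1$labels$values)
  expect_equal(nrow(res2$audit), 0)
  expect_lte(n_comp(res1$labels$values), n_comp(lr$values))

  # containment: every changed cell is an audited island cell or a
  # reassigned outlier
  changed <- which(res1$labels$values != lr$values)
  touched <- union(unlist(res1$island_cells), res1$outlier_cells)
  expect_true(all(changed %in% touched))
})

test_that("checkerboard smoothing leaves no sub-threshold component", {
  m <- matrix(0L, 12, 12)
  m[(row(m) + col(m)) %% 2 == 0] <- 1L
  lr <- label_raster(m, cell_size = 5)
  res <- smooth_labels(lr, smoothing_spec(island_size = 2, cell_size = 5))
  expect_gte(min_component_size(res$labels), 2)
})

test_that("pre-existing clustering outliers are absorbed before smoothing", {
  m <- matrix(0L, 6, 6)
  m[, 4:6] <- 1L
  m[3, 3] <- -1L
  lr <- label_raster(m, cell_size = 5)
  res <- smooth_labels(lr, smoothing_spec(island_size = 2, cell_size = 5))
  expect_equal(res$labels$values[3, 3], 0L)
  expect_true(all(res$labels$values >= 0))
})

test_that("island size converts from machinery area", {
  expect_equal(island_size_from_area(100, 5), 4L)
  expect_equal(island_size_from_area(101, 5), 5L)
})
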