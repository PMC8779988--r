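test_that("zone maps are contiguous, non-empty, and deterministic", {
  spec1 <- field_sim_spec(extent = c(100, 100), n_zones = 1,
                          attribute_specs = default_attribute_specs(1))
  expect_true(all(generate_zone_map(spec1)$values == 0L))

  spec <- field_sim_spec(extent = c(150, 150), n_zones = 4, seed = 23)
  zm <- generate_zone_map(spec)
  expect_setequal(unique(as.vector(zm$values)), 0:3)
  for (l in 0:3)
    expect_length(flood_fill_components(zm$values, l), 1)
  expect_identical(generate_zone_map(spec)$values, zm$values)

  banded <- field_sim_spec(extent = c(100, 100), n_zones = 4, seed = 1,
                           zone_geometry = "banded")
  zb <- generate_zone_map(banded)
  expect_equal(as.vector(table(zb$values)), rep(100, 4))
})

test_that("attribute generator honors its own statistical spec", {
  # correlation length -> 0: the empirical semivariogram is flat
  att0 <- list(A = list(zone_means = 0, corr_length = 0, spatial_sd = 1,
                        nugget_sd = 0))
  spec <- field_sim_spec(extent = c(150, 150), n_zones = 1,
                         attribute_specs = att0, cross_corr = list(),
                         seed = 31)
  f <- simulate_field(spec)
  cells <- mask_cells(f$stack)
  ctr <- cell_centers(f$stack, cells)
  sub <- sample(length(cells), 250)
  ps <- point_samples(ctr[sub, 1], ctr[sub, 2],
                      data.frame(A = f$stack$layers$A[cells][sub]))
  emp <- empirical_semivariogram(ps, "A", n_lags = 6, max_lag = 80)
  expect_lt(max(emp$gamma) / min(emp$gamma), 1.35)

  # forced cross-correlation r = 0.9 on a 100x100 flat-zone field
  att <- list(A = list(zone_means = 0, corr_length = 30, spatial_sd = 1,
                       nugget_sd = 0.05),
              B = list(zone_means = 0, corr_length = 30, spatial_sd = 1,
                       nugget_sd = 0.05))
  spec <- field_sim_spec(extent = c(500, 500), n_zones = 1,
                         attribute_specs = att,
                         cross_corr = list(list(a = "A", b = "B", r = 0.9)),
                         seed = 32)
  zm <- generate_zone_map(spec)
  st <- generate_attributes(zm, spec)
  r <- cor(as.vector(st$layers$A), as.vector(st$layers$B))
  expect_gt(r, 0.85); expect_lt(r, 0.95)

  # zero noise, zone means {0, 10}: within-zone variance 0, truth VRI 100
  att2 <- list(A = list(zone_means = c(0, 10), corr_length = 30,
                        spatial_sd = 0, nugget_sd = 0))
  spec <- field_sim_spec(extent = c(100, 100), n_zones = 2,
                         attribute_specs = att2, cross_corr = list(),
                         seed = 33)
  zm <- generate_zone_map(spec)
  st <- generate_attributes(zm, spec)
  v <- vri(st, zm$values[mask_cells(st)])
  expect_equal(v$per_attribute[["A"]], 100)
})

test_that("transect sampling follows the line/step geometry", {
  att <- list(A = list(zone_means = c(0, 10), corr_length = 30,
                       spatial_sd = 0.5, nugget_sd = 0.1))
  # 100 m x 96 m field, 12 m spacing: lines at 6, 18, ..., 90 -> 8 lines
  spec <- field_sim_spec(extent = c(100, 96), cell_size = 4, n_zones = 2,
                         attribute_specs = att, cross_corr = list(),
                         transect_spacing = 12, along_line_step = 1,
                         seed = 41)
  f <- simulate_field(spec)
  expect_equal(attr(f$samples, "n_lines"), 8L)
  expect_equal(length(unique(f$samples$y)), 8)
  # dense along-line: 100 points per line
  expect_equal(f$samples$n, 800)
  # anisotropy: along-line step much finer than line spacing
  expect_lt(min(diff(sort(unique(f$samples$x)))), 2)

  # noise-free samples equal the raster value of the containing cell
  g <- geometry_of(f$stack)
  col <- floor((f$samples$x - g$origin[1]) / g$cell_size) + 1
  row <- g$nrows - floor((f$samples$y - g$origin[2]) / g$cell_size)
  cell <- (col - 1) * g$nrows + row
  expect_equal(f$samples$attributes$A, f$stack$layers$A[cell])

  # step = spacing degenerates to an isotropic grid
  spec2 <- field_sim_spec(extent = c(96, 96), cell_size = 4, n_zones = 2,
                          attribute_specs = att, cross_corr = list(),
                          transect_spacing = 12, along_line_step = 11.99,
                          seed = 42)
  f2 <- simulate_field(spec2)
  expect_equal(length(unique(f2$samples$x)), 8)

  expect_error(field_sim_spec(transect_spacing = 0.5, along_line_step = 1),
               "transect_spacing")
})

test_that("adjusted Rand index matches its definition", {
  expect_equal(adjusted_rand_index(c(0, 0, 1, 1), c(5, 5, 9, 9)), 1)
  expect_equal(adjusted_rand_index(c(0, 0, 0), c(0, 0, 0)), 1)
  # hand-computed small case: a=(0,0,1,1), b=(0,1,0,1): sij=0, si=sj=2,
  # n2=6 -> exp=2/3, max=2 -> ARI=(0-2/3)/(2-2/3)=-0.5
  expect_equal(adjusted_rand_index(c(0, 0, 1, 1), c(0, 1, 0, 1)), -0.5)
})

test_that("recovery experiments score the pipeline against simulation truth", {
  # truth against itself is perfect recovery
  spec <- separated_field_spec(seed = 51)
  f <- simulate_field(spec)
  cells <- mask_cells(f$stack)
  expect_equal(adjusted_rand_index(f$truth$values[cells],
                                   f$truth$values[cells]), 1)

  # single-zone field with k = 1: ARI trivially 1, VRI exactly 0
  att <- list(A = list(zone_means = 5, corr_length = 20, spatial_sd = 1,
                       nugget_sd = 0.2))
  spec1 <- field_sim_spec(extent = c(100, 100), n_zones = 1,
                          attribute_specs = att, cross_corr = list(),
                          seed = 52)
  rec <- recovery_experiment(spec1, casp_config(scenario = "kmeans-wn-nc",
                                                k = 1, seed = 1))
  expect_equal(rec$ari, 1)
  expect_equal(rec$vri, 0)

  # simulation is deterministic given the seed
  f2 <- simulate_field(spec)
  expect_identical(f$stack$layers, f2$stack$layers)
  expect_identical(f$samples$x, f2$samples$x)
})
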