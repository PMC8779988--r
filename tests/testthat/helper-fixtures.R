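# Shared fixtures, all built in code.

# The 4-point two-pair geometry: two tight pairs 10 apart.
two_pair_geometry <- function() {
  list(X = rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1)),
       labels = c(0L, 0L, 1L, 1L))
}

# Isotropic Gaussian blobs.
make_blobs <- function(n_per, centers, sd = 1, seed = 1) {
  set.seed(seed)
  centers <- as.matrix(centers)
  X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    sweep(matrix(rnorm(n_per * ncol(centers), sd = sd), n_per), 2L,
          centers[i, ], `+`)))
  list(X = X, truth = rep(seq_len(nrow(centers)) - 1L, each = n_per))
}

# 40x40 map of 4 horizontal band zones with 6 planted islands of sizes
# 1, 2, 3 (two each) dropped well inside foreign bands.
planted_island_map <- function(cell_size = 5) {
  m <- matrix(rep(rep(0:3, each = 10), 40), nrow = 40)
  put <- function(m, cells, lab) { m[cells] <- lab; m }
  idx <- function(r, c) (c - 1) * 40 + r
  m <- put(m, idx(5, 20), 2L)                       # size 1 in band 0
  m <- put(m, idx(15, 8), 3L)                       # size 1 in band 1
  m <- put(m, c(idx(25, 30), idx(25, 31)), 0L)      # size 2 in band 2
  m <- put(m, c(idx(35, 12), idx(36, 12)), 1L)      # size 2 in band 3
  m <- put(m, c(idx(7, 33), idx(8, 33), idx(8, 34)), 3L)   # size 3 in band 0
  m <- put(m, c(idx(28, 5), idx(28, 6), idx(29, 5)), 1L)   # size 3 in band 2
  label_raster(m, c(0, 0), cell_size)
}

# Stack where one attribute's scale dwarfs the others: `big` follows
# vertical bands at scale 1000, four small attributes follow horizontal
# bands at scale 1.
dominant_scale_stack <- function(seed = 1) {
  set.seed(seed)
  nr <- 40; nc <- 40
  vert <- matrix(rep(c(rep(0, nc / 2), rep(1, nc / 2)), each = nr), nr)
  horiz <- matrix(rep(c(rep(0, nr / 2), rep(1, nr / 2)), nc), nr)
  noise <- function(s) matrix(rnorm(nr * nc, sd = s), nr)
  layers <- list(big = grid_layer(1000 * vert + noise(50)))
  for (i in 1:4)
    layers[[paste0("s", i)]] <- grid_layer(horiz + noise(0.05))
  list(stack = stack_layers(layers),
       vertical = as.integer(vert[which(vert > -1)]),
       horizontal = as.integer(horiz[which(horiz > -1)]))
}

# Well-separated 4-zone simulation spec: zone-mean gaps equal to 5x the
# total within-zone noise sd (sqrt(spatial^2 + nugget^2) = 1, gaps = 5).
separated_field_spec <- function(seed) {
  att <- function() list(zone_means = c(0, 5, 10, 15), corr_length = 20,
                         spatial_sd = sqrt(0.9), nugget_sd = sqrt(0.1))
  field_sim_spec(extent = c(200, 200), cell_size = 5, n_zones = 4,
                 attribute_specs = list(A1 = att(), A2 = att(), A3 = att()),
                 cross_corr = list(), seed = seed)
}

expect_same_partition <- function(a, b) {
  expect_equal(adjusted_rand_index(a, b), 1)
}
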