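test_that("EXG is 2G - R - B, unclipped, shape-preserving", {
  expect_equal(compute_exg(matrix(10), matrix(20), matrix(5)), matrix(25))
  # symmetric inputs cancel exactly
  c0 <- matrix(runif(9, 0, 255), 3, 3)
  expect_equal(compute_exg(c0, c0, c0), matrix(0, 3, 3))
  expect_equal(compute_exg(matrix(50, 3, 3), matrix(100, 3, 3),
                           matrix(50, 3, 3)),
               matrix(100, 3, 3))
  # negatives preserved (soil brighter than vegetation)
  expect_equal(compute_exg(matrix(200), matrix(10), matrix(100)),
               matrix(-280))
  expect_error(compute_exg(matrix(0, 2, 2), matrix(0, 3, 3), matrix(0, 2, 2)),
               "dimensions")
})

test_that("DEM derivation matches the double-loop sliding-window oracle", {
  set.seed(101)
  for (case in 1:5) {
    H <- sample(24:64, 1); W <- sample(24:64, 1)
    dsm <- matrix(100 + rnorm(H * W), H, W)
    minw <- sample(c(3L, 5L, 8L, 20L), 1)
    meanw <- sample(c(2L, 3L, 5L), 1)
    got <- derive_dem(dsm, minw, meanw)
    want <- oracle_dem(dsm, minw, meanw)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("minimum filter removes sub-window plateaus entirely", {
  d <- matrix(10, 100, 100)
  d[40:54, 40:54] <- 12 # 15 x 15 plateau < 20 x 20 window
  dem <- derive_dem(d, 20, 5)
  expect_equal(dem, matrix(10, 100, 100))
})

test_that("DEM never exceeds the DSM on a monotone ramp", {
  ramp <- outer(seq(0, 5, length.out = 40), seq(0, 3, length.out = 40), "+")
  dem <- derive_dem(ramp, 7, 3)
  expect_equal(dem, oracle_dem(ramp, 7, 3), tolerance = 1e-9)
  expect_true(all(dem <= ramp + 1e-9))
})

test_that("derive_dem validates its windows", {
  expect_error(derive_dem(matrix(1, 10, 10), 20, 5), "window exceeds")
  expect_error(derive_dem(matrix(1, 10, 10), 0, 5), "positive")
  expect_error(derive_dem(matrix(c(1, NA, 1, 1), 2, 2), 1, 1), "finite")
})

test_that("CHM is the DSM-DEM difference", {
  d <- matrix(runif(100, 95, 105), 10, 10)
  expect_equal(compute_chm(d, d), matrix(0, 10, 10))
  expect_equal(compute_chm(d + 2.5, d), matrix(2.5, 10, 10))
  expect_error(compute_chm(d, d[1:5, ]), "dimensions")
})

test_that("CHM recovered from a flat-terrain scene equals the bump field", {
  # one small dome on flat ground; dome fits inside the min window
  H <- 80
  dsm <- matrix(50, H, H)
  bump <- render_ellipse(H, H, c(40, 40), 14, 12) / 255
  dome <- 2 * bump * (1 - ((row(dsm) - 40)^2 + (col(dsm) - 40)^2) / 49)
  dome[dome < 0] <- 0
  dsm <- dsm + dome
  chm <- compute_chm(dsm, derive_dem(dsm, 20, 5))
  inside <- bump > 0 & dome > 0.2 # away from the dome border
  expect_lt(max(abs(chm[inside] - dome[inside])), 0.15)
  expect_lt(max(abs(chm[!bump])), 0.05)
})

test_that("the six band combinations carry their layer counts", {
  want <- c(RGB = 3L, `RGB-DSM` = 4L, `RGB-CHM` = 4L, EXG = 1L,
            `EXG-DSM` = 2L, `EXG-CHM` = 2L)
  for (nm in names(want)) expect_equal(band_combination(nm)$layers,
                                       unname(want[nm]))
  expect_error(band_combination("RGBA"), "unknown band combination")
})

test_that("stack_bands orders layers per recipe and names missing bands", {
  px <- array(0, c(8, 8, 5))
  px[, , 1] <- 1; px[, , 2] <- 2; px[, , 3] <- 3 # r, g, b
  px[, , 4] <- 9; px[, , 5] <- 0.7               # dsm, chm
  st <- raster_stack(px, c("red", "green", "blue", "dsm", "chm"), 0.0153)
  g <- stack_bands(st, "RGB-CHM")
  expect_equal(dim(g)[3], 4L)
  # recipe order: blue, green, red, CHM
  expect_equal(unique(as.vector(g[, , 1])), 3)
  expect_equal(unique(as.vector(g[, , 2])), 2)
  expect_equal(unique(as.vector(g[, , 3])), 1)
  expect_equal(unique(as.vector(g[, , 4])), 0.7)
  expect_equal(dim(stack_bands(st, "EXG"))[3], 1L)
  # EXG derived on the fly from colour bands
  expect_equal(unique(as.vector(stack_bands(st, "EXG"))), 2 * 2 - 1 - 3)
  # RGB works on a stack lacking CHM
  st2 <- raster_stack(px[, , 1:3], c("red", "green", "blue"), 0.0153)
  expect_equal(dim(stack_bands(st2, "RGB"))[3], 3L)
  expect_error(stack_bands(st2, "RGB-CHM"), "chm")
})

test_that("normalised stacks are in [0,1] with elevation scaled by height", {
  px <- array(0, c(8, 8, 4))
  px[, , 1:3] <- array(runif(8 * 8 * 3, 0, 255), c(8, 8, 3))
  px[, , 4] <- 100 + array(runif(64, 0, 2.5), c(8, 8)) # DSM around 100 m
  st <- raster_stack(px, c("red", "green", "blue", "dsm"), 0.0153)
  g <- stack_bands(st, "RGB-DSM", normalize = TRUE, max_height = 5)
  expect_true(all(g >= 0 & g <= 1))
  # elevation band keeps relative relief: range 2.5 m / 5 m = 0.5
  expect_equal(diff(range(g[, , 4])), diff(range(px[, , 4])) / 5)
})

test_that("tiling is non-overlapping, partials dropped, labels preserved", {
  grid <- array(runif(1024 * 1024 * 2), c(1024, 1024, 2))
  lab <- matrix(sample(c(0, 255), 1024^2, TRUE), 1024, 1024)
  ts <- tile_pair(grid, lab, 256)
  expect_equal(length(ts), 16L)
  expect_true(all(vapply(ts$tiles, function(t) all(t$label %in% c(0, 255)),
                         TRUE)))
  # tiles reproduce their source windows
  o <- ts$origin_index[3, ]
  expect_equal(ts$tiles[[3]]$input,
               grid[o[1]:(o[1] + 255), o[2]:(o[2] + 255), , drop = FALSE])
  expect_equal(sum(duplicated(ts$origin_index)), 0L)
  ts2 <- tile_pair(grid[1:300, 1:300, , drop = FALSE], lab[1:300, 1:300], 256)
  expect_equal(length(ts2), 1L)
  expect_warning(tile_pair(grid[1:100, 1:100, , drop = FALSE],
                           lab[1:100, 1:100], 256), "smaller")
})

test_that("rotation augmentation quadruples tiles and preserves geometry", {
  grid <- array(runif(512 * 512 * 3), c(512, 512, 3))
  lab <- matrix(0, 512, 512); lab[100:150, 200:300] <- 255
  ts <- tile_pair(grid, lab, 256)
  aug <- augment_rotations(ts)
  expect_equal(length(aug), 4L * length(ts))
  # crown pixel count invariant under each rotation
  counts <- vapply(aug$tiles, function(t) sum(t$label == 255), 1)
  expect_equal(counts, rep(counts[seq_len(length(ts))], 4))
  # 180 degrees twice is the identity
  r180 <- crownscope:::rot90_mat(ts$tiles[[1]]$label, 2)
  expect_equal(crownscope:::rot90_mat(r180, 2), ts$tiles[[1]]$label)
  # input and label rotate together: crown position tracks across chips
  t90 <- aug$tiles[[length(ts) + 1]]
  expect_equal(t90$label, crownscope:::rot90_mat(ts$tiles[[1]]$label, 1))
  expect_equal(t90$input[, , 2], crownscope:::rot90_mat(ts$tiles[[1]]$input[, , 2], 1))
  bad <- structure(list(tiles = list(list(input = array(0, c(4, 6, 1)),
                                          label = matrix(0, 4, 6))),
                        tile_size = 4L,
                        origin_index = matrix(1L, 1, 2)),
                   class = "crown_tileset")
  expect_error(augment_rotations(bad), "square")
})
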