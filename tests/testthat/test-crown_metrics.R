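res_ref <- 0.01532703 # survey ground sampling distance, m/pixel

test_that("instances carry pixel counts and CPA from the resolution", {
  m <- matrix(0, 10, 10); m[4:5, 4:5] <- 255
  inst <- extract_crown_instances(m, res_ref, min_crown_pixels = 1L)
  expect_equal(nrow(inst$table), 1L)
  expect_equal(inst$table$pixel_count, 4L)
  expect_equal(inst$table$cpa_m2, 4 * res_ref^2, tolerance = 1e-12)
  expect_equal(inst$table$cpa_m2, 9.3967e-4, tolerance = 1e-4)
  expect_false(inst$table$touches_border)
})

test_that("empty and invalid masks are handled", {
  expect_equal(nrow(extract_crown_instances(matrix(0, 8, 8), 0.015)$table), 0L)
  expect_error(extract_crown_instances(matrix(1, 4, 4), 0.015), "binary")
  expect_error(extract_crown_instances(matrix(0, 4, 4), -1), "binary|positive")
})

test_that("labeling uses 8-connectivity and agrees with flood fill", {
  m <- matrix(0, 12, 12)
  m[2:4, 2:4] <- 255
  m[5:7, 5:7] <- 255 # touches the first diagonally -> one instance
  m[10:11, 10:11] <- 255
  inst <- extract_crown_instances(m, 0.015, min_crown_pixels = 1L)
  expect_equal(nrow(inst$table), 2L)
  expect_equal(max(inst$labels), max(oracle_components8(m)))
  set.seed(42)
  for (i in 1:3) {
    r <- matrix(sample(c(0, 255), 400, TRUE, prob = c(0.7, 0.3)), 20, 20)
    lab <- extract_crown_instances(r, 0.015, min_crown_pixels = 1L)$labels
    want <- oracle_components8(r)
    expect_equal(max(lab), max(want))
    # same partition: labels agree up to renaming
    expect_equal(length(unique(paste(lab, want))),
                 length(unique(as.vector(want[want > 0]))) + 1L)
  }
})

test_that("the speckle filter drops small components", {
  m <- matrix(0, 30, 30)
  m[2:3, 2:3] <- 255            # 4 px speckle
  m[10:20, 10:20] <- 255        # 121 px crown
  inst <- extract_crown_instances(m, 0.015, min_crown_pixels = 50L)
  expect_equal(nrow(inst$table), 1L)
  expect_equal(inst$table$pixel_count, 121L)
  expect_true(all(inst$labels[2:3, 2:3] == 0))
})

test_that("CPA totals are conserved across instances", {
  set.seed(31)
  sc <- gen_scene(8, 1024, seed = 31)
  inst <- extract_crown_instances(sc$truth$mask, sc$truth$resolution,
                                  min_crown_pixels = 50L)
  kept_px <- sum(inst$table$pixel_count)
  expect_equal(sum(inst$table$cpa_m2), kept_px * sc$truth$resolution^2,
               tolerance = 1e-12)
})

test_that("ellipse fitting recovers rendered axes", {
  mask <- render_ellipse(160, 160, c(80, 80), 100, 60)
  f <- fit_crown_ellipse(mask, 0.015)
  expect_equal(f$cw_mean, 1.2, tolerance = 0.02)
  expect_equal(f$cw_max, 1.5, tolerance = 0.02)
  expect_equal(f$cw_min, 0.9, tolerance = 0.02)
  # circle: both axes equal the diameter
  circ <- render_ellipse(120, 120, c(60, 60), 80, 80)
  fc <- fit_crown_ellipse(circ, 0.015)
  expect_equal(fc$cw_max, 80 * 0.015, tolerance = 0.02 * 80 * 0.015)
  expect_equal(fc$cw_min, 80 * 0.015, tolerance = 0.02 * 80 * 0.015)
  # rotation leaves the axes unchanged
  rot <- render_ellipse(160, 160, c(80, 80), 100, 60, theta = pi / 2)
  fr <- fit_crown_ellipse(rot, 0.015)
  expect_equal(fr$cw_max, f$cw_max, tolerance = 0.01 * f$cw_max)
  expect_equal(fr$cw_min, f$cw_min, tolerance = 0.01 * f$cw_min)
})

test_that("median axis recovery error over 50 random ellipses is below 2%", {
  set.seed(77)
  rel_err <- replicate(50, {
    major <- runif(1, 40, 200)
    minor <- runif(1, 0.6, 1) * major
    th <- runif(1, 0, pi)
    H <- ceiling(major) + 20
    mask <- render_ellipse(H, H, c(H / 2, H / 2), major, minor, th)
    f <- fit_crown_ellipse(mask, 1)
    truth <- (major + minor) / 2
    abs(f$cw_mean - truth) / truth
  })
  expect_lt(median(rel_err), 0.02)
})

test_that("cw_max is never below cw_min", {
  set.seed(78)
  for (i in 1:10) {
    major <- runif(1, 30, 120)
    minor <- runif(1, 0.5, 1) * major
    mask <- render_ellipse(140, 140, c(70, 70), major, minor, runif(1, 0, pi))
    f <- fit_crown_ellipse(mask, 0.015)
    expect_gte(f$cw_max, f$cw_min)
  }
})

test_that("degenerate components are rejected and flagged", {
  # fewer than 5 pixels cannot define a conic
  tiny <- matrix(0, 10, 10); tiny[4:5, 4:5] <- 255
  expect_error(fit_crown_ellipse(tiny, 0.015),
               "too small|edge|degenerate|conic")
  inst <- extract_crown_instances(tiny, 0.015, min_crown_pixels = 1L)
  expect_true(inst$table$unfittable)
  expect_true(is.na(inst$table$cw_mean_m))
  # area and height are still reported for unfittable instances
  expect_equal(inst$table$cpa_m2, 4 * 0.015^2)
})

test_that("tree height is the CHM maximum over the crown, local per crown", {
  m <- matrix(0, 20, 20); m[3:7, 3:7] <- 255; m[12:16, 12:16] <- 255
  inst <- extract_crown_instances(m, 0.015, min_crown_pixels = 1L)
  chm <- matrix(0, 20, 20)
  chm[3:7, 3:7] <- 2.5
  chm[12:16, 12:16] <- seq(0.1, 2.0, length.out = 25)
  inst <- estimate_tree_height(chm, inst)
  expect_equal(sort(inst$table$height_m), c(2.0, 2.5))
  # a single label query returns a scalar
  l1 <- inst$table$label[which.max(inst$table$height_m)]
  expect_equal(estimate_tree_height(chm, inst, label = l1), 2.5)
  # locality: perturbing the other crown's CHM leaves this height unchanged
  chm2 <- chm; chm2[12:16, 12:16] <- 99
  expect_equal(estimate_tree_height(chm2, inst, label = l1), 2.5)
  expect_error(estimate_tree_height(chm[1:5, ], inst), "dimensions")
})

test_that("height scales linearly with the CHM bump amplitude", {
  sc <- gen_scene(5, 800, seed = 55)
  inst <- extract_crown_instances(sc$truth$mask, sc$truth$resolution,
                                  min_crown_pixels = 1L)
  dome <- get_band(sc$stack, "dsm") - sc$truth$terrain
  h1 <- estimate_tree_height(dome, inst)$table$height_m
  h3 <- estimate_tree_height(3 * dome, inst)$table$height_m
  expect_equal(h3, 3 * h1, tolerance = 1e-12)
})

test_that("border-touching crowns are filtered out", {
  m <- matrix(0, 20, 20)
  m[1:5, 8:12] <- 255    # clipped by the top edge
  m[10:14, 8:12] <- 255  # interior
  inst <- extract_crown_instances(m, 0.015, min_crown_pixels = 1L)
  expect_equal(sum(inst$table$touches_border), 1L)
  kept <- filter_border_crowns(inst)
  expect_equal(nrow(kept$table), 1L)
  expect_false(any(kept$table$touches_border))
  expect_equal(sum(kept$labels > 0), 25)
  empty <- filter_border_crowns(extract_crown_instances(matrix(0, 8, 8),
                                                        0.015))
  expect_equal(nrow(empty$table), 0L)
})

test_that("measure_crowns writes the per-crown CSV", {
  m <- matrix(0, 40, 40); m[10:25, 10:25] <- 255
  out <- tempfile(fileext = ".csv")
  measure_crowns(m, 0.015, chm = matrix(1.8, 40, 40), out = out)
  tab <- read.csv(out)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$height_m, 1.8)
  expect_equal(tab$cpa_m2, 256 * 0.015^2)
  unlink(out)
})
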