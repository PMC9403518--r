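# build crown_instances straight from a labeled toy mask
inst_from_mask <- function(mask, resolution = 0.015)
  extract_crown_instances(mask, resolution, min_crown_pixels = 1L)

test_that("compute_iou returns percentages and rejects the empty-empty case", {
  a <- matrix(0, 6, 6); a[2:4, 2:4] <- 255
  expect_equal(compute_iou(a, a), 100)
  b <- matrix(0, 6, 6); b[3:5, 2:4] <- 255 # overlap 6, union 12
  expect_equal(compute_iou(a, b), 50)
  expect_equal(compute_iou(a, 255 - a), 0)
  expect_equal(compute_iou(a > 0, b > 0), 50) # logical input accepted
  expect_error(compute_iou(matrix(0, 3, 3), matrix(0, 3, 3)), "empty")
  expect_error(compute_iou(a, matrix(0, 3, 3)), "grid")
})

test_that("match_crowns is one-to-one with a strict threshold", {
  ref <- matrix(0, 20, 20); ref[3:8, 3:8] <- 255
  # two predictions over one reference crown: only the better one matches
  pred <- matrix(0, 20, 20)
  pred[3:8, 3:7] <- 255   # IoU 30/36 = 83.3%
  pred[3:8, 9:10] <- 255  # disjoint clump, IoU 0
  m <- match_crowns(inst_from_mask(pred), inst_from_mask(ref))
  expect_equal(m$tp, 1L); expect_equal(m$fp, 1L); expect_equal(m$fn, 0L)
  expect_equal(m$matched_ious, 30 / 36 * 100, tolerance = 1e-9)
  # a pair at exactly the threshold is rejected (strictly greater required)
  half <- matrix(0, 20, 20); half[3:8, 2:7] <- 255 # IoU vs ref: 30/42
  m50 <- match_crowns(inst_from_mask(half), inst_from_mask(ref),
                      iou_threshold = 30 / 42 * 100)
  expect_equal(m50$tp, 0L)
  expect_equal(m50$fp, 1L); expect_equal(m50$fn, 1L)
  # and is accepted just below it
  m49 <- match_crowns(inst_from_mask(half), inst_from_mask(ref),
                      iou_threshold = 30 / 42 * 100 - 1e-9)
  expect_equal(m49$tp, 1L)
  expect_error(match_crowns(inst_from_mask(pred),
                            inst_from_mask(ref[1:10, ])), "grid")
})

test_that("greedy matching agrees with exhaustive assignment on small scenes", {
  set.seed(202)
  for (case in 1:6) {
    # up to 5 blocks each side, jittered so IoUs spread around the threshold
    ref <- matrix(0, 60, 60); pred <- matrix(0, 60, 60)
    nr <- sample(2:5, 1)
    for (k in seq_len(nr)) {
      r <- 2 + 12 * ((k - 1) %% 4); c <- 2 + 14 * ((k - 1) %/% 4)
      ref[r:(r + 8), c:(c + 8)] <- 255
      dr <- sample(-3:3, 1); dc <- sample(-3:3, 1)
      pr <- max(1, r + dr); pc <- max(1, c + dc)
      pred[pr:min(60, pr + 8), pc:min(60, pc + 8)] <- 255
    }
    pi_ <- inst_from_mask(pred); ri <- inst_from_mask(ref)
    got <- match_crowns(pi_, ri, 50)
    # brute-force IoU matrix from the label maps
    iou_mat <- matrix(0, nrow(pi_$table), nrow(ri$table))
    for (i in seq_len(nrow(iou_mat))) for (j in seq_len(ncol(iou_mat))) {
      A <- pi_$labels == pi_$table$label[i]
      B <- ri$labels == ri$table$label[j]
      if (any(A & B)) iou_mat[i, j] <- sum(A & B) / sum(A | B) * 100
    }
    want <- oracle_assignment(iou_mat, 50)
    expect_equal(got$tp, want$count)
    expect_equal(sum(got$matched_ious), want$total, tolerance = 1e-9)
  }
})

test_that("detection metrics follow the P/R/F1 definitions and flag 0/0", {
  d <- detection_metrics(detection_counts(tp = 198L, fp = 26L, fn = 37L))
  expect_equal(d$precision, 198 / 224 * 100, tolerance = 1e-12)
  expect_equal(d$recall, 198 / 235 * 100, tolerance = 1e-12)
  expect_equal(d$f1, 2 * d$precision * d$recall / (d$precision + d$recall))
  none <- detection_metrics(detection_counts(0L, 0L, 5L))
  expect_true(is.na(none$precision)); expect_true(is.na(none$f1))
  expect_equal(none$recall, 0)
  noref <- detection_metrics(detection_counts(0L, 3L, 0L))
  expect_true(is.na(noref$recall))
})

test_that("F1 is bounded by its components and symmetric in P/R", {
  set.seed(17)
  for (i in 1:20) {
    tp <- sample(1:50, 1); fp <- sample(0:20, 1); fn <- sample(0:20, 1)
    d <- detection_metrics(detection_counts(tp, fp, fn))
    expect_lte(d$f1, max(d$precision, d$recall) + 1e-9)
    expect_gte(d$f1, min(d$precision, d$recall) - 1e-9)
    sw <- detection_metrics(detection_counts(tp, fn, fp)) # swap P and R
    expect_equal(sw$f1, d$f1, tolerance = 1e-12)
  }
})

test_that("regression metrics match hand-computed values", {
  x <- c(1, 2, 3); y <- c(1.1, 1.9, 3.2)
  r <- regression_metrics(x, y)
  expect_equal(r$rmse, sqrt(0.06 / 3), tolerance = 1e-12)
  expect_equal(r$rmse, 0.1414, tolerance = 1e-3)
  expect_equal(r$rrmse, r$rmse / 2 * 100, tolerance = 1e-12)
  expect_equal(r$rrmse, 7.0711, tolerance = 1e-4)
  expect_equal(r$r2, 1 - 0.06 / sum((y - mean(y))^2), tolerance = 1e-12)
  expect_equal(r$r2, 0.9733, tolerance = 1e-4)
  expect_equal(r$n, 3L)
  # the conventional form uses the reference mean in the denominator
  rc <- regression_metrics(x, y, conventional = TRUE)
  expect_equal(rc$r2, 1 - 0.06 / 2, tolerance = 1e-12)
  expect_equal(regression_metrics(x, x)$r2, 1)
  expect_equal(regression_metrics(x, x)$rmse, 0)
  expect_error(regression_metrics(x, y[1:2]), "lengths")
  expect_error(regression_metrics(1, 1), "at least 2")
})

test_that("rRMSE and R2 are invariant under a common rescaling of units", {
  set.seed(23)
  x <- runif(30, 1, 3); y <- x + rnorm(30, sd = 0.1)
  r1 <- regression_metrics(x, y)
  r100 <- regression_metrics(100 * x, 100 * y) # metres -> centimetres
  expect_equal(r100$rrmse, r1$rrmse, tolerance = 1e-9)
  expect_equal(r100$r2, r1$r2, tolerance = 1e-9)
  expect_equal(r100$rmse, 100 * r1$rmse, tolerance = 1e-9)
})

test_that("evaluating a mask against itself is perfect", {
  sc <- gen_scene(6, 512, seed = 61)
  rep <- evaluate_run(sc$truth$mask, sc$truth$mask, sc$truth$resolution)
  expect_equal(rep$counts$fp, 0L)
  expect_equal(rep$counts$fn, 0L)
  expect_equal(rep$detection$precision, 100)
  expect_equal(rep$detection$recall, 100)
  expect_equal(rep$mean_matched_iou, 100)
  expect_equal(rep$pooled_iou, 100)
  expect_equal(rep$regression$cw_mean_m$rmse, 0)
  expect_equal(rep$regression$cpa_m2$rmse, 0)
})

test_that("an empty prediction yields only false negatives", {
  sc <- gen_scene(4, 800, seed = 62)
  expect_warning(
    rep <- evaluate_run(matrix(0, 800, 800), sc$truth$mask,
                        sc$truth$resolution),
    "fewer than 2 matched")
  expect_equal(rep$counts$tp, 0L)
  expect_equal(rep$counts$fp, 0L)
  expect_equal(rep$counts$fn, rep$counts$n_reference)
  expect_true(is.na(rep$detection$precision))
  expect_equal(rep$detection$recall, 0)
})

test_that("counts are conserved: tp + fp = predictions, tp + fn = references", {
  sc <- gen_scene(8, 1024, seed = 63)
  noisy <- sc$truth$mask
  noisy[1:240, 1:240] <- 0                 # delete part of the scene
  noisy[800:860, 800:860] <- 255           # spurious clump
  rep <- evaluate_run(noisy, sc$truth$mask, sc$truth$resolution)
  expect_equal(rep$counts$tp + rep$counts$fp, rep$counts$n_predicted)
  expect_equal(rep$counts$tp + rep$counts$fn, rep$counts$n_reference)
})

test_that("ref_metrics overrides reference attributes in the regression", {
  m <- matrix(0, 64, 64); m[10:29, 10:29] <- 255; m[40:59, 36:55] <- 255
  ref <- inst_from_mask(m)
  rm <- data.frame(label = ref$table$label,
                   cw_mean_m = c(1.0, 2.0))
  rep <- evaluate_run(m, ref, 0.015, ref_metrics = rm,
                      min_crown_pixels = 1L)
  # predicted widths regress against the supplied values, not the refit
  fit <- rep$regression$cw_mean_m
  expect_equal(fit$n, 2L)
  got_mean <- mean(rep$predicted$table$cw_mean_m)
  expect_equal(fit$rrmse, fit$rmse / 1.5 * 100, tolerance = 1e-9)
  expect_gt(fit$rmse, 0) # supplied values differ from the refit widths
})

test_that("reports serialise to JSON", {
  sc <- gen_scene(4, 800, seed = 64)
  rep <- evaluate_run(sc$truth$mask, sc$truth$mask, sc$truth$resolution)
  path <- tempfile(fileext = ".json")
  write_report(rep, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$counts$tp, rep$counts$tp)
  expect_equal(back$detection$f1, 100)
  unlink(path)
})

test_that("bundled benchmark tallies reproduce their published rates", {
  tab <- reference_detection_counts()
  expect_equal(nrow(tab), 6L)
  expect_true(all(tab$tp + tab$fn == 235L))
  for (i in seq_len(nrow(tab))) {
    d <- detection_metrics(detection_counts(tab$tp[i], tab$fp[i], tab$fn[i]))
    expect_equal(round(d$precision, 2), tab$precision_pct[i])
    expect_equal(round(d$recall, 2), tab$recall_pct[i])
    expect_equal(round(d$f1, 2), tab$f1_pct[i])
  }
})
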