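#' Intersection over union of two pixel regions
#'
#' @param a,b region masks on the same grid: logical matrices or \{0, 255\}
#'   matrices.
#' @return IoU as a percentage in \[0, 100\].
#' @export
compute_iou <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("regions must share the pixel grid")
  a <- a != 0; b <- b != 0
  u <- sum(a | b)
  if (u == 0) stop("IoU is undefined when both regions are empty")
  sum(a & b) / u * 100
}

#' Match predicted crowns to reference crowns
#'
#' One-to-one matching: every predicted/reference pair whose IoU strictly
#' exceeds the threshold is a candidate; candidates are accepted greedily in
#' descending IoU order (ties broken by smaller predicted, then reference,
#' label), each instance used at most once. Accepted pairs are true
#' positives; unmatched predictions are false positives; unmatched reference
#' crowns are false negatives.
#'
#' @param predicted,reference `crown_instances` on the same pixel grid.
#' @param iou_threshold acceptance threshold in percent (default 50; a pair
#'   at exactly the threshold is rejected).
#' @return A `detection_counts` list: `tp`, `fp`, `fn`, `matched_ious`
#'   (percent, one per accepted pair), `n_predicted`, `n_reference`, and
#'   `pairs` (data frame of accepted pred/ref labels and IoUs).
#' @export
match_crowns <- function(predicted, reference, iou_threshold = 50) {
  stopifnot(inherits(predicted, "crown_instances"),
            inherits(reference, "crown_instances"))
  if (!all(dim(predicted$labels) == dim(reference$labels)))
    stop("instance sets must share the pixel grid")
  plab <- predicted$table$label
  rlab <- reference$table$label
  np <- length(plab); nr <- length(rlab)
  cand <- data.frame(pred = integer(), ref = integer(), iou = numeric())
  if (np && nr) {
    P <- predicted$labels; R <- reference$labels
    keep_p <- logical(max(P, 1L)); keep_p[plab] <- TRUE
    keep_r <- logical(max(R, 1L)); keep_r[rlab] <- TRUE
    both <- P > 0 & R > 0
    both[both] <- keep_p[P[both]] & keep_r[R[both]]
    if (any(both)) {
      ov <- table(pred = P[both], ref = R[both])
      psize <- stats::setNames(predicted$table$pixel_count, plab)
      rsize <- stats::setNames(reference$table$pixel_count, rlab)
      for (i in rownames(ov)) for (j in colnames(ov)) {
        inter <- ov[i, j]
        if (inter == 0) next
        un <- psize[[i]] + rsize[[j]] - inter
        iou <- inter / un * 100
        if (iou > iou_threshold)
          cand <- rbind(cand, data.frame(pred = as.integer(i),
                                         ref = as.integer(j), iou = iou))
      }
    }
  }
  pairs <- data.frame(pred = integer(), ref = integer(), iou = numeric())
  if (nrow(cand)) {
    cand <- cand[order(-cand$iou, cand$pred, cand$ref), , drop = FALSE]
    used_p <- integer(); used_r <- integer()
    for (k in seq_len(nrow(cand))) {
      if (cand$pred[k] %in% used_p || cand$ref[k] %in% used_r) next
      pairs <- rbind(pairs, cand[k, ])
      used_p <- c(used_p, cand$pred[k])
      used_r <- c(used_r, cand$ref[k])
    }
  }
  tp <- nrow(pairs)
  structure(list(tp = tp, fp = np - tp, fn = nr - tp,
                 matched_ious = pairs$iou, n_predicted = np,
                 n_reference = nr, pairs = pairs),
            class = "detection_counts")
}

#' Build detection counts directly from tallies
#'
#' @param tp,fp,fn integer tallies of matched predictions, unmatched
#'   predictions, and missed reference crowns.
#' @return a `detection_counts` list.
#' @export
detection_counts <- function(tp, fp, fn) {
  structure(list(tp = tp, fp = fp, fn = fn, matched_ious = numeric(),
                 n_predicted = tp + fp, n_reference = tp + fn,
                 pairs = NULL), class = "detection_counts")
}

#' Detection precision, recall and F1 score
#'
#' P = TP / (TP + FP) x 100, R = TP / (TP + FN) x 100,
#' F1 = 2PR / (P + R). A zero denominator makes the corresponding metric
#' undefined (`NA`), never 0.
#'
#' @param counts a `detection_counts` (from [match_crowns()] or
#'   [detection_counts()]).
#' @return list with `precision`, `recall`, `f1`, all in percent.
#' @export
detection_metrics <- function(counts) {
  stopifnot(inherits(counts, "detection_counts"))
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  precision <- if (tp + fp > 0) tp / (tp + fp) * 100 else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) * 100 else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  list(precision = precision, recall = recall, f1 = f1)
}

#' Regression accuracy: R2, RMSE and relative RMSE
#'
#' Measures agreement between estimated and reference crown attributes.
#' RMSE = sqrt(sum((y - x)^2) / N) and rRMSE = RMSE / mean(x) x 100. The
#' coefficient of determination is computed as
#' R2 = 1 - sum((y - x)^2) / sum((y - mean(y))^2), i.e. with the estimate
#' mean in the denominator; set `conventional = TRUE` for the textbook form
#' with the reference mean.
#'
#' @param reference,estimate numeric vectors of equal length (n >= 2),
#'   reference values x and model estimates y in the same units.
#' @param conventional use sum((x - mean(x))^2) as the R2 denominator.
#' @return list with `r2`, `rmse`, `rrmse` (percent) and `n`.
#' @export
regression_metrics <- function(reference, estimate, conventional = FALSE) {
  x <- as.numeric(reference); y <- as.numeric(estimate)
  if (length(x) != length(y)) stop("reference and estimate lengths differ")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2L) stop("need at least 2 pairs")
  sse <- sum((y - x)^2)
  den <- if (conventional) sum((x - mean(x))^2) else sum((y - mean(y))^2)
  r2 <- if (den > 0) 1 - sse / den else NA_real_
  rmse <- sqrt(sse / n)
  rrmse <- if (mean(x) != 0) rmse / mean(x) * 100 else NA_real_
  list(r2 = r2, rmse = rmse, rrmse = rrmse, n = n)
}

#' Evaluate a predicted crown mask against reference crowns
#'
#' Full accuracy protocol: extract predicted instances, drop
#' border-incomplete crowns on both sides, match one-to-one at the IoU
#' threshold, compute detection metrics, then regression metrics for crown
#' width and crown projection area (and height when both sides carry it)
#' over the matched pairs.
#'
#' @param pred_mask predicted binary \{0, 255\} matrix.
#' @param reference a `crown_instances` object, or a reference \{0, 255\}
#'   mask from which instances are extracted.
#' @param resolution meters per pixel.
#' @param ref_metrics optional data frame overriding the reference per-crown
#'   attributes (columns `label`, and any of `cw_mean_m`, `cpa_m2`,
#'   `height_m`), e.g. field-measured values keyed to reference labels.
#' @param chm optional canopy height matrix for height estimation.
#' @param iou_threshold match acceptance threshold, percent (default 50).
#' @param min_crown_pixels speckle filter for predicted instances.
#' @param keep_border keep border-touching crowns (default `FALSE`).
#' @return a `crown_report`: list with `counts`, `detection` (precision,
#'   recall, f1), `mean_matched_iou`, `pooled_iou` (both percent), and a
#'   `regression` block per attribute.
#' @export
evaluate_run <- function(pred_mask, reference, resolution, ref_metrics = NULL,
                         chm = NULL, iou_threshold = 50,
                         min_crown_pixels = 50L, keep_border = FALSE) {
  pred <- extract_crown_instances(pred_mask, resolution, min_crown_pixels)
  if (is.matrix(reference))
    reference <- extract_crown_instances(reference, resolution,
                                         min_crown_pixels = 1L)
  stopifnot(inherits(reference, "crown_instances"))
  if (!is.null(chm)) {
    pred <- estimate_tree_height(chm, pred)
    if (all(is.na(reference$table$height_m)))
      reference <- estimate_tree_height(chm, reference)
  }
  if (!keep_border) {
    pred <- filter_border_crowns(pred)
    reference <- filter_border_crowns(reference)
  }
  counts <- match_crowns(pred, reference, iou_threshold)
  det <- detection_metrics(counts)
  mean_iou <- if (counts$tp > 0) mean(counts$matched_ious) else NA_real_
  pooled <- tryCatch(compute_iou(pred$labels > 0, reference$labels > 0),
                     error = function(e) NA_real_)
  rtab <- reference$table
  if (!is.null(ref_metrics)) {
    stopifnot("label" %in% names(ref_metrics))
    for (col in intersect(c("cw_mean_m", "cpa_m2", "height_m"),
                          names(ref_metrics)))
      rtab[[col]] <- ref_metrics[[col]][match(rtab$label, ref_metrics$label)]
  }
  regression <- list()
  if (counts$tp >= 2) {
    pm <- counts$pairs
    ptab <- pred$table
    for (attr in c("cw_mean_m", "cpa_m2", "height_m")) {
      x <- rtab[[attr]][match(pm$ref, rtab$label)]
      y <- ptab[[attr]][match(pm$pred, ptab$label)]
      if (sum(is.finite(x) & is.finite(y)) >= 2)
        regression[[attr]] <- regression_metrics(x, y)
    }
  } else if (counts$tp < 2) {
    warning("fewer than 2 matched pairs; regression block omitted")
  }
  structure(list(counts = counts, detection = det,
                 mean_matched_iou = mean_iou, pooled_iou = pooled,
                 regression = regression, predicted = pred,
                 reference = reference),
            class = "crown_report")
}

#' @export
print.crown_report <- function(x, digits = 2, ...) {
  c_ <- x$counts; d <- x$detection
  cat("Crown detection\n")
  cat(sprintf("  predicted %d  reference %d  TP %d  FP %d  FN %d\n",
              c_$n_predicted, c_$n_reference, c_$tp, c_$fp, c_$fn))
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.*f", digits, v))
  cat(sprintf("  precision %s%%  recall %s%%  F1 %s%%\n",
              fmt(d$precision), fmt(d$recall), fmt(d$f1)))
  cat(sprintf("  mean matched IoU %s%%  pooled pixel IoU %s%%\n",
              fmt(x$mean_matched_iou), fmt(x$pooled_iou)))
  for (nm in names(x$regression)) {
    r <- x$regression[[nm]]
    cat(sprintf("  %s: R2 %.4f  RMSE %.4f  rRMSE %s%%  (n=%d)\n",
                nm, r$r2, r$rmse, fmt(r$rrmse), r$n))
  }
  invisible(x)
}

#' Serialise a crown report to JSON
#'
#' @param report a `crown_report`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "crown_report"))
  out <- list(
    counts = report$counts[c("tp", "fp", "fn", "n_predicted", "n_reference")],
    detection = report$detection,
    mean_matched_iou = report$mean_matched_iou,
    pooled_iou = report$pooled_iou,
    regression = report$regression)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
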