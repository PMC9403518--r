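#' Extract crown instances from a binary mask
#'
#' Connected components of the crown class (value 255) under 8-connectivity
#' become crown instances. Components smaller than `min_crown_pixels` are
#' dropped as speckle. For each instance the crown projection area (CPA) is
#' pixel count x resolution^2, and crown width is measured by Canny edge
#' extraction on the component followed by a direct least-squares ellipse
#' fit: the major and minor axis lengths give the maximum and minimum crown
#' width and their mean the reported crown width.
#'
#' @param mask matrix with values in \{0, 255\}.
#' @param resolution meters per pixel (> 0).
#' @param min_crown_pixels smallest component kept (default 50, about
#'   0.012 m2 at a 0.0153 m resolution).
#' @param enclosing use the minimum-area style bounding ellipse of the edge
#'   points instead of the least-squares fit (default `FALSE`).
#' @return A `crown_instances` object: list with `table` (one row per
#'   instance: label, pixel_count, cpa_m2, cw_max_m, cw_min_m, cw_mean_m,
#'   height_m, touches_border, unfittable), `labels` (the label matrix) and
#'   `resolution`.
#' @export
extract_crown_instances <- function(mask, resolution, min_crown_pixels = 50L,
                                    enclosing = FALSE) {
  stopifnot(is.matrix(mask))
  if (!all(mask %in% c(0, 255)))
    stop("mask must be binary with values in {0, 255}")
  if (resolution <= 0) stop("resolution must be positive")
  lab <- cpp_label8(matrix(as.integer(mask != 0), nrow(mask)))
  nlab <- max(lab)
  H <- nrow(mask); W <- ncol(mask)
  rows <- list()
  for (l in seq_len(nlab)) {
    px <- which(lab == l, arr.ind = TRUE)
    if (nrow(px) < min_crown_pixels) {
      lab[lab == l] <- 0L
      next
    }
    touches <- any(px[, 1] == 1L | px[, 1] == H | px[, 2] == 1L | px[, 2] == W)
    fit <- tryCatch(
      fit_crown_ellipse_px(px, resolution, enclosing = enclosing),
      error = function(e) NULL)
    rows[[length(rows) + 1L]] <- data.frame(
      label = l, pixel_count = nrow(px),
      cpa_m2 = nrow(px) * resolution^2,
      cw_max_m = if (is.null(fit)) NA_real_ else fit$cw_max,
      cw_min_m = if (is.null(fit)) NA_real_ else fit$cw_min,
      cw_mean_m = if (is.null(fit)) NA_real_ else fit$cw_mean,
      height_m = NA_real_, touches_border = touches,
      unfittable = is.null(fit))
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = integer(), pixel_count = integer(),
               cpa_m2 = numeric(), cw_max_m = numeric(),
               cw_min_m = numeric(), cw_mean_m = numeric(),
               height_m = numeric(), touches_border = logical(),
               unfittable = logical())
  structure(list(table = tab, labels = lab, resolution = resolution),
            class = "crown_instances")
}

#' @export
print.crown_instances <- function(x, ...) {
  cat(sprintf("<crown_instances> %d instance(s) at %.6g m/px\n",
              nrow(x$table), x$resolution))
  if (nrow(x$table)) print(utils::head(x$table, 10))
  invisible(x)
}

#' Crown width from an ellipse fitted to a component's edge
#'
#' Renders the component into a padded crop, extracts its edge pixels with
#' Canny's algorithm, and fits an ellipse to the edge points by direct least
#' squares. Full axis lengths scaled by the resolution give the maximum and
#' minimum crown width; the crown width is their mean.
#'
#' @param component either a logical/binary matrix of the component or a
#'   two-column matrix of (row, col) pixel indices.
#' @param resolution meters per pixel.
#' @param enclosing fit the smallest covering ellipse of the edge points
#'   (axis-aligned second-moment scaling) rather than least squares.
#' @return list with `cw_max`, `cw_min`, `cw_mean` (meters) and `ellipse`
#'   (center, semi-axes and orientation in pixel units of the original
#'   mask frame).
#' @export
fit_crown_ellipse <- function(component, resolution, enclosing = FALSE) {
  stopifnot(is.matrix(component))
  fit_crown_ellipse_px(which(component != 0, arr.ind = TRUE), resolution,
                       enclosing)
}

# same, from a 2-column (row, col) pixel index matrix
fit_crown_ellipse_px <- function(px, resolution, enclosing = FALSE) {
  if (nrow(px) < 5L) stop("component too small for an ellipse fit")
  pad <- 3L
  r0 <- min(px[, 1]) - pad; c0 <- min(px[, 2]) - pad
  crop <- matrix(0, max(px[, 1]) - r0 + pad + 1L, max(px[, 2]) - c0 + pad + 1L)
  crop[cbind(px[, 1] - r0, px[, 2] - c0)] <- 255
  edges <- canny_edges(crop)
  ep <- which(edges, arr.ind = TRUE)
  if (nrow(ep) < 5L) stop("fewer than 5 edge pixels; cannot fit a conic")
  pts <- cbind(x = ep[, 2], y = ep[, 1]) # (col, row) as (x, y)
  if (enclosing) {
    fit <- enclosing_ellipse(pts)
  } else {
    fit <- fit_ellipse_direct(pts)
  }
  fit$center <- c(row = unname(fit$center["y"]) + r0,
                  col = unname(fit$center["x"]) + c0)
  cw_max <- 2 * fit$semi_major * resolution
  cw_min <- 2 * fit$semi_minor * resolution
  list(cw_max = cw_max, cw_min = cw_min, cw_mean = (cw_max + cw_min) / 2,
       ellipse = fit)
}

# Covering ellipse from second moments, inflated so all points fall inside:
# a deterministic stand-in for the minimum-area enclosing ellipse.
enclosing_ellipse <- function(pts) {
  mu <- colMeans(pts)
  X <- sweep(pts, 2, mu)
  S <- crossprod(X) / nrow(X)
  eg <- eigen(S, symmetric = TRUE)
  # Mahalanobis radius of the farthest point sets the scale
  Si <- solve(S)
  d2 <- rowSums((X %*% Si) * X)
  r <- sqrt(max(d2))
  axes <- r * sqrt(eg$values)
  list(center = c(x = mu[1], y = mu[2]),
       semi_major = max(axes), semi_minor = min(axes),
       theta = atan2(eg$vectors[2, 1], eg$vectors[1, 1]) %% pi)
}

#' Tree height from a canopy height model
#'
#' Tree height of a crown is the maximum CHM value over the crown's pixels.
#'
#' @param chm canopy height matrix co-registered with the instances' mask.
#' @param instances a `crown_instances` object.
#' @param label if given, return the height of that single instance as a
#'   scalar; otherwise fill `height_m` for every instance and return the
#'   updated object.
#' @return scalar height (m) or updated `crown_instances`.
#' @export
estimate_tree_height <- function(chm, instances, label = NULL) {
  stopifnot(inherits(instances, "crown_instances"), is.matrix(chm))
  if (!all(dim(chm) == dim(instances$labels)))
    stop("chm and instance mask must share dimensions")
  one <- function(l) {
    v <- chm[instances$labels == l]
    if (!length(v)) stop("instance ", l, " has no pixels")
    max(v)
  }
  if (!is.null(label)) return(one(label))
  if (nrow(instances$table))
    instances$table$height_m <- vapply(instances$table$label, one, 1.0)
  instances
}

#' Drop crowns clipped by the raster border
#'
#' Crowns touching the image edge are incomplete shapes; they are excluded
#' from width/area accuracy assessment.
#'
#' @param instances a `crown_instances` object.
#' @return a `crown_instances` with border-touching instances removed (their
#'   labels are also cleared from the label matrix).
#' @export
filter_border_crowns <- function(instances) {
  stopifnot(inherits(instances, "crown_instances"))
  drop <- instances$table$label[instances$table$touches_border]
  if (length(drop))
    instances$labels[instances$labels %in% drop] <- 0L
  instances$table <- instances$table[!instances$table$touches_border, ,
                                     drop = FALSE]
  rownames(instances$table) <- NULL
  instances
}

#' Measure crowns in a mask and write a CSV report
#'
#' Convenience wrapper: extracts instances, optionally attaches CHM-derived
#' heights, and returns (and optionally writes) the per-crown table.
#'
#' @param mask binary \{0, 255\} matrix.
#' @param resolution meters per pixel.
#' @param chm optional canopy height matrix.
#' @param out optional CSV path.
#' @inheritParams extract_crown_instances
#' @return the `crown_instances` object (invisibly if `out` is given).
#' @export
measure_crowns <- function(mask, resolution, chm = NULL, out = NULL,
                           min_crown_pixels = 50L) {
  inst <- extract_crown_instances(mask, resolution, min_crown_pixels)
  if (!is.null(chm)) inst <- estimate_tree_height(chm, inst)
  if (!is.null(out)) {
    utils::write.csv(inst$table, out, row.names = FALSE)
    return(invisible(inst))
  }
  inst
}
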