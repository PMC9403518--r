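#' Generate a seeded synthetic orchard scene
#'
#' Emulates a low-hill oil-tea orchard as seen by a UAV survey: an RGB
#' orthomosaic of green elliptical crowns (radial colour falloff plus pixel
#' jitter) over an earth-toned background, a DSM combining a smooth
#' low-amplitude terrain with an elliptic-paraboloid height dome per crown,
#' a binary ground-truth mask, and a per-crown truth table. Crown widths are
#' drawn from a scaled Beta distribution spanning `cw_range` with mean near
#' 2 m, matching the surveyed stand statistics (min 1.16 m, max 3.47 m,
#' mean 1.99 m); tree heights stay below `height_max` (shrub habit, < 3 m).
#'
#' @param n_crowns number of crowns to place.
#' @param size scene side length in pixels (square scene).
#' @param resolution meters per pixel (default 0.01532703).
#' @param cw_range crown width range in meters (default c(1.16, 3.47)).
#' @param height_max upper bound on tree height in meters (default 3).
#' @param overlap_allowed if `FALSE` (default), crowns are placed by
#'   rejection sampling with a minimum center spacing so components stay
#'   separate.
#' @param noise_sd additive background/crown colour noise, digital numbers
#'   (default 8).
#' @param seed integer seed; identical seeds give bit-identical scenes.
#' @return list with `stack` (a [raster_stack()] carrying red, green, blue,
#'   dsm) and `truth` (class `scene_truth`: `crowns` data frame with
#'   center/axes/orientation/height and derived cw/cpa truth, `mask`,
#'   `terrain`, `resolution`).
#' @examples
#' sc <- gen_scene(3, size = 256, seed = 7)
#' nrow(sc$truth$crowns)
#' @export
gen_scene <- function(n_crowns, size, resolution = 0.01532703,
                      cw_range = c(1.16, 3.47), height_max = 3.0,
                      overlap_allowed = FALSE, noise_sd = 8, seed = 1L) {
  stopifnot(n_crowns >= 0, size >= 32)
  set.seed(seed)
  H <- W <- as.integer(size)

  # terrain: gentle tilted plane plus a long-wavelength undulation (~0.5 m)
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  terrain <- 100 + 0.3 * rr / H + 0.2 * cc / W +
    0.15 * sin(2 * pi * rr / H) * cos(2 * pi * cc / W)

  # crown geometry: cw ~ scaled Beta(2, 3.57) over cw_range (mean ~1.99 m)
  crowns <- NULL
  if (n_crowns > 0) {
    cw <- cw_range[1] + diff(cw_range) * stats::rbeta(n_crowns, 2, 3.57)
    ratio <- stats::runif(n_crowns, 0.75, 0.95)
    major_px <- cw * 2 / (1 + ratio) / resolution   # full major axis, px
    minor_px <- ratio * major_px
    theta <- stats::runif(n_crowns, 0, pi)
    height <- stats::runif(n_crowns, 0.4 * height_max, 0.95 * height_max)
    a <- major_px / 2; b <- minor_px / 2
    centers <- matrix(NA_real_, n_crowns, 2)
    # place the largest crowns first: small ones slot into the gaps
    order_by_size <- order(a, decreasing = TRUE)
    for (i in order_by_size) {
      margin <- a[i] + 3
      if (2 * margin >= min(H, W))
        stop("scene too small for a crown of width ", round(cw[i], 2), " m")
      placed <- FALSE
      for (try in seq_len(2000L)) {
        cand <- c(stats::runif(1, margin, H - margin),
                  stats::runif(1, margin, W - margin))
        prev <- which(!is.na(centers[, 1]))
        ok <- overlap_allowed || !length(prev) ||
          all(sqrt((centers[prev, 1] - cand[1])^2 +
                   (centers[prev, 2] - cand[2])^2) > a[prev] + a[i] + 3)
        if (ok) { centers[i, ] <- cand; placed <- TRUE; break }
      }
      if (!placed)
        stop("could not place crown ", i, " without overlap; the scene is ",
             "too small for ", n_crowns, " crowns at this width range")
    }
    crowns <- data.frame(id = seq_len(n_crowns),
                         center_row = centers[, 1], center_col = centers[, 2],
                         major_px = major_px, minor_px = minor_px,
                         orientation = theta, height_m = height,
                         cw_mean_m = (major_px + minor_px) / 2 * resolution)
  }

  mask <- matrix(0, H, W)
  dome <- matrix(0, H, W)
  rho2 <- matrix(NA_real_, H, W)  # normalized squared radius inside a crown
  pixel_count <- integer(if (is.null(crowns)) 0 else n_crowns)
  if (!is.null(crowns)) for (i in seq_len(n_crowns)) {
    a <- crowns$major_px[i] / 2; b <- crowns$minor_px[i] / 2
    th <- crowns$orientation[i]
    r0 <- crowns$center_row[i]; c0 <- crowns$center_col[i]
    rs <- max(1L, floor(r0 - a)):min(H, ceiling(r0 + a))
    cs <- max(1L, floor(c0 - a)):min(W, ceiling(c0 + a))
    dr <- matrix(rs - r0, length(rs), length(cs))
    dc <- matrix(cs - c0, length(rs), length(cs), byrow = TRUE)
    # rotate into the ellipse frame (x along the major axis)
    xr <- dc * cos(th) + dr * sin(th)
    yr <- -dc * sin(th) + dr * cos(th)
    q <- (xr / a)^2 + (yr / b)^2
    inside <- q <= 1
    pixel_count[i] <- sum(inside)
    sub <- cbind(rep(rs, times = length(cs))[inside],
                 rep(cs, each = length(rs))[inside])
    mask[sub] <- 255
    dome[sub] <- pmax(dome[sub], crowns$height_m[i] * (1 - q[inside]))
    rho2[sub] <- q[inside]
  }
  if (!is.null(crowns)) {
    crowns$pixel_count <- pixel_count
    crowns$cpa_m2 <- pixel_count * resolution^2
  }

  dsm <- terrain + dome
  # colours: earth-toned ground, green crowns with radial falloff
  red <- matrix(120, H, W); green <- matrix(100, H, W)
  blue <- matrix(80, H, W)
  inb <- !is.na(rho2)
  if (any(inb)) {
    fall <- 1 - rho2[inb]
    red[inb] <- 55 + 15 * fall
    green[inb] <- 105 + 55 * fall
    blue[inb] <- 45 + 10 * fall
  }
  n <- H * W
  red <- red + stats::rnorm(n, sd = noise_sd)
  green <- green + stats::rnorm(n, sd = noise_sd)
  blue <- blue + stats::rnorm(n, sd = noise_sd)
  clamp8 <- function(x) matrix(pmin(pmax(round(x), 0), 255), H, W)
  px <- array(0, c(H, W, 4))
  px[, , 1] <- clamp8(red); px[, , 2] <- clamp8(green)
  px[, , 3] <- clamp8(blue); px[, , 4] <- dsm
  stack <- raster_stack(px, c("red", "green", "blue", "dsm"), resolution)

  truth <- structure(list(crowns = crowns, mask = mask, terrain = terrain,
                          resolution = resolution, seed = seed),
                     class = "scene_truth")
  list(stack = stack, truth = truth)
}

#' @export
print.scene_truth <- function(x, ...) {
  n <- if (is.null(x$crowns)) 0L else nrow(x$crowns)
  cat(sprintf("<scene_truth> %d crown(s), %d x %d px, %.6g m/px (seed %d)\n",
              n, nrow(x$mask), ncol(x$mask), x$resolution, x$seed))
  invisible(x)
}

#' Turn a scene into training tiles for a band combination
#'
#' Derives any bands the combination needs (EXG from the colour bands, CHM
#' via [derive_dem()] and [compute_chm()]), stacks them in recipe order with
#' per-band normalisation, tiles the grid with the truth mask as labels, and
#' optionally applies rotation augmentation.
#'
#' @param scene list from [gen_scene()] (or a [raster_stack()]).
#' @param truth a `scene_truth` (defaults to `scene$truth`).
#' @param combo a [band_combination()] or name.
#' @param tile_size chip side (default 256).
#' @param augment apply the x4 rotation augmentation.
#' @param min_window,mean_window DEM filter windows (see [derive_dem()]).
#' @param max_height elevation normalisation ceiling in meters.
#' @return a `crown_tileset`.
#' @export
scene_to_tiles <- function(scene, truth = NULL, combo = "RGB-CHM",
                           tile_size = 256L, augment = FALSE,
                           min_window = 20L, mean_window = 5L,
                           max_height = 5) {
  if (inherits(scene, "raster_stack")) stack <- scene
  else { stack <- scene$stack; if (is.null(truth)) truth <- scene$truth }
  stopifnot(inherits(stack, "raster_stack"), inherits(truth, "scene_truth"))
  if (is.character(combo)) combo <- band_combination(combo)
  if ("chm" %in% combo$bands && !has_band(stack, "chm")) {
    if (!has_band(stack, "dsm"))
      stop("band combination ", combo$name,
           " needs a CHM but the stack has no dsm band to derive it from")
    dsm <- get_band(stack, "dsm")
    stack <- set_band(stack, "chm",
                      compute_chm(dsm, derive_dem(dsm, min_window,
                                                  mean_window)))
  }
  grid <- stack_bands(stack, combo, normalize = TRUE,
                      max_height = max_height)
  tiles <- tile_pair(grid, truth$mask, tile_size)
  if (augment) tiles <- augment_rotations(tiles)
  tiles
}
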