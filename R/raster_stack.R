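#' Multi-band raster stack
#'
#' Container for a pixel-aligned set of raster bands (orthomosaic channels,
#' DSM, DEM, CHM, EXG) sharing one grid and one ground resolution.
#'
#' @param pixels 3-D numeric array (rows x cols x bands), or a matrix for a
#'   single band.
#' @param band_names character vector naming each band, e.g.
#'   `c("red", "green", "blue")`. Recognised names used elsewhere in the
#'   pipeline: `red`, `green`, `blue`, `dsm`, `dem`, `chm`, `exg`.
#' @param resolution ground sampling distance in meters per pixel (> 0).
#' @param nodata optional sentinel value marking missing pixels.
#'
#' @return An object of class `raster_stack`.
#' @examples
#' px <- array(runif(8 * 8 * 3), c(8, 8, 3))
#' rs <- raster_stack(px, c("red", "green", "blue"), resolution = 0.0153)
#' dim(get_band(rs, "green"))
#' @export
raster_stack <- function(pixels, band_names, resolution, nodata = NULL) {
  if (is.matrix(pixels)) pixels <- array(pixels, c(dim(pixels), 1L))
  stopifnot(is.array(pixels), length(dim(pixels)) == 3L)
  if (length(band_names) != dim(pixels)[3])
    stop("band_names length (", length(band_names),
         ") must equal band count (", dim(pixels)[3], ")")
  if (!is.numeric(resolution) || length(resolution) != 1L || resolution <= 0)
    stop("resolution must be a positive scalar (meters per pixel)")
  structure(
    list(pixels = pixels, band_names = as.character(band_names),
         resolution = resolution, nodata = nodata),
    class = "raster_stack")
}

#' @export
print.raster_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<raster_stack> %d x %d px, %d band(s) [%s], %.6g m/px\n",
              d[1], d[2], d[3], paste(x$band_names, collapse = ", "),
              x$resolution))
  invisible(x)
}

#' @export
dim.raster_stack <- function(x) dim(x$pixels)

#' Extract one band as a matrix
#' @param stack a [raster_stack()].
#' @param name band name.
#' @return numeric matrix.
#' @export
get_band <- function(stack, name) {
  stopifnot(inherits(stack, "raster_stack"))
  i <- match(name, stack$band_names)
  if (is.na(i)) stop("band '", name, "' not present in stack (has: ",
                     paste(stack$band_names, collapse = ", "), ")")
  stack$pixels[, , i]
}

#' Test whether a band is present
#' @inheritParams get_band
#' @return logical.
#' @export
has_band <- function(stack, name) name %in% stack$band_names

#' Add or replace a band
#' @inheritParams get_band
#' @param values numeric matrix matching the stack's grid.
#' @return the modified `raster_stack`.
#' @export
set_band <- function(stack, name, values) {
  stopifnot(inherits(stack, "raster_stack"), is.matrix(values))
  d <- dim(stack$pixels)
  if (!all(dim(values) == d[1:2]))
    stop("band '", name, "' dimensions do not match the stack grid")
  i <- match(name, stack$band_names)
  if (is.na(i)) {
    px <- array(0, c(d[1], d[2], d[3] + 1L))
    px[, , seq_len(d[3])] <- stack$pixels
    px[, , d[3] + 1L] <- values
    stack$pixels <- px
    stack$band_names <- c(stack$band_names, name)
  } else {
    stack$pixels[, , i] <- values
  }
  stack
}

#' Input band combinations
#'
#' The six supported model-input recipes and their layer counts: plain colour
#' (`RGB`), colour plus an elevation layer (`RGB-DSM`, `RGB-CHM`), the excess
#' green index alone (`EXG`), and EXG plus an elevation layer (`EXG-DSM`,
#' `EXG-CHM`). Colour combinations are layered blue, green, red, then the
#' elevation band.
#'
#' @param name combination name, one of
#'   `"RGB", "RGB-DSM", "RGB-CHM", "EXG", "EXG-DSM", "EXG-CHM"`.
#' @return A list with elements `name`, `layers` (integer layer count), and
#'   `bands` (ordered band names drawn from the stack).
#' @examples
#' band_combination("RGB-CHM")$layers  # 4
#' @export
band_combination <- function(name) {
  name <- toupper(name)
  recipes <- list(
    "RGB"     = c("blue", "green", "red"),
    "RGB-DSM" = c("blue", "green", "red", "dsm"),
    "RGB-CHM" = c("blue", "green", "red", "chm"),
    "EXG"     = "exg",
    "EXG-DSM" = c("exg", "dsm"),
    "EXG-CHM" = c("exg", "chm"))
  if (!name %in% names(recipes))
    stop("unknown band combination '", name, "'; expected one of ",
         paste(names(recipes), collapse = ", "))
  bands <- recipes[[name]]
  structure(list(name = name, layers = length(bands), bands = bands),
            class = "band_combination")
}

#' List all supported band combinations
#' @return character vector of the six combination names.
#' @export
band_combinations <- function() {
  c("RGB", "RGB-DSM", "RGB-CHM", "EXG", "EXG-DSM", "EXG-CHM")
}

#' Assemble the model-input layer grid for a band combination
#'
#' Orders the required source bands into a 3-D grid (rows x cols x layers).
#' If the combination needs `exg` and the stack lacks it but carries red,
#' green and blue, EXG is computed on the fly.
#'
#' @param stack a [raster_stack()].
#' @param combo a [band_combination()] or its name.
#' @param normalize if `TRUE`, colour/EXG bands are min-max scaled to
#'   \[0, 1\] over the grid and elevation bands are divided by `max_height`.
#' @param max_height normalisation ceiling for elevation bands, meters.
#' @return 3-D array with `combo$layers` layers in recipe order.
#' @export
stack_bands <- function(stack, combo, normalize = FALSE, max_height = 5) {
  stopifnot(inherits(stack, "raster_stack"))
  if (is.character(combo)) combo <- band_combination(combo)
  if ("exg" %in% combo$bands && !has_band(stack, "exg")) {
    if (all(c("red", "green", "blue") %in% stack$band_names)) {
      stack <- set_band(stack, "exg",
                        compute_exg(get_band(stack, "red"),
                                    get_band(stack, "green"),
                                    get_band(stack, "blue")))
    }
  }
  missing <- setdiff(combo$bands, stack$band_names)
  if (length(missing))
    stop("band combination ", combo$name, " requires band(s) missing from ",
         "the stack: ", paste(missing, collapse = ", "))
  d <- dim(stack$pixels)
  out <- array(0, c(d[1], d[2], combo$layers))
  elev <- c("dsm", "dem", "chm")
  for (k in seq_along(combo$bands)) {
    b <- get_band(stack, combo$bands[k])
    if (normalize) {
      if (combo$bands[k] %in% elev) {
        # elevations are relative to the grid minimum, scaled by max_height
        b <- pmin(pmax((b - min(b)) / max_height, 0), 1)
      } else {
        rng <- range(b)
        b <- if (diff(rng) > 0) (b - rng[1]) / diff(rng) else b * 0
      }
    }
    out[, , k] <- b
  }
  out
}
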