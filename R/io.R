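# Raster IO built on the tiff/png packages. Plain (non-georeferenced) TIFF
# and PNG are supported; the ground resolution is supplied explicitly since
# no GDAL-backed reader is used.

#' Read a raster file into a stack
#'
#' @param path TIFF or PNG file. 8-bit images are read as raw digital
#'   numbers (0-255); float TIFFs (e.g. DSM layers) written by
#'   [write_raster()] are restored to their original values via the `.json`
#'   scaling sidecar stored next to them.
#' @param resolution meters per pixel for the returned stack.
#' @param band_names names for the layers; defaults to `red`, `green`,
#'   `blue`(, `alpha`) for 3-4 band images and `band1` style otherwise.
#' @return a [raster_stack()].
#' @export
read_raster <- function(path, resolution, band_names = NULL) {
  ext <- tolower(tools::file_ext(path))
  side <- paste0(path, ".json")
  img <- switch(ext,
    tif = , tiff = if (file.exists(side)) {
      s <- jsonlite::read_json(side)
      tiff::readTIFF(path) * s$scale + s$offset
    } else {
      round(tiff::readTIFF(path) * 255, 9)
    },
    png = png::readPNG(path) * 255,
    stop("unsupported raster format: .", ext))
  if (is.matrix(img)) img <- array(img, c(dim(img), 1L))
  nb <- dim(img)[3]
  if (is.null(band_names)) {
    band_names <- if (nb %in% 3:4) c("red", "green", "blue", "alpha")[1:nb]
    else paste0("band", seq_len(nb))
  }
  raster_stack(img, band_names, resolution)
}

#' Write a single band or multi-band grid as TIFF
#'
#' Float data (e.g. elevation in meters) is min-max scaled into \[0, 1\],
#' written as 32-bit samples, and the offset/scale recorded in a `.json`
#' sidecar next to the file so [read_raster()] can restore the original
#' values. Values already in 0-255 with `uint8 = TRUE` are written as plain
#' 8-bit samples with no sidecar.
#'
#' @param x matrix or 3-D array.
#' @param path output `.tif` path.
#' @param uint8 write 8-bit samples (input expected in 0-255).
#' @return the path, invisibly.
#' @export
write_raster <- function(x, path, uint8 = FALSE) {
  if (uint8) {
    tiff::writeTIFF(x / 255, path, bits.per.sample = 8L)
  } else {
    rng <- range(x)
    scale <- if (diff(rng) > 0) diff(rng) else 1
    tiff::writeTIFF((x - rng[1]) / scale, path, bits.per.sample = 32L)
    jsonlite::write_json(list(offset = rng[1], scale = scale),
                         paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Read / write a binary crown mask
#'
#' Masks are single-band rasters with values 0 (background) and 255 (crown).
#' On read, 0/1-coded masks are rescaled to 0/255 and any intermediate
#' values are thresholded at one half.
#'
#' @param path mask file (TIFF or PNG).
#' @return matrix with values in \{0, 255\}.
#' @export
read_mask <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path) * 255,
    png = png::readPNG(path) * 255,
    stop("unsupported mask format: .", ext))
  if (!is.matrix(img)) img <- img[, , 1]
  mx <- max(img)
  if (mx <= 1) img <- img * 255
  (img >= mx / 2 & img > 0) * 255
}

#' @rdname read_mask
#' @param mask matrix with values in \{0, 255\}.
#' @export
write_mask <- function(mask, path) {
  stopifnot(all(mask %in% c(0, 255)))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") png::writePNG(mask / 255, path)
  else tiff::writeTIFF(mask / 255, path, bits.per.sample = 8L)
  invisible(path)
}
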