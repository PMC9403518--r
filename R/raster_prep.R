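#' Excess green index
#'
#' Computes the visible-band vegetation index EXG = 2G - R - B, which
#' highlights green vegetation against earth-toned backgrounds (soil, rock,
#' litter). Values are not clipped; negative values are meaningful and kept.
#'
#' @param red,green,blue numeric matrices of identical dimensions (raw band
#'   values, typically 8-bit digital numbers).
#' @return numeric matrix of the same dimensions.
#' @examples
#' compute_exg(matrix(10), matrix(20), matrix(5))  # 25
#' @export
compute_exg <- function(red, green, blue) {
  if (!all(dim(red) == dim(green)) || !all(dim(red) == dim(blue)))
    stop("red, green and blue bands must share dimensions")
  2 * green - red - blue
}

#' Derive a bare-ground elevation model from a surface model
#'
#' Estimates the DEM by passing the DSM through a moving-minimum filter
#' (suppressing above-ground objects smaller than the window) followed by a
#' moving-mean filter (smoothing the blocky minimum output). Both filters use
#' edge-replication padding so raster margins are not biased downwards.
#'
#' @param dsm numeric matrix of surface elevations (m).
#' @param min_window side of the square minimum-filter window in pixels
#'   (default 20).
#' @param mean_window side of the square mean-filter window in pixels
#'   (default 5).
#' @return numeric matrix, same dimensions: the estimated DEM.
#' @seealso [compute_chm()]
#' @export
derive_dem <- function(dsm, min_window = 20L, mean_window = 5L) {
  stopifnot(is.matrix(dsm))
  if (any(!is.finite(dsm))) stop("dsm must be finite")
  min_window <- as.integer(min_window); mean_window <- as.integer(mean_window)
  if (min_window < 1L || mean_window < 1L)
    stop("filter windows must be positive integers")
  if (min_window > min(dim(dsm)) || mean_window > min(dim(dsm)))
    stop("filter window exceeds raster dimensions (",
         paste(dim(dsm), collapse = " x "), ")")
  cpp_mean_filter(cpp_min_filter(dsm, min_window), mean_window)
}

#' Canopy height model
#'
#' Per-pixel vegetation height above ground: CHM = DSM - DEM. Negative values
#' (DEM locally above DSM, possible after smoothing) are preserved; their
#' count is reported via a message when `quiet = FALSE`.
#'
#' @param dsm,dem numeric matrices of identical dimensions (m).
#' @param quiet suppress the negative-pixel message.
#' @return numeric matrix of canopy heights (m).
#' @export
compute_chm <- function(dsm, dem, quiet = TRUE) {
  if (!all(dim(dsm) == dim(dem)))
    stop("dsm and dem must share dimensions")
  chm <- dsm - dem
  nneg <- sum(chm < 0)
  if (!quiet && nneg > 0)
    message(nneg, " CHM pixel(s) are negative (DEM above DSM)")
  chm
}

#' Cut an input grid and its label mask into training tiles
#'
#' Tiles are taken on a non-overlapping grid anchored at the top-left corner;
#' trailing partial windows are dropped so every chip is exactly
#' `tile_size` x `tile_size`.
#'
#' @param input_grid 3-D numeric array (rows x cols x layers) of model input.
#' @param label_mask 2-D matrix with values in \{0, 255\}, same grid.
#' @param tile_size chip side length in pixels (default 256).
#' @return A `crown_tileset`: list with `tiles` (each a list of `input` array
#'   and `label` matrix), `tile_size`, and `origin_index` (matrix of 1-based
#'   row/col offsets of each tile in the source raster).
#' @export
tile_pair <- function(input_grid, label_mask, tile_size = 256L) {
  if (is.matrix(input_grid)) input_grid <- array(input_grid, c(dim(input_grid), 1L))
  stopifnot(length(dim(input_grid)) == 3L, is.matrix(label_mask))
  d <- dim(input_grid)
  if (!all(d[1:2] == dim(label_mask)))
    stop("input grid and label mask must share row/col dimensions")
  tile_size <- as.integer(tile_size)
  nr <- d[1] %/% tile_size
  nc <- d[2] %/% tile_size
  if (nr < 1L || nc < 1L) {
    warning("raster (", d[1], " x ", d[2], ") is smaller than one ",
            tile_size, "-px tile; returning an empty tile set")
    return(structure(list(tiles = list(), tile_size = tile_size,
                          origin_index = matrix(integer(), 0, 2)),
                     class = "crown_tileset"))
  }
  tiles <- vector("list", nr * nc)
  origin <- matrix(0L, nr * nc, 2, dimnames = list(NULL, c("row", "col")))
  k <- 0L
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      k <- k + 1L
      r0 <- (i - 1L) * tile_size
      c0 <- (j - 1L) * tile_size
      rows <- (r0 + 1L):(r0 + tile_size)
      cols <- (c0 + 1L):(c0 + tile_size)
      tiles[[k]] <- list(input = input_grid[rows, cols, , drop = FALSE],
                         label = label_mask[rows, cols])
      origin[k, ] <- c(r0 + 1L, c0 + 1L)
    }
  }
  structure(list(tiles = tiles, tile_size = tile_size, origin_index = origin),
            class = "crown_tileset")
}

#' @export
print.crown_tileset <- function(x, ...) {
  cat(sprintf("<crown_tileset> %d tile(s) of %d x %d px\n",
              length(x$tiles), x$tile_size, x$tile_size))
  invisible(x)
}

#' @export
length.crown_tileset <- function(x) length(x$tiles)

# rotate a matrix 90 deg counter-clockwise k times
rot90_mat <- function(m, k = 1L) {
  k <- k %% 4L
  for (i in seq_len(k)) m <- t(m)[ncol(m):1, , drop = FALSE]
  m
}

rot90_grid <- function(a, k = 1L) {
  k <- k %% 4L
  if (k == 0L) return(a)
  d <- dim(a)
  nd <- if (k %% 2L == 1L) c(d[2], d[1], d[3]) else d
  out <- array(0, nd)
  for (l in seq_len(d[3])) out[, , l] <- rot90_mat(a[, , l], k)
  out
}

#' Quadruple a tile set by rotation
#'
#' Appends 90, 180 and 270 degree rotations of every (input, label) pair;
#' input and label chips are rotated identically so geometry stays aligned.
#'
#' @param tiles a `crown_tileset` of square tiles.
#' @return a `crown_tileset` with 4x as many tiles (originals first).
#' @export
augment_rotations <- function(tiles) {
  stopifnot(inherits(tiles, "crown_tileset"))
  for (t in tiles$tiles) {
    d <- dim(t$input)
    if (d[1] != d[2]) stop("rotation augmentation requires square tiles")
  }
  out <- tiles$tiles
  for (k in 1:3) {
    out <- c(out, lapply(tiles$tiles, function(t) {
      list(input = rot90_grid(t$input, k), label = rot90_mat(t$label, k))
    }))
  }
  origin <- tiles$origin_index[rep(seq_len(nrow(tiles$origin_index)), 4), ,
                               drop = FALSE]
  structure(list(tiles = out, tile_size = tiles$tile_size,
                 origin_index = origin),
            class = "crown_tileset")
}
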