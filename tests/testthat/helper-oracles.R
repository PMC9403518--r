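# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately re-derive results by direct enumeration so they
# share no code with the implementation paths they check.

# literal double-loop sliding-window filters with edge replication,
# window covering offsets [-(w-1)/2, w/2]
oracle_window_filter <- function(x, w, fun) {
  lo <- -((w - 1) %/% 2); hi <- w %/% 2
  H <- nrow(x); W <- ncol(x)
  out <- x
  for (i in seq_len(H)) for (j in seq_len(W)) {
    rs <- pmin(pmax(i + lo:hi, 1L), H)
    cs <- pmin(pmax(j + lo:hi, 1L), W)
    out[i, j] <- fun(x[rs, cs])
  }
  out
}
oracle_dem <- function(dsm, min_w, mean_w) {
  oracle_window_filter(oracle_window_filter(dsm, min_w, min), mean_w, mean)
}

# rasterize a filled ellipse (full axes in px) into an H x W {0,255} mask
render_ellipse <- function(H, W, center, major, minor, theta = 0) {
  a <- major / 2; b <- minor / 2
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  dr <- rr - center[1]; dc <- cc - center[2]
  xr <- dc * cos(theta) + dr * sin(theta)
  yr <- -dc * sin(theta) + dr * cos(theta)
  ((xr / a)^2 + (yr / b)^2 <= 1) * 255
}

# connected components by literal flood fill (8-neighbourhood), queue-based
oracle_components8 <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W); nxt <- 0L
  for (j in seq_len(W)) for (i in seq_len(H)) {
    if (mask[i, j] == 0 || lab[i, j] > 0) next
    nxt <- nxt + 1L
    queue <- list(c(i, j)); lab[i, j] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) {
        qi <- p[1] + di; qj <- p[2] + dj
        if (qi < 1 || qi > H || qj < 1 || qj > W) next
        if (mask[qi, qj] != 0 && lab[qi, qj] == 0L) {
          lab[qi, qj] <- nxt
          queue[[length(queue) + 1L]] <- c(qi, qj)
        }
      }
    }
  }
  lab
}

# exhaustive one-to-one assignment: maximises match count, then total IoU,
# over all injective pred -> ref maps with IoU strictly above the threshold
oracle_assignment <- function(iou_mat, threshold = 50) {
  np <- nrow(iou_mat); nr <- ncol(iou_mat)
  best <- list(count = -1L, total = -Inf, pairs = NULL)
  recurse <- function(p, used_r, pairs) {
    if (p > np) {
      count <- nrow(pairs)
      total <- if (count) sum(pairs$iou) else 0
      if (count > best$count ||
          (count == best$count && total > best$total + 1e-12))
        best <<- list(count = count, total = total, pairs = pairs)
      return(invisible())
    }
    recurse(p + 1L, used_r, pairs) # leave p unmatched
    for (r in seq_len(nr)) {
      if (r %in% used_r || iou_mat[p, r] <= threshold) next
      recurse(p + 1L, c(used_r, r),
              rbind(pairs, data.frame(pred = p, ref = r,
                                      iou = iou_mat[p, r])))
    }
  }
  recurse(1L, integer(), data.frame(pred = integer(), ref = integer(),
                                    iou = numeric()))
  best
}

# a minimal tile set of solid-crown / solid-background colour chips
make_solid_tileset <- function(n_tiles, tile_size = 64L, noise_sd = 8,
                               seed = 1L) {
  set.seed(seed)
  mk <- function(crown) {
    base <- if (crown) c(60, 130, 45) else c(120, 100, 80)
    inp <- array(0, c(tile_size, tile_size, 3))
    for (k in 1:3)
      inp[, , k] <- (base[k] + stats::rnorm(tile_size^2, sd = noise_sd)) / 255
    list(input = inp,
         label = matrix(if (crown) 255 else 0, tile_size, tile_size))
  }
  structure(list(tiles = lapply(seq_len(n_tiles), function(i) mk(i %% 2 == 0)),
                 tile_size = tile_size,
                 origin_index = matrix(0L, n_tiles, 2)),
            class = "crown_tileset")
}
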