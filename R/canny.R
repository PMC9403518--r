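# Canny edge detection on a single-band image: Gaussian smoothing, Sobel
# gradients, non-maximum suppression along the quantized gradient direction,
# and double-threshold hysteresis. Thresholds are derived from the gradient
# magnitude statistics (median-based), so no tuning is needed per image.

conv2_same <- function(x, k) {
  kr <- nrow(k); kc <- ncol(k)
  pr <- (kr - 1L) %/% 2L; pc <- (kc - 1L) %/% 2L
  H <- nrow(x); W <- ncol(x)
  out <- matrix(0, H, W)
  for (i in seq_len(kr)) for (j in seq_len(kc)) {
    di <- i - 1L - pr; dj <- j - 1L - pc
    rs <- pmin(pmax(seq_len(H) + di, 1L), H)
    cs <- pmin(pmax(seq_len(W) + dj, 1L), W)
    out <- out + k[i, j] * x[rs, cs]
  }
  out
}

gaussian_kernel <- function(sigma = 1, size = 5L) {
  half <- (size - 1L) / 2
  g <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

shift_mat <- function(x, dr, dc) {
  H <- nrow(x); W <- ncol(x)
  rs <- pmin(pmax(seq_len(H) + dr, 1L), H)
  cs <- pmin(pmax(seq_len(W) + dc, 1L), W)
  x[rs, cs]
}

#' Canny edge detection
#'
#' @param img numeric matrix (any scale).
#' @param sigma Gaussian smoothing bandwidth in pixels.
#' @param low,high optional magnitude thresholds; when `NULL` they are set
#'   from the median of the non-zero gradient magnitudes (`high` = 1.33 x
#'   median, `low` = 0.5 x `high`).
#' @return logical matrix of edge pixels.
#' @export
canny_edges <- function(img, sigma = 1, low = NULL, high = NULL) {
  stopifnot(is.matrix(img))
  sm <- conv2_same(img, gaussian_kernel(sigma))
  sx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)  # d/dcol
  sy <- t(sx)                                          # d/drow
  gx <- conv2_same(sm, sx)
  gy <- conv2_same(sm, sy)
  mag <- sqrt(gx^2 + gy^2)
  if (all(mag == 0)) return(matrix(FALSE, nrow(img), ncol(img)))
  if (is.null(high)) {
    med <- stats::median(mag[mag > 0])
    high <- 1.33 * med
  }
  if (is.null(low)) low <- 0.5 * high

  # quantize direction to 0 / 45 / 90 / 135 degrees and suppress non-maxima
  ang <- atan2(gy, gx) * 180 / pi
  ang[ang < 0] <- ang[ang < 0] + 180
  sector <- findInterval(ang, c(22.5, 67.5, 112.5, 157.5)) %% 4L
  keep <- matrix(FALSE, nrow(img), ncol(img))
  # sector 0: horizontal gradient -> compare along columns
  nb <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  for (s in 0:3) {
    d <- nb[[s + 1L]]
    m1 <- shift_mat(mag, d[1], d[2])
    m2 <- shift_mat(mag, -d[1], -d[2])
    keep <- keep | (sector == s & mag >= m1 & mag >= m2)
  }
  strong <- keep & mag >= high
  weak <- keep & mag >= low
  if (!any(strong)) return(strong)
  lab <- cpp_label8(matrix(as.integer(weak), nrow(weak)))
  good <- unique(lab[strong])
  weak & matrix(lab %in% good, nrow(lab))
}

# Halir & Flusser numerically-stable direct least-squares ellipse fit.
# points: two-column matrix (x, y). Returns center, semi-axes (a >= b),
# orientation of the major axis in radians.
fit_ellipse_direct <- function(points) {
  if (nrow(points) < 5L) stop("ellipse fit needs at least 5 points")
  x <- points[, 1]; y <- points[, 2]
  mx <- mean(x); my <- mean(y)
  x <- x - mx; y <- y - my
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  Tm <- tryCatch(-solve(S3, t(S2)), error = function(e)
    stop("degenerate point set (collinear edge pixels)"))
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  # pick the eigenvector satisfying the ellipse constraint 4ac - b^2 > 0
  cond <- 4 * ev$vectors[1, ] * ev$vectors[3, ] - ev$vectors[2, ]^2
  ok <- which(Re(cond) > 0 & abs(Im(ev$values)) < 1e-8)
  if (!length(ok)) stop("degenerate point set (no ellipse solution)")
  a1 <- Re(ev$vectors[, ok[1]])
  coef <- c(a1, as.numeric(Tm %*% a1)) # A B C D E F (centered frame)
  A <- coef[1]; B <- coef[2]; C <- coef[3]
  D <- coef[4]; E <- coef[5]; Fc <- coef[6]
  den <- 4 * A * C - B^2
  xc <- (B * E - 2 * C * D) / den
  yc <- (B * D - 2 * A * E) / den
  F0 <- A * xc^2 + B * xc * yc + C * yc^2 + D * xc + E * yc + Fc
  Q <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  eq <- eigen(Q, symmetric = TRUE)
  lam <- eq$values
  if (any(lam * (-F0) <= 0)) stop("degenerate conic (not an ellipse)")
  axes <- sqrt(-F0 / lam) # semi-axes; lam ascending gives major first
  ord <- order(axes, decreasing = TRUE)
  major_vec <- eq$vectors[, ord[1]]
  list(center = c(x = xc + mx, y = yc + my),
       semi_major = axes[ord[1]], semi_minor = axes[ord[2]],
       theta = atan2(major_vec[2], major_vec[1]) %% pi)
}
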