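# Internal polygon geometry helpers.
#
# Convention used throughout the package: a boundary is an n x 2 matrix of
# (x, y) vertices, x = column index, y = row index, 0-based, origin at the
# top-left pixel center. Polygons are closed implicitly (first vertex is NOT
# repeated at the end). "Counterclockwise" means positive shoelace signed
# area on the (x, y) values.

polygon_signed_area <- function(v) {
  x <- v[, 1L]; y <- v[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

polygon_edge_lengths <- function(v) {
  vn <- rbind(v[-1L, , drop = FALSE], v[1L, , drop = FALSE])
  sqrt(rowSums((vn - v)^2))
}

polygon_perimeter <- function(v) sum(polygon_edge_lengths(v))

#' @noRd
#' Arc-length-weighted (line-integral) moments of a closed polygon boundary.
#' Exact per-edge integrals of 1, x, y, x^2, xy, y^2 against ds, so the
#' result is independent of how the vertex list is indexed.
polygon_line_moments <- function(v) {
  x0 <- v[, 1L]; y0 <- v[, 2L]
  x1 <- c(x0[-1L], x0[1L]); y1 <- c(y0[-1L], y0[1L])
  len <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
  L <- sum(len)
  if (L <= 0) stop("degenerate polygon: zero perimeter", call. = FALSE)
  cx <- sum(len * (x0 + x1) / 2) / L
  cy <- sum(len * (y0 + y1) / 2) / L
  # central second moments
  a0 <- x0 - cx; a1 <- x1 - cx
  b0 <- y0 - cy; b1 <- y1 - cy
  sxx <- sum(len * (a0 * a0 + a0 * a1 + a1 * a1) / 3) / L
  syy <- sum(len * (b0 * b0 + b0 * b1 + b1 * b1) / 3) / L
  sxy <- sum(len * (2 * a0 * b0 + a0 * b1 + a1 * b0 + 2 * a1 * b1) / 6) / L
  list(centroid = c(cx, cy), sxx = sxx, syy = syy, sxy = sxy,
       perimeter = L, rms_radius = sqrt(sxx + syy))
}

#' @noRd
#' Line integral of x^3 ds over the polygon boundary, central in x.
polygon_line_x3 <- function(v, cx) {
  x0 <- v[, 1L] - cx; y0 <- v[, 2L]
  x1 <- c(x0[-1L], x0[1L]); y1 <- c(v[-1L, 2L], v[1L, 2L])
  len <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
  # along an edge x(t) = x0 + t (x1 - x0); int_0^1 x^3 dt in closed form
  d <- x1 - x0
  sum(len * (x0^3 + 1.5 * x0^2 * d + x0 * d^2 + d^3 / 4))
}

rotate_points <- function(v, angle) {
  ca <- cos(angle); sa <- sin(angle)
  cbind(ca * v[, 1L] - sa * v[, 2L], sa * v[, 1L] + ca * v[, 2L])
}

#' @noRd
#' Resample a closed polygon at n points equally spaced in arc length,
#' starting at the first vertex, preserving traversal order.
resample_closed <- function(v, n) {
  vc <- rbind(v, v[1L, , drop = FALSE])
  seg <- sqrt(rowSums(diff(vc)^2))
  per <- sum(seg)
  if (per <= 0) stop("degenerate polygon: zero perimeter", call. = FALSE)
  cs <- c(0, cumsum(seg))
  target <- per * (seq_len(n) - 1L) / n
  idx <- findInterval(target, cs, rightmost.closed = TRUE)
  idx[idx >= length(cs)] <- length(cs) - 1L
  frac <- (target - cs[idx]) / pmax(seg[idx], .Machine$double.xmin)
  p0 <- vc[idx, , drop = FALSE]
  p1 <- vc[idx + 1L, , drop = FALSE]
  p0 + frac * (p1 - p0)
}

#' @noRd
#' Iterate equal-arc-length resampling to its fixed point: a polygon whose
#' edges all have the same length, so that resampling it again returns its
#' own vertices. The first vertex is preserved exactly at every iteration.
resample_equalized <- function(v, n, tol = 1e-12, max_iter = 400L) {
  p <- resample_closed(v, n)
  for (i in seq_len(max_iter)) {
    len <- polygon_edge_lengths(p)
    if (max(abs(len - mean(len))) < tol * mean(len)) break
    p <- resample_closed(p, n)
  }
  p
}

#' @noRd
#' Rasterize a closed polygon onto a height x width pixel grid (centers at
#' 0-based integer coordinates). Returns linear indices into the
#' column-major height x width matrix, by even-odd crossing number.
rasterize_polygon <- function(v, width, height) {
  xr <- range(v[, 1L]); yr <- range(v[, 2L])
  x0 <- max(0L, floor(xr[1L])); x1 <- min(width - 1L, ceiling(xr[2L]))
  y0 <- max(0L, floor(yr[1L])); y1 <- min(height - 1L, ceiling(yr[2L]))
  if (x1 < x0 || y1 < y0) return(integer(0))
  px <- rep(x0:x1, each = y1 - y0 + 1L)
  py <- rep(y0:y1, times = x1 - x0 + 1L)
  inside <- rep(FALSE, length(px))
  nv <- nrow(v)
  j <- nv
  for (i in seq_len(nv)) {
    xi <- v[i, 1L]; yi <- v[i, 2L]
    xj <- v[j, 1L]; yj <- v[j, 2L]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  sel <- which(inside)
  if (!length(sel)) return(integer(0))
  # matrix is indexed [row, col] = [y + 1, x + 1], column-major
  (px[sel]) * height + py[sel] + 1L
}

#' @noRd
#' Minimum distance between the boundaries of two polygons, approximated on
#' densely resampled points. Returns 0 when the polygons overlap.
polygon_min_distance <- function(a, b, n = 128L) {
  pa <- resample_closed(a, n)
  pb <- resample_closed(b, n)
  d2 <- outer(pa[, 1L], pb[, 1L], `-`)^2 + outer(pa[, 2L], pb[, 2L], `-`)^2
  dmin <- sqrt(min(d2))
  if (dmin == 0) return(0)
  # overlap test: any vertex of one inside the other
  if (point_in_polygon(pa[1L, 1L], pa[1L, 2L], b) ||
      point_in_polygon(pb[1L, 1L], pb[1L, 2L], a)) return(0)
  dmin
}

point_in_polygon <- function(px, py, v) {
  nv <- nrow(v)
  j <- nv
  inside <- FALSE
  for (i in seq_len(nv)) {
    xi <- v[i, 1L]; yi <- v[i, 2L]
    xj <- v[j, 1L]; yj <- v[j, 2L]
    if (((yi > py) != (yj > py)) &&
        (px < (xj - xi) * (py - yi) / (yj - yi) + xi)) inside <- !inside
    j <- i
  }
  inside
}
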