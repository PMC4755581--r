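# Shared low-level geometry helpers. Pixel centers sit at integer
# coordinates (1-based); x = column (vessel longitudinal axis), y = row
# (circumferential axis), z = slice.

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

# rotation about the X axis: +Y moves toward +Z for positive angles
rotX <- function(deg) {
  a <- deg2rad(deg)
  matrix(c(1, 0, 0,
           0, cos(a), sin(a),
           0, -sin(a), cos(a)), 3, 3)
}

# rotation about the Z axis (in the XY imaging plane)
rotZ <- function(deg) {
  a <- deg2rad(deg)
  matrix(c(cos(a), sin(a), 0,
           -sin(a), cos(a), 0,
           0, 0, 1), 3, 3)
}

# wrap an angle in degrees into [0, 360)
wrap360 <- function(deg) ((deg %% 360) + 360) %% 360

# fold an undirected axis angle into [-90, 90); +90 maps to -90
fold90 <- function(deg) {
  d <- ((deg + 90) %% 180 + 180) %% 180 - 90
  d[d == 90] <- -90
  d
}

polygonSignedArea <- function(P) {
  n <- nrow(P)
  i2 <- c(2:n, 1)
  sum(P[, 1] * P[i2, 2] - P[i2, 1] * P[, 2]) / 2
}

# even-odd point-in-polygon test (closed polygon, first point not repeated)
pointInPolygon <- function(pt, P) {
  n <- nrow(P)
  j <- c(n, 1:(n - 1))
  x <- P[, 1]; y <- P[, 2]
  xj <- x[j]; yj <- y[j]
  cross <- ((y > pt[2]) != (yj > pt[2])) &
    (pt[1] < (xj - x) * (pt[2] - y) / (yj - y) + x)
  sum(cross) %% 2 == 1
}

# Even-odd scanline rasterization of an unordered soup of line segments
# forming closed loop(s). segs: matrix with columns x1, y1, x2, y2.
# Returns an nx-by-ny logical matrix; a pixel is set when its center lies
# inside the union of loops.
fillSegmentSoupMask <- function(segs, nx, ny) {
  mask <- matrix(FALSE, nx, ny)
  if (is.null(segs) || nrow(segs) == 0) return(mask)
  x1 <- segs[, 1]; y1 <- segs[, 2]; x2 <- segs[, 3]; y2 <- segs[, 4]
  ylo <- pmin(y1, y2); yhi <- pmax(y1, y2)
  for (py in seq_len(ny)) {
    cross <- ylo <= py & yhi > py          # half-open rule at vertices
    if (!any(cross)) next
    t <- (py - y1[cross]) / (y2[cross] - y1[cross])
    xs <- sort(x1[cross] + t * (x2[cross] - x1[cross]))
    if (length(xs) %% 2 == 1) xs <- xs[-length(xs)]   # degenerate tangency
    k <- length(xs) / 2
    if (k == 0) next
    for (i in seq_len(k)) {
      a <- ceiling(xs[2 * i - 1] - 1e-9)
      b <- floor(xs[2 * i] + 1e-9)
      if (b >= a) {
        a <- max(a, 1L); b <- min(b, nx)
        if (b >= a) mask[a:b, py] <- TRUE
      }
    }
  }
  mask
}

# rasterize one closed polygon (first point not repeated) into a mask
fillPolygonMask <- function(P, nx, ny) {
  n <- nrow(P)
  i2 <- c(2:n, 1)
  fillSegmentSoupMask(cbind(P[, 1], P[, 2], P[i2, 1], P[i2, 2]), nx, ny)
}

# Intersections of one ray (origin o, unit direction d) with a set of line
# segments given as columns x1, y1, x2, y2 plus an id column. Returns a
# data.frame with t (distance along ray), x, y, id, sorted by t.
rayIntersections <- function(o, d, edges) {
  if (nrow(edges) == 0)
    return(data.frame(t = numeric(0), x = numeric(0), y = numeric(0),
                      id = integer(0)))
  ex <- edges[, 3] - edges[, 1]
  ey <- edges[, 4] - edges[, 2]
  denom <- d[1] * ey - d[2] * ex
  wx <- edges[, 1] - o[1]
  wy <- edges[, 2] - o[2]
  t <- (wx * ey - wy * ex) / denom
  u <- (wx * d[2] - wy * d[1]) / denom
  ok <- is.finite(t) & is.finite(u) & t > 1e-9 & u >= -1e-9 & u <= 1 + 1e-9
  if (!any(ok))
    return(data.frame(t = numeric(0), x = numeric(0), y = numeric(0),
                      id = integer(0)))
  t <- t[ok]
  res <- data.frame(t = t, x = o[1] + t * d[1], y = o[2] + t * d[2],
                    id = as.integer(edges[ok, 5]))
  res[order(res$t, res$id), , drop = FALSE]
}

# polyline of an EdgeSegment (or list of them) as an edge table for
# rayIntersections: columns x1, y1, x2, y2, id
segmentEdgeTable <- function(segments) {
  if (length(segments) == 0)
    return(matrix(numeric(0), ncol = 5))
  do.call(rbind, lapply(segments, function(s) {
    p <- s@points
    if (nrow(p) < 2)
      return(cbind(p[1, 1], p[1, 2], p[1, 1] + 1e-6, p[1, 2], s@id))
    n <- nrow(p)
    cbind(p[-n, 1], p[-n, 2], p[-1, 1], p[-1, 2], s@id)
  }))
}

# Catmull-Rom (cardinal spline, tension 0) evaluation between p1 and p2
# with neighbors p0, p3; t is a vector in [0, 1].
catmullRom <- function(p0, p1, p2, p3, t) {
  t2 <- t * t; t3 <- t2 * t
  h1 <- -0.5 * t3 + t2 - 0.5 * t
  h2 <- 1.5 * t3 - 2.5 * t2 + 1
  h3 <- -1.5 * t3 + 2 * t2 + 0.5 * t
  h4 <- 0.5 * t3 - 0.5 * t2
  cbind(h1 * p0[1] + h2 * p1[1] + h3 * p2[1] + h4 * p3[1],
        h1 * p0[2] + h2 * p1[2] + h3 * p2[2] + h4 * p3[2])
}

# total arc length of an ordered 2D point chain
chainLength <- function(P) {
  if (nrow(P) < 2) return(0)
  sum(sqrt(rowSums(diff(P)^2)))
}

# shortest distance from points (n x 2) to the infinite line through a, b
pointLineDistance <- function(P, a, b) {
  v <- b - a
  nv <- sqrt(sum(v^2))
  abs((P[, 1] - a[1]) * v[2] - (P[, 2] - a[2]) * v[1]) / nv
}

# does a polyline (open chain) self-intersect? O(n^2) segment pair test;
# adjacent segments excluded. Used on assembled boundaries (a few hundred
# points), not on raw edge maps.
chainSelfIntersects <- function(P, closed = TRUE) {
  n <- nrow(P)
  if (n < 4) return(FALSE)
  idx <- if (closed) cbind(seq_len(n), c(2:n, 1)) else cbind(1:(n - 1), 2:n)
  m <- nrow(idx)
  A <- P[idx[, 1], , drop = FALSE]
  B <- P[idx[, 2], , drop = FALSE]
  for (i in seq_len(m - 2)) {
    js <- (i + 2):m
    if (closed && i == 1) js <- js[js != m]
    if (!length(js)) next
    if (anySegIntersect(A[i, ], B[i, ], A[js, , drop = FALSE],
                        B[js, , drop = FALSE])) return(TRUE)
  }
  FALSE
}

anySegIntersect <- function(a1, a2, B1, B2) {
  d <- a2 - a1
  ex <- B2[, 1] - B1[, 1]; ey <- B2[, 2] - B1[, 2]
  den <- d[1] * ey - d[2] * ex
  wx <- B1[, 1] - a1[1]; wy <- B1[, 2] - a1[2]
  t <- (wx * ey - wy * ex) / den
  u <- (wx * d[2] - wy * d[1]) / den
  any(is.finite(t) & is.finite(u) &
        t > 1e-9 & t < 1 - 1e-9 & u > 1e-9 & u < 1 - 1e-9)
}

# resample an ordered chain at roughly unit (pixel) arc-length spacing
resampleChain <- function(P, step = 1) {
  if (nrow(P) < 2) return(P)
  d <- c(0, cumsum(sqrt(rowSums(diff(P)^2))))
  L <- d[length(d)]
  if (L < step) return(P[c(1, nrow(P)), , drop = FALSE])
  s <- seq(0, L, by = step)
  cbind(stats::approx(d, P[, 1], xout = s, ties = "ordered")$y,
        stats::approx(d, P[, 2], xout = s, ties = "ordered")$y)
}
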