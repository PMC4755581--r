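# Shared fixtures and independent oracles. Expensive objects are computed
# once per test run and cached here.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

## fixtures --------------------------------------------------------------------

# a bright horizontal band (rows y in [y1, y2]) with smooth edges
bandImage <- function(nx = 80, ny = 80, y1 = 35, y2 = 46, noise = 0) {
  img <- matrix(0, nx, ny)
  yy <- matrix(rep(seq_len(ny), each = nx), nx, ny)
  img <- pmin(pmax((pmin(yy - y1, y2 - yy) + 1.5) / 3, 0), 1)
  if (noise > 0) img <- img + matrix(rnorm(nx * ny, 0, noise), nx, ny)
  img
}

# filled disk intensity image with a smooth rim
diskImage <- function(nx = 100, ny = 100, cx = 50, cy = 50, r = 30) {
  xx <- matrix(rep(seq_len(nx), ny), nx, ny)
  yy <- matrix(rep(seq_len(ny), each = nx), nx, ny)
  d <- sqrt((xx - cx)^2 + (yy - cy)^2)
  pmin(pmax((r - d + 1.5) / 3, 0), 1)
}

# binary ellipse mask rotated by angleDeg from the Y axis
ellipseMask <- function(nx = 80, ny = 80, a = 25, b = 8, angleDeg = 0,
                        cx = 40, cy = 40) {
  xx <- matrix(rep(seq_len(nx), ny), nx, ny) - cx
  yy <- matrix(rep(seq_len(ny), each = nx), nx, ny) - cy
  th <- angleDeg * pi / 180
  u <- xx * sin(th) + yy * cos(th)     # along the long axis
  v <- xx * cos(th) - yy * sin(th)
  (u / a)^2 + (v / b)^2 <= 1
}

# small one-cell synthetic stack reused across files
oneCellStack <- function() {
  cached("oneCellStack",
         makeCellStack(1, noiseSd = 0.02, seed = 7,
                       gridShape = c(200, 200, 60)))
}

# a NucleusGeometry with given center/vector and endpoints at +/- len
simpleGeometry <- function(center = c(50, 50), vector = c(0, 1), len = 10) {
  v <- vector / sqrt(sum(vector^2))
  ep <- rbind(center + v * len, center - v * len)
  new("NucleusGeometry", center = center,
      skeleton = rbind(ep[1, ], center, ep[2, ]), endpoints = ep,
      cellVector = v, lowAnisotropy = FALSE)
}

# closed circular pixel chain (as one EdgeSegment) around a center; the
# closing step duplicates the first pixel so the polyline has no opening
circleSegment <- function(center = c(50, 50), r = 20, id = 1L,
                          edgeClass = "A") {
  th <- seq(0, 2 * pi, length.out = ceiling(2 * pi * r))[-1]
  P <- unique(round(cbind(center[1] + r * cos(th), center[2] + r * sin(th))))
  P <- chainFromPoints(rbind(P, P[1, ]))
  EdgeSegment(P, edgeClass = edgeClass, id = id)
}

# make an ordered point list 8-connected by linear interpolation
chainFromPoints <- function(P) {
  out <- P[1, , drop = FALSE]
  for (i in 2:nrow(P)) {
    prev <- out[nrow(out), ]
    step <- P[i, ] - prev
    while (max(abs(step)) > 1) {
      prev <- prev + sign(step)
      out <- rbind(out, prev)
      step <- P[i, ] - prev
    }
    if (max(abs(step)) > 0) out <- rbind(out, P[i, ])
  }
  # drop consecutive repeats only: a closing revisit of the first pixel is
  # legitimate and keeps loops watertight
  keep <- c(TRUE, rowSums(abs(diff(out))) > 0)
  out[keep, , drop = FALSE]
}

## independent oracles ---------------------------------------------------------

# nearest intersection per ray by solving the 2x2 linear system per edge
# (independent of the package's cross-product formulation)
oracleFirstHits <- function(rays, segments) {
  out <- vector("list", nrow(rays))
  for (i in seq_len(nrow(rays))) {
    o <- c(rays$originX[i], rays$originY[i])
    d <- c(rays$dirX[i], rays$dirY[i])
    best <- NULL
    for (s in segments) {
      P <- segmentPoints(s)
      if (nrow(P) < 2) next
      for (k in 1:(nrow(P) - 1)) {
        A <- cbind(d, P[k, ] - P[k + 1, ])
        if (abs(det(A)) < 1e-12) next
        sol <- solve(A, P[k, ] - o)
        if (sol[1] > 1e-9 && sol[2] >= -1e-9 && sol[2] <= 1 + 1e-9) {
          if (is.null(best) || sol[1] < best$t - 1e-9 ||
              (abs(sol[1] - best$t) <= 1e-9 && s@id < best$id))
            best <- list(t = sol[1], id = s@id)
        }
      }
    }
    out[[i]] <- best
  }
  out
}

# retained segment ids per exhaustive first-hit computation
oracleRetained <- function(rays, segments) {
  hits <- oracleFirstHits(rays, segments)
  firstBySeg <- new.env()
  ids <- integer(0)
  for (i in seq_along(hits)) {
    h <- hits[[i]]
    if (is.null(h)) next
    ids <- c(ids, h$id)
  }
  sort(unique(ids))
}

# Catmull-Rom evaluated from the polynomial definition (independent basis)
oracleCR <- function(p0, p1, p2, p3, t) {
  b <- function(a0, a1, a2, a3)
    0.5 * ((2 * a1) + (-a0 + a2) * t + (2 * a0 - 5 * a1 + 4 * a2 - a3) * t^2 +
             (-a0 + 3 * a1 - 3 * a2 + a3) * t^3)
  cbind(b(p0[1], p1[1], p2[1], p3[1]), b(p0[2], p1[2], p2[2], p3[2]))
}

# turning-angle curvature, recomputed directly
oracleCurvature <- function(P) {
  n <- nrow(P)
  acc <- 0
  len <- 0
  for (i in 2:n) len <- len + sqrt(sum((P[i, ] - P[i - 1, ])^2))
  for (i in 2:(n - 1)) {
    v1 <- P[i, ] - P[i - 1, ]
    v2 <- P[i + 1, ] - P[i, ]
    if (sum(v1^2) < 1e-20 || sum(v2^2) < 1e-20) next
    a1 <- atan2(v1[2], v1[1]); a2 <- atan2(v2[2], v2[1])
    acc <- acc + abs(atan2(sin(a2 - a1), cos(a2 - a1)))
  }
  c(acc = acc, avg = acc / len)
}

# brute-force junction search for bilateral interpolation (direction 1->2)
oracleJunction <- function(P1, P2, metric = c("acc", "avg")) {
  metric <- match.arg(metric)
  best <- NULL
  for (j in seq_len(nrow(P2))) {
    p1 <- P1[nrow(P1), ]
    p2 <- P2[j, ]
    p0 <- if (nrow(P1) > 1) P1[nrow(P1) - 1, ] else p1 + (p1 - p2) * 0.01
    p3 <- if (j < nrow(P2)) P2[j + 1, ] else p2 + (p2 - p1) * 0.01
    nS <- max(2, ceiling(sqrt(sum((p2 - p1)^2))))
    t <- seq(0, 1, length.out = nS + 1)[-c(1, nS + 1)]
    fill <- if (length(t)) oracleCR(p0, p1, p2, p3, t) else NULL
    linked <- rbind(P1, fill, P2[j:nrow(P2), , drop = FALSE])
    cm <- oracleCurvature(linked)
    val <- if (metric == "acc") cm[["acc"]] else cm[["avg"]]
    if (is.null(best) || val < best$val - 1e-12) best <- list(j = j, val = val)
  }
  best$j
}

# direct Eq-style stability recomputation (double loop)
oracleStability <- function(P, seedList, w) {
  M <- length(seedList)
  O <- matrix(0, nrow(P), M)
  for (j in seq_len(M)) {
    S0 <- seedList[[j]]
    for (i in seq_len(nrow(P))) {
      dmin <- Inf
      for (k in seq_len(nrow(S0)))
        dmin <- min(dmin, sqrt(sum((P[i, ] - S0[k, ])^2)))
      O[i, j] <- 1 - dmin / w
    }
  }
  rowMeans(O)
}

# dominant eigenvector by power iteration
oraclePowerIteration <- function(C, iters = 500) {
  v <- rep(1, ncol(C)) / sqrt(ncol(C))
  for (i in seq_len(iters)) {
    v <- C %*% v
    v <- v / sqrt(sum(v^2))
  }
  as.numeric(v)
}

# second-moment orientation of a binary mask, degrees from the Y axis
oracleMomentAngle <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  ctr <- colMeans(idx)
  cc <- sweep(idx, 2, ctr)
  C <- crossprod(cc) / nrow(cc)
  v <- eigen(C, symmetric = TRUE)$vectors[, 1]
  ang <- atan2(v[1], v[2]) * 180 / pi
  ((ang + 90) %% 180) - 90
}

## cached phantom sweep for the acceptance block -------------------------------

phantomSweep <- function() {
  cached("phantomSweep", {
    tilts <- seq(10, 60, by = 10)
    res <- list()
    for (size in c(70, 40)) {
      axes <- if (size == 70) c(35, 10, 10) else c(20, 6, 6)
      for (tl in tilts) {
        ph <- renderPhantom(PhantomSpec(axes, tiltDeg = tl))
        # reconstruct through the 2D-to-3D path before measuring
        bs <- volumeSliceBoundaries(ph$volume)
        rv <- stackBoundaries(bs, zStep = 1, xyPixel = 1,
                              gridShape = dim(voxels(ph$volume)))
        res[[length(res) + 1]] <- data.frame(
          size = size, tilt = tl,
          alphaCov = as.numeric(tiltAngleOfVolume(rv)),
          alphaNorm = as.numeric(tiltAngleOfVolume(rv, normalized = TRUE)))
      }
    }
    do.call(rbind, res)
  })
}
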