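# Low-level raster helpers shared by preprocessing and reconstruction.

# neighbor access: shifted[x, y] == m[x + dx, y + dy], `fill` outside
shiftMat <- function(m, dx, dy, fill = 0) {
  nx <- nrow(m); ny <- ncol(m)
  out <- matrix(fill, nx, ny)
  xs <- max(1, 1 + dx):min(nx, nx + dx)
  ys <- max(1, 1 + dy):min(ny, ny + dy)
  if (length(xs) && length(ys))
    out[xs - dx, ys - dy] <- m[xs, ys]
  out
}

# true branch points of a thinned mask: pixels whose circular neighborhood
# has >= 3 rises (0 -> 1 transitions); unlike the raw 8-neighbor count this
# does not mark pixels merely adjacent to a T junction
branchPointMask <- function(mask) {
  p <- (mask != 0) * 1
  P2 <- shiftMat(p, 0, -1); P3 <- shiftMat(p, 1, -1)
  P4 <- shiftMat(p, 1, 0);  P5 <- shiftMat(p, 1, 1)
  P6 <- shiftMat(p, 0, 1);  P7 <- shiftMat(p, -1, 1)
  P8 <- shiftMat(p, -1, 0); P9 <- shiftMat(p, -1, -1)
  A <- (P2 == 0 & P3 == 1) + (P3 == 0 & P4 == 1) + (P4 == 0 & P5 == 1) +
    (P5 == 0 & P6 == 1) + (P6 == 0 & P7 == 1) + (P7 == 0 & P8 == 1) +
    (P8 == 0 & P9 == 1) + (P9 == 0 & P2 == 1)
  (mask != 0) & A >= 3
}

# 8-neighbor count of a logical matrix
neighborCount8 <- function(mask) {
  m <- mask * 1
  s <- shiftMat(m, 1, 0) + shiftMat(m, -1, 0) + shiftMat(m, 0, 1) +
    shiftMat(m, 0, -1) + shiftMat(m, 1, 1) + shiftMat(m, 1, -1) +
    shiftMat(m, -1, 1) + shiftMat(m, -1, -1)
  s
}

# Zhang-Suen morphological thinning of a binary matrix; returns a
# single-pixel-wide skeleton. Implemented here because no installed imaging
# package exposes thinning.
thinBinary <- function(mask) {
  m <- mask != 0
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      p <- m * 1
      # neighbors clockwise from north; matrix is [x, y] with y increasing
      # downward, north = y - 1
      P2 <- shiftMat(p, 0, -1); P3 <- shiftMat(p, 1, -1)
      P4 <- shiftMat(p, 1, 0);  P5 <- shiftMat(p, 1, 1)
      P6 <- shiftMat(p, 0, 1);  P7 <- shiftMat(p, -1, 1)
      P8 <- shiftMat(p, -1, 0); P9 <- shiftMat(p, -1, -1)
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      A <- (P2 == 0 & P3 == 1) + (P3 == 0 & P4 == 1) + (P4 == 0 & P5 == 1) +
        (P5 == 0 & P6 == 1) + (P6 == 0 & P7 == 1) + (P7 == 0 & P8 == 1) +
        (P8 == 0 & P9 == 1) + (P9 == 0 & P2 == 1)
      if (phase == 1) {
        cond <- m & B >= 2 & B <= 6 & A == 1 &
          (P2 * P4 * P6 == 0) & (P4 * P6 * P8 == 0)
      } else {
        cond <- m & B >= 2 & B <= 6 & A == 1 &
          (P2 * P4 * P8 == 0) & (P2 * P6 * P8 == 0)
      }
      if (any(cond)) {
        m[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

# Trace the connected components of a thinned, junction-free binary matrix
# into ordered pixel chains. Components that are cycles are opened at an
# arbitrary pixel. Returns a list of n-by-2 coordinate matrices.
traceChains <- function(mask) {
  nx <- nrow(mask); ny <- ncol(mask)
  idx <- which(mask)
  if (!length(idx)) return(list())
  off <- cbind(c(1, -1, 0, 0, 1, 1, -1, -1), c(0, 0, 1, -1, 1, -1, 1, -1))
  nbCount <- neighborCount8(mask)
  remaining <- mask        # pixels not yet assigned to a chain
  chains <- list()
  # start at endpoints first so open chains are traced end-to-end
  starts <- idx[order(nbCount[idx] != 1)]
  for (k0 in starts) {
    if (!remaining[k0]) next
    chain <- integer(256)
    n <- 0L
    cur <- k0
    repeat {
      remaining[cur] <- FALSE
      n <- n + 1L
      if (n > length(chain)) chain <- c(chain, integer(length(chain)))
      chain[n] <- cur
      cx <- (cur - 1L) %% nx + 1L; cy <- (cur - 1L) %/% nx + 1L
      nxt <- NA_integer_
      for (oi in seq_len(8)) {      # 4-neighbors first for smoother chains
        qx <- cx + off[oi, 1]; qy <- cy + off[oi, 2]
        if (qx < 1 || qx > nx || qy < 1 || qy > ny) next
        q <- (qy - 1L) * nx + qx
        if (remaining[q]) { nxt <- q; break }
      }
      if (is.na(nxt)) break
      cur <- nxt
    }
    chain <- chain[seq_len(n)]
    chains[[length(chains) + 1]] <- cbind((chain - 1L) %% nx + 1L,
                                          (chain - 1L) %/% nx + 1L)
  }
  chains
}

## 3D array morphology ---------------------------------------------------------

arrShift <- function(a, dx, dy, dz, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, d)
  xs <- max(1, 1 + dx):min(d[1], d[1] + dx)
  ys <- max(1, 1 + dy):min(d[2], d[2] + dy)
  zs <- max(1, 1 + dz):min(d[3], d[3] + dz)
  out[xs - dx, ys - dy, zs - dz] <- a[xs, ys, zs]
  out
}

# 3D dilation/erosion with a 3x3x3 box structuring element
dilate3d <- function(a, iterations = 1L) {
  for (i in seq_len(iterations)) {
    r <- a
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1)
      if (dx || dy || dz) r <- r | arrShift(a, dx, dy, dz, FALSE)
    a <- r
  }
  a
}

erode3d <- function(a, iterations = 1L) {
  for (i in seq_len(iterations)) {
    r <- a
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1)
      if (dx || dy || dz) r <- r & arrShift(a, dx, dy, dz, FALSE)
    a <- r
  }
  a
}

closing3d <- function(a) erode3d(dilate3d(a))
opening3d <- function(a) dilate3d(erode3d(a))

# separable Gaussian smoothing of a 3D numeric array (zero padded)
smooth3d <- function(a, sigma) {
  if (sigma <= 0) return(a)
  r <- max(1L, ceiling(3 * sigma))
  w <- stats::dnorm(-r:r, sd = sigma)
  w <- w / sum(w)
  for (axis in 1:3) {
    out <- array(0, dim(a))
    for (i in -r:r) {
      sh <- c(0, 0, 0); sh[axis] <- i
      out <- out + w[i + r + 1] * arrShift(a, sh[1], sh[2], sh[3], 0)
    }
    a <- out
  }
  a
}

# foreground voxels with at least one 6-neighbor outside the object
surfaceVoxelMask <- function(fg) {
  inner <- fg &
    arrShift(fg, 1, 0, 0) & arrShift(fg, -1, 0, 0) &
    arrShift(fg, 0, 1, 0) & arrShift(fg, 0, -1, 0) &
    arrShift(fg, 0, 0, 1) & arrShift(fg, 0, 0, -1)
  fg & !inner
}

# coordinates (n x 3, voxel units) of surface voxels of a BinaryVolume
surfaceVoxelCoords <- function(fg) {
  idx <- which(surfaceVoxelMask(fg))
  d <- dim(fg)
  cbind((idx - 1) %% d[1] + 1,
        ((idx - 1) %/% d[1]) %% d[2] + 1,
        (idx - 1) %/% (d[1] * d[2]) + 1)
}

# keep the 3D connected component (box connectivity) containing `seed`
# (length-3 voxel index); grown by frontier dilation
seededComponent3d <- function(fg, seed) {
  comp <- array(FALSE, dim(fg))
  sx <- round(seed)
  sx <- pmin(pmax(sx, 1), dim(fg))
  if (!fg[sx[1], sx[2], sx[3]]) {
    # snap to the nearest foreground voxel within a small window
    found <- FALSE
    for (r in 1:5) {
      xs <- max(1, sx[1] - r):min(dim(fg)[1], sx[1] + r)
      ys <- max(1, sx[2] - r):min(dim(fg)[2], sx[2] + r)
      zs <- max(1, sx[3] - r):min(dim(fg)[3], sx[3] + r)
      sub <- fg[xs, ys, zs, drop = FALSE]
      if (any(sub)) {
        w <- which(sub, arr.ind = TRUE)[1, ]
        sx <- c(xs[w[1]], ys[w[2]], zs[w[3]])
        found <- TRUE
        break
      }
    }
    if (!found) return(comp)
  }
  comp[sx[1], sx[2], sx[3]] <- TRUE
  repeat {
    grown <- dilate3d(comp) & fg
    if (sum(grown) == sum(comp)) break
    comp <- grown
  }
  comp
}
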