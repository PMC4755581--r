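# Synthetic two-channel stacks of fusiform cells. The generator's defaults
# are the VSMC population conditions: length 62.9 +/- 14.9 um, width
# 4.6 +/- 0.6 um, thickness 6.2 +/- 1.8 um, a bimodal in-plane orientation
# (-19.4 +/- 9.3 and 10.9 +/- 4.7 degrees) and a half-normal out-of-plane
# tilt with SD 7.6 degrees; voxels 0.412 x 0.412 x 0.25 um.

#' Default VSMC geometry ranges
#'
#' @return List of population parameters used by
#'   \code{\link{makeCellStack}}: normal (mean, sd) for L, W, T in um, the
#'   two in-plane orientation modes, and the half-normal tilt SD.
#' @export
vsmcGeometryRanges <- function() {
  list(L = c(62.9, 14.9), W = c(4.6, 0.6), T = c(6.2, 1.8),
       betaModes = list(c(-19.4, 9.3), c(10.9, 4.7)),
       betaWeights = c(0.5, 0.5), alphaSd = 7.6,
       nucleus = c(L = 15, W = 3, T = 3))
}

#' Sample in-plane angles from the bimodal orientation mixture
#'
#' @param n number of angles.
#' @param modes list of two (mean, sd) pairs in degrees.
#' @param weights mixing proportions.
#' @param seed integer seed.
#' @return Numeric vector of angles in degrees, folded into [-90, 90).
#' @export
sampleInPlaneAngles <- function(n, modes = vsmcGeometryRanges()$betaModes,
                                weights = c(0.5, 0.5), seed = 1L) {
  set.seed(seed)
  comp <- sample.int(2L, n, replace = TRUE, prob = weights)
  mu <- vapply(modes, `[`, numeric(1), 1)[comp]
  sd <- vapply(modes, `[`, numeric(1), 2)[comp]
  fold90(stats::rnorm(n, mu, sd))
}

# smoothstep on a signed distance (um): 0 outside, 1 inside, gradient
# maximum exactly on the boundary
.edgeProfile <- function(signedDist, band) {
  t <- pmin(pmax(signedDist / band + 0.5, 0), 1)
  t * t * (3 - 2 * t)
}

# render one spindle (or nucleus ellipsoid) into a channel array, in place
# semantics via returned sub-array. Returns list(channel, mask evaluated?)
.renderSpindle <- function(channel, center, u1, u2, u3, L, W, Tt, spacing,
                           band = 1, taper = 0.6) {
  d <- dim(channel)
  # bounding box in voxels
  halfSpan <- abs(u1) * L / 2 + (abs(u2) + abs(u3)) * max(W, Tt) / 2 + band * 2
  lo <- pmax(1L, floor((center - halfSpan) / spacing))
  hi <- pmin(d, ceiling((center + halfSpan) / spacing))
  if (any(lo > hi)) return(channel)
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  px <- xs * spacing[1]; py <- ys * spacing[2]; pz <- zs * spacing[3]
  nxl <- length(xs); nyl <- length(ys); nzl <- length(zs)
  gx <- rep(px, times = nyl * nzl)
  gy <- rep(rep(py, each = nxl), times = nzl)
  gz <- rep(pz, each = nxl * nyl)
  rx <- gx - center[1]; ry <- gy - center[2]; rz <- gz - center[3]
  s1 <- rx * u1[1] + ry * u1[2] + rz * u1[3]
  s2 <- rx * u2[1] + ry * u2[2] + rz * u2[3]
  s3 <- rx * u3[1] + ry * u3[2] + rz * u3[3]
  sd <- .spindleSignedDist(s1, s2, s3, L, W, Tt, taper)
  I <- .edgeProfile(sd, band)
  sub <- array(I, c(nxl, nyl, nzl))
  channel[xs, ys, zs] <- pmax(channel[xs, ys, zs], sub)
  channel
}

# approximate signed distance (um, positive inside) to a fusiform body of
# length L, width W, thickness Tt whose cross-section radii taper as
# (1 - u^2)^taper along the axis
.spindleSignedDist <- function(s1, s2, s3, L, W, Tt, taper) {
  u <- pmin(abs(2 * s1 / L), 1)
  f <- (1 - u^2)^taper
  r2 <- pmax(W / 2 * f, 1e-6)
  r3 <- pmax(Tt / 2 * f, 1e-6)
  rho <- sqrt((s2 / r2)^2 + (s3 / r3)^2)
  axial <- L / 2 - abs(s1)                 # distance to the end caps
  radial <- (1 - rho) * pmin(r2, r3)
  pmin(radial, axial)
}

#' Generate a synthetic two-channel fusiform-cell stack
#'
#' Cells are solid spindle-shaped intensity profiles with a smooth boundary
#' falloff and a mild depth-dependent intensity drop; nuclei are interior
#' ellipsoids rendered into the second channel. Ground truth carries each
#' cell's exact geometry and per-slice contours. Deterministic for a fixed
#' seed.
#'
#' @param nCells number of cells to place.
#' @param geometryRanges population parameters, see
#'   \code{\link{vsmcGeometryRanges}}.
#' @param noiseSd additive Gaussian read-noise SD (intensity units,
#'   default 0.03).
#' @param overlapFraction fraction of cells placed as crossing pairs with a
#'   neighbor (default 0).
#' @param seed integer RNG seed.
#' @param gridShape stack dimensions in voxels (default 256 x 256 x 64).
#' @param spacing voxel size in um (default 0.412 x 0.412 x 0.25).
#' @param depthFalloff fractional intensity drop from first to last slice
#'   (default 0.15).
#' @param maxTries placement attempts per cell before reporting infeasible
#'   packing.
#' @return A \linkS4class{SyntheticStack}.
#' @export
makeCellStack <- function(nCells, geometryRanges = vsmcGeometryRanges(),
                          noiseSd = 0.03, overlapFraction = 0, seed = 1L,
                          gridShape = c(256L, 256L, 64L),
                          spacing = c(0.412, 0.412, 0.25),
                          depthFalloff = 0.15, maxTries = 200L) {
  gr <- utils::modifyList(vsmcGeometryRanges(), geometryRanges)
  set.seed(seed)
  d <- as.integer(gridShape)
  ext <- d * spacing                       # physical extent, um
  cellCh <- array(0, d)
  nucCh <- array(0, d)
  truth <- vector("list", nCells)
  rtrunc <- function(ms, lo) max(lo, stats::rnorm(1, ms[1], ms[2]))
  i <- 1L
  while (i <= nCells) {
    pair <- overlapFraction > 0 && i > 1L &&
      stats::runif(1) < overlapFraction
    placed <- FALSE
    for (try in seq_len(maxTries)) {
      # geometry redrawn per attempt so an oversized draw cannot jam the
      # placement; the accepted draws still follow the population truncated
      # to what the grid can hold
      L <- rtrunc(gr$L, 20)
      W <- rtrunc(gr$W, 2)
      Tt <- rtrunc(gr$T, 2.5)
      if (pair) {
        prevT <- truth[[i - 1L]]
        # crossing orientation: draw beta from the other mode
        betaMode <- if (prevT$betaMode == 1L) 2L else 1L
      } else {
        betaMode <- sample.int(2L, 1, prob = gr$betaWeights)
      }
      m <- gr$betaModes[[betaMode]]
      beta <- fold90(stats::rnorm(1, m[1], m[2]))
      alpha <- abs(stats::rnorm(1, 0, gr$alphaSd))
      zspan <- L * sin(deg2rad(alpha)) + Tt
      if (zspan > ext[3] - 2 * spacing[3]) next
      u1 <- c(sin(deg2rad(beta)) * cos(deg2rad(alpha)),
              cos(deg2rad(beta)) * cos(deg2rad(alpha)),
              sin(deg2rad(alpha)))
      u2 <- c(cos(deg2rad(beta)), -sin(deg2rad(beta)), 0)
      u3 <- c(u1[2] * u2[3] - u1[3] * u2[2],
              u1[3] * u2[1] - u1[1] * u2[3],
              u1[1] * u2[2] - u1[2] * u2[1])
      half <- abs(u1) * L / 2 + (abs(u2) + abs(u3)) * max(W, Tt) / 2 + 1
      if (any(2 * half + 2 > ext)) next
      if (pair) {
        # crossing pair: close enough that the 63-um bodies overlap, far
        # enough apart that the ~15-um nuclei stay disjoint
        prevC <- truth[[i - 1L]]$center
        offDir <- c(stats::rnorm(2), 0)
        offDir <- offDir / max(sqrt(sum(offDir^2)), 1e-9)
        center <- prevC + offDir * stats::runif(1, 8, 20) +
          c(0, 0, stats::runif(1, -4, 4))
        # nuclei (as axis segments) must not collide
        prevU <- truth[[i - 1L]]$u1
        tpts <- seq(-6, 6, by = 1)
        A <- t(vapply(tpts, function(s) prevC + s * prevU, numeric(3)))
        B <- t(vapply(tpts, function(s) center + s * u1, numeric(3)))
        dmin <- min(vapply(seq_len(nrow(A)), function(i2)
          min(sqrt(colSums((t(B) - A[i2, ])^2))), numeric(1)))
        if (dmin < 4) next
      } else {
        center <- c(stats::runif(1, half[1] + 1, ext[1] - half[1] - 1),
                    stats::runif(1, half[2] + 1, ext[2] - half[2] - 1),
                    stats::runif(1, half[3] + 1, ext[3] - half[3] - 1))
      }
      if (any(center - half < 0) || any(center + half > ext)) next
      placed <- TRUE
      break
    }
    if (!placed)
      stop("infeasible packing: could not place cell ", i,
           " in the grid after ", maxTries, " tries")
    cellCh <- .renderSpindle(cellCh, center, u1, u2, u3, L, W, Tt, spacing,
                             band = 1, taper = 0.6)
    nuc <- gr$nucleus
    nL <- min(nuc[["L"]], 0.8 * L)
    nW <- min(nuc[["W"]], 0.85 * W)
    nT <- min(nuc[["T"]], 0.85 * Tt)
    nucCh <- .renderSpindle(nucCh, center, u1, u2, u3, nL, nW, nT, spacing,
                            band = 0.8, taper = 0.5)
    truth[[i]] <- list(id = i, center = center, L = L, W = W, T = Tt,
                       beta = beta, alpha = alpha, betaMode = betaMode,
                       u1 = u1, nucleus = c(nL, nW, nT),
                       contours = NULL)
    i <- i + 1L
  }
  # per-slice truth contours (noise-free boundary at signed distance 0)
  for (k in seq_len(nCells)) {
    tr <- truth[[k]]
    truth[[k]]$contours <- .truthContours(tr, d, spacing)
  }
  # the nucleus displaces F-actin: a dimmer region inside the cell channel
  # (this is what creates the "inner edges" around the nucleus)
  cellCh <- cellCh * (1 - 0.35 * pmin(nucCh, 1))
  # depth-dependent intensity falloff plus read noise
  fall <- 1 - depthFalloff * (seq_len(d[3]) - 1) / max(d[3] - 1, 1)
  for (z in seq_len(d[3])) {
    cellCh[, , z] <- cellCh[, , z] * fall[z]
    nucCh[, , z] <- nucCh[, , z] * fall[z]
  }
  if (noiseSd > 0) {
    cellCh <- pmax(cellCh + stats::rnorm(length(cellCh), 0, noiseSd), 0)
    nucCh <- pmax(nucCh + stats::rnorm(length(nucCh), 0, noiseSd), 0)
  }
  new("SyntheticStack", cellChannel = cellCh, nucleusChannel = nucCh,
      truth = truth, spacing = as.numeric(spacing), seed = as.integer(seed))
}

# analytic truth contours per slice, in voxel coordinates
.truthContours <- function(tr, d, spacing) {
  u1 <- tr$u1
  beta <- tr$beta
  u2 <- c(cos(deg2rad(beta)), -sin(deg2rad(beta)), 0)
  u3 <- c(u1[2] * u2[3] - u1[3] * u2[2],
          u1[3] * u2[1] - u1[1] * u2[3],
          u1[1] * u2[2] - u1[2] * u2[1])
  halfSpan <- abs(u1) * tr$L / 2 +
    (abs(u2) + abs(u3)) * max(tr$W, tr$T) / 2 + 2
  lo <- pmax(1L, floor((tr$center - halfSpan) / spacing))
  hi <- pmin(d, ceiling((tr$center + halfSpan) / spacing))
  out <- list()
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]
  px <- xs * spacing[1]; py <- ys * spacing[2]
  for (z in lo[3]:hi[3]) {
    pz <- z * spacing[3]
    rx <- outer(px - tr$center[1], rep(1, length(py)))
    ry <- outer(rep(1, length(px)), py - tr$center[2])
    rz <- pz - tr$center[3]
    s1 <- rx * u1[1] + ry * u1[2] + rz * u1[3]
    s2 <- rx * u2[1] + ry * u2[2] + rz * u2[3]
    s3 <- rx * u3[1] + ry * u3[2] + rz * u3[3]
    sd <- .spindleSignedDist(s1, s2, s3, tr$L, tr$W, tr$T, 0.6)
    if (max(sd) <= 0) next
    cl <- grDevices::contourLines(px, py, sd, levels = 0)
    if (!length(cl)) next
    best <- which.max(vapply(cl, function(c0) length(c0$x), 1L))
    out[[as.character(z)]] <- cbind(cl[[best]]$x / spacing[1],
                                    cl[[best]]$y / spacing[2])
  }
  out
}
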