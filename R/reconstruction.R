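# 2D-to-3D reconstruction: rasterize and stack per-slice boundaries into a
# solid binary volume, extract an iso-surface mesh, and smooth it.

#' Stack per-slice boundaries into a binary volume
#'
#' Each closed contour is rasterized and filled on its slice; 3D
#' morphological closing then bridges small inter-slice holes and isolated
#' voxels are removed.
#'
#' @param boundaries list of \linkS4class{Boundary2D} objects (slice slots
#'   must be set).
#' @param zStep z spacing in micrometres.
#' @param xyPixel in-plane pixel size in micrometres.
#' @param gridShape integer length-3 output dimensions; default tight
#'   bounds with a 2-voxel margin.
#' @param close apply the 3x3x3 morphological closing (default TRUE).
#' @return A \linkS4class{BinaryVolume}.
#' @export
stackBoundaries <- function(boundaries, zStep = 0.25, xyPixel = 0.412,
                            gridShape = NULL, close = TRUE) {
  boundaries <- boundaries[!vapply(boundaries, is.null, TRUE)]
  if (!length(boundaries)) stop("need at least one boundary")
  for (b in boundaries)
    if (chainSelfIntersects(b@contour))
      stop("non-simple contour on slice ", b@slice,
           "; repair upstream before stacking")
  slices <- vapply(boundaries, function(b) b@slice, 1L)
  if (anyNA(slices)) stop("boundaries must carry slice indices")
  if (is.null(gridShape)) {
    allPts <- do.call(rbind, lapply(boundaries, boundaryContour))
    gridShape <- c(ceiling(max(allPts[, 1])) + 2L,
                   ceiling(max(allPts[, 2])) + 2L,
                   max(slices) + 1L)
  }
  gridShape <- as.integer(gridShape)
  vox <- array(FALSE, gridShape)
  for (b in boundaries) {
    z <- b@slice
    if (z < 1 || z > gridShape[3]) next
    vox[, , z] <- vox[, , z] | fillPolygonMask(b@contour, gridShape[1],
                                               gridShape[2])
  }
  if (close && length(boundaries) > 1) {
    # in-plane closing repairs small contour defects; a z-only gap fill
    # bridges single missing slices. (A full 3x3x3 closing would stretch
    # the voxel columns of thin, tilted cells and bias the thickness.)
    brush <- EBImage::makeBrush(3, "box")
    for (z in seq_len(gridShape[3])) {
      if (!any(vox[, , z])) next
      vox[, , z] <- EBImage::closing(vox[, , z] * 1, brush) > 0
    }
    vox <- vox | (arrShift(vox, 0, 0, 1) & arrShift(vox, 0, 0, -1))
  }
  # remove isolated voxels (no 6-neighbor support)
  nb <- arrShift(vox, 1, 0, 0) | arrShift(vox, -1, 0, 0) |
    arrShift(vox, 0, 1, 0) | arrShift(vox, 0, -1, 0) |
    arrShift(vox, 0, 0, 1) | arrShift(vox, 0, 0, -1)
  vox <- vox & (nb | sum(vox) == 1)
  BinaryVolume(vox, c(xyPixel, xyPixel, zStep))
}

# marching-tetrahedra case table: edge indices per triangle, edges being
# 1:(v1,v2) 2:(v1,v3) 3:(v1,v4) 4:(v2,v3) 5:(v2,v4) 6:(v3,v4)
.mtCases <- list(
  `1` = list(c(1, 2, 3)), `2` = list(c(1, 4, 5)), `4` = list(c(2, 4, 6)),
  `8` = list(c(3, 5, 6)),
  `3` = list(c(2, 4, 5), c(2, 5, 3)), `5` = list(c(1, 4, 6), c(1, 6, 3)),
  `9` = list(c(1, 2, 6), c(1, 6, 5)), `6` = list(c(1, 2, 6), c(1, 6, 5)),
  `10` = list(c(1, 4, 6), c(1, 6, 3)), `12` = list(c(2, 4, 5), c(2, 5, 3)),
  `14` = list(c(1, 2, 3)), `13` = list(c(1, 4, 5)), `11` = list(c(2, 4, 6)),
  `7` = list(c(3, 5, 6)))
.mtEdgeEnds <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
# 6-tetrahedra cube decomposition around the main diagonal (corners
# numbered 1..8: (0,0,0),(1,0,0),(1,1,0),(0,1,0),(0,0,1),(1,0,1),
# (1,1,1),(0,1,1)); face diagonals agree between neighboring cubes
.mtTets <- rbind(c(1, 6, 2, 7), c(1, 2, 3, 7), c(1, 3, 4, 7),
                 c(1, 4, 8, 7), c(1, 8, 5, 7), c(1, 5, 6, 7))
.cubeOffsets <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
                      c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))

#' Extract a closed surface mesh from a binary volume
#'
#' The foreground is optionally smoothed with a small Gaussian (sub-voxel
#' surface placement) and contoured at the 0.5 iso-level by marching
#' tetrahedra; coordinates are returned in physical units via the volume
#' spacing. The volume is zero-padded so the surface always closes.
#'
#' @param volume a nonempty \linkS4class{BinaryVolume}.
#' @param smoothSigma Gaussian sigma in voxels applied to the indicator
#'   field before contouring (default 1); automatically disabled when
#'   smoothing would erase the object (tiny volumes).
#' @return A \linkS4class{TriangleMesh} with outward-oriented faces.
#' @export
extractSurface <- function(volume, smoothSigma = 1) {
  stopifnot(is(volume, "BinaryVolume"))
  fg <- volume@voxels
  if (!any(fg)) stop("empty volume")
  F <- array(0, dim(fg) + 2L)
  F[2:(dim(fg)[1] + 1), 2:(dim(fg)[2] + 1), 2:(dim(fg)[3] + 1)] <- fg * 1
  if (smoothSigma > 0) {
    Fs <- smooth3d(F, smoothSigma)
    if (max(Fs) > 0.55) F <- Fs            # else keep the binary field
  }
  mesh <- marchingTetrahedra(F, iso = 0.5)
  # undo padding and scale to physical units
  v <- sweep(mesh@vertices, 2, c(1, 1, 1))
  v <- sweep(v, 2, volume@spacing, "*")
  TriangleMesh(v, mesh@faces)
}

# marching tetrahedra on a numeric field; returns a mesh in grid
# coordinates (grid point (i,j,k) at coordinate (i,j,k))
marchingTetrahedra <- function(F, iso = 0.5) {
  d <- dim(F)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  cx <- 1:(nx - 1); cy <- 1:(ny - 1); cz <- 1:(nz - 1)
  corner <- function(o) F[cx + o[1], cy + o[2], cz + o[3], drop = FALSE]
  vals <- lapply(seq_len(8), function(i) corner(.cubeOffsets[i, ]))
  cmin <- Reduce(pmin, vals)
  cmax <- Reduce(pmax, vals)
  active <- which(cmin < iso & cmax >= iso)
  if (!length(active))
    return(TriangleMesh(matrix(0, 0, 3), matrix(0L, 0, 3)))
  dims <- c(nx - 1, ny - 1, nz - 1)
  ai <- (active - 1) %% dims[1] + 1
  aj <- ((active - 1) %/% dims[1]) %% dims[2] + 1
  ak <- (active - 1) %/% (dims[1] * dims[2]) + 1
  cornerId <- function(o)   # global grid point linear id per active cube
    (ai + o[1]) + (aj + o[2] - 1) * nx + (ak + o[3] - 1) * nx * ny
  gids <- vapply(seq_len(8), function(i) cornerId(.cubeOffsets[i, ]),
                 numeric(length(active)))
  gvals <- vapply(seq_len(8), function(i) vals[[i]][active],
                  numeric(length(active)))
  gids <- matrix(gids, ncol = 8)
  gvals <- matrix(gvals, ncol = 8)
  triA <- list(); triB <- list(); flipQ <- list()
  n <- 0L
  for (t in seq_len(6)) {
    tid <- gids[, .mtTets[t, ], drop = FALSE]
    tval <- gvals[, .mtTets[t, ], drop = FALSE]
    inside <- tval >= iso
    code <- inside[, 1] + 2 * inside[, 2] + 4 * inside[, 3] + 8 * inside[, 4]
    for (cs in names(.mtCases)) {
      rows <- which(code == as.integer(cs))
      if (!length(rows)) next
      # inside centroid (mean of inside-corner grid coordinates)
      insMask <- matrix(inside[rows, ], ncol = 4)
      for (tri in .mtCases[[cs]]) {
        # each triangle vertex sits on a tet edge: record both endpoint ids
        # and values for interpolation
        ea <- .mtEdgeEnds[tri, 1]
        eb <- .mtEdgeEnds[tri, 2]
        n <- n + 1L
        triA[[n]] <- cbind(tid[rows, ea[1]], tid[rows, eb[1]],
                           tid[rows, ea[2]], tid[rows, eb[2]],
                           tid[rows, ea[3]], tid[rows, eb[3]])
        triB[[n]] <- cbind(tval[rows, ea[1]], tval[rows, eb[1]],
                           tval[rows, ea[2]], tval[rows, eb[2]],
                           tval[rows, ea[3]], tval[rows, eb[3]])
        # inside reference point for orientation: first inside corner
        firstIn <- apply(insMask, 1, function(z) which(z)[1])
        flipQ[[n]] <- tid[cbind(rows, firstIn)]
      }
    }
  }
  A <- do.call(rbind, triA)     # id pairs per triangle vertex
  V <- do.call(rbind, triB)     # values per pair
  Q <- unlist(flipQ)            # inside reference grid id per triangle
  gcoord <- function(id) cbind((id - 1) %% nx + 1,
                               ((id - 1) %/% nx) %% ny + 1,
                               (id - 1) %/% (nx * ny) + 1)
  vertOn <- function(idA, idB, fA, fB) {
    t <- (iso - fA) / (fB - fA)
    gcoord(idA) + t * (gcoord(idB) - gcoord(idA))
  }
  P1 <- vertOn(A[, 1], A[, 2], V[, 1], V[, 2])
  P2 <- vertOn(A[, 3], A[, 4], V[, 3], V[, 4])
  P3 <- vertOn(A[, 5], A[, 6], V[, 5], V[, 6])
  # orient: normal away from the inside reference point
  nrml <- cbind((P2[, 2] - P1[, 2]) * (P3[, 3] - P1[, 3]) -
                  (P2[, 3] - P1[, 3]) * (P3[, 2] - P1[, 2]),
                (P2[, 3] - P1[, 3]) * (P3[, 1] - P1[, 1]) -
                  (P2[, 1] - P1[, 1]) * (P3[, 3] - P1[, 3]),
                (P2[, 1] - P1[, 1]) * (P3[, 2] - P1[, 2]) -
                  (P2[, 2] - P1[, 2]) * (P3[, 1] - P1[, 1]))
  qc <- gcoord(Q)
  cen <- (P1 + P2 + P3) / 3
  flip <- rowSums(nrml * (qc - cen)) > 0
  tmp <- P2[flip, , drop = FALSE]
  P2[flip, ] <- P3[flip, , drop = FALSE]
  P3[flip, ] <- tmp
  # dedupe vertices by their defining grid-edge key
  keyOf <- function(a, b) paste(pmin(a, b), pmax(a, b))
  k1 <- keyOf(A[, 1], A[, 2]); k2 <- keyOf(A[, 3], A[, 4])
  k3 <- keyOf(A[, 5], A[, 6])
  kk <- c(k1, k2, k3)
  uk <- unique(kk)
  idx <- match(kk, uk)
  nTri <- nrow(A)
  verts <- matrix(0, length(uk), 3)
  allP <- rbind(P1, P2, P3)
  # swap applied to P2/P3 kept the edge association intact per column
  k2s <- k2; k3s <- k3
  k2s[flip] <- k3[flip]; k3s[flip] <- k2[flip]
  kk <- c(k1, k2s, k3s)
  idx <- match(kk, uk)
  verts[idx, ] <- allP
  faces <- cbind(idx[seq_len(nTri)], idx[nTri + seq_len(nTri)],
                 idx[2 * nTri + seq_len(nTri)])
  ok <- faces[, 1] != faces[, 2] & faces[, 2] != faces[, 3] &
    faces[, 1] != faces[, 3]
  TriangleMesh(verts, faces[ok, , drop = FALSE])
}

#' Smooth a binary volume across slices
#'
#' Three-slice majority vote along z: a voxel survives when at least two of
#' (z-1, z, z+1) are foreground in its column. This removes the
#' single-slice lateral jitter left by stacking independently segmented 2D
#' boundaries (the voxel-space analogue of smoothing the reconstructed
#' surface before measuring it) without eroding thin in-plane structures
#' such as the tapered cell tails.
#'
#' @param volume a \linkS4class{BinaryVolume}.
#' @return The filtered \linkS4class{BinaryVolume}; if filtering would
#'   erase the object (single-slice input) the input is returned unchanged.
#' @export
smoothVolume <- function(volume) {
  stopifnot(is(volume, "BinaryVolume"))
  v <- volume@voxels
  up <- arrShift(v, 0, 0, 1)
  dn <- arrShift(v, 0, 0, -1)
  out <- (v & (up | dn)) | (up & dn)
  if (!any(out)) return(volume)
  BinaryVolume(out, volume@spacing)
}

#' Laplacian mesh smoothing
#'
#' Relaxes each vertex toward the centroid of its neighbors. A vertex mask
#' restricts the relaxation to a subset ("selected face" smoothing).
#'
#' @param mesh a \linkS4class{TriangleMesh}.
#' @param iterations smoothing passes (0 = identity).
#' @param strength step toward the neighbor centroid in [0, 1]
#'   (default 0.3; modest shrinkage).
#' @param mask optional logical per-vertex mask; only masked vertices move.
#' @return The smoothed \linkS4class{TriangleMesh} (vertex count and face
#'   topology unchanged).
#' @export
laplacianSmooth <- function(mesh, iterations = 5L, strength = 0.3,
                            mask = NULL) {
  stopifnot(is(mesh, "TriangleMesh"))
  if (iterations == 0L || nrow(mesh@faces) == 0) return(mesh)
  f <- mesh@faces
  e <- unique(rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)],
                    f[, 2:1], f[, 3:2], f[, c(1, 3)]))
  A <- Matrix::sparseMatrix(i = e[, 1], j = e[, 2], x = 1,
                            dims = rep(nrow(mesh@vertices), 2))
  deg <- Matrix::rowSums(A)
  deg[deg == 0] <- 1
  V <- mesh@vertices
  move <- if (is.null(mask)) rep(TRUE, nrow(V)) else mask
  for (i in seq_len(iterations)) {
    nbMean <- as.matrix(A %*% V) / deg
    V[move, ] <- V[move, ] + strength * (nbMean[move, ] - V[move, ])
  }
  TriangleMesh(V, mesh@faces)
}

#' Total surface area of a mesh
#'
#' @param mesh a \linkS4class{TriangleMesh}.
#' @return Area in squared coordinate units.
#' @export
meshArea <- function(mesh) {
  v <- mesh@vertices; f <- mesh@faces
  if (!nrow(f)) return(0)
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}

#' Enclosed volume of a closed oriented mesh
#'
#' @param mesh a watertight \linkS4class{TriangleMesh} with consistent
#'   outward orientation.
#' @return Volume in cubed coordinate units.
#' @export
meshVolume <- function(mesh) {
  v <- mesh@vertices; f <- mesh@faces
  if (!nrow(f)) return(0)
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c3 <- v[f[, 3], , drop = FALSE]
  abs(sum(a[, 1] * (b[, 2] * c3[, 3] - b[, 3] * c3[, 2]) -
            a[, 2] * (b[, 1] * c3[, 3] - b[, 3] * c3[, 1]) +
            a[, 3] * (b[, 1] * c3[, 2] - b[, 2] * c3[, 1]))) / 6
}
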