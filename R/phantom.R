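# Virtual ellipsoid phantom: the validation object for the tilt-angle
# estimator. The ellipsoid long axis starts along +Y (the circumferential
# axis, where the in-plane angle is zero), is tilted out of the XY plane
# about X, then rotated within the plane about Z.

#' Generate an ellipsoid surface mesh
#'
#' Builds a watertight UV-sphere triangulation scaled to the requested
#' semi-axes (long axis along +Y before rotation) and rotated by the
#' phantom's out-of-plane tilt and in-plane angle. The mesh is centered at
#' the origin.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param nTheta azimuthal samples (default 64).
#' @param nPhi polar rings (default 32).
#' @return A \linkS4class{TriangleMesh}. The composed rotation applied to
#'   the +Y axis gives the mesh long-axis direction.
#' @examples
#' m <- makeEllipsoidMesh(PhantomSpec(c(35, 10, 10), tiltDeg = 30))
#' @export
makeEllipsoidMesh <- function(spec, nTheta = 64L, nPhi = 32L) {
  stopifnot(is(spec, "PhantomSpec"))
  a <- spec@semiAxes
  if (any(a <= 0)) stop("degenerate semi-axes")
  theta <- seq(0, 2 * pi, length.out = nTheta + 1L)[-(nTheta + 1L)]
  phi <- seq(0, pi, length.out = nPhi + 1L)   # 0 and pi are the poles
  ringPhi <- phi[2:nPhi]
  nRing <- length(ringPhi)
  # long axis along Y: y = a cos(phi); cross-section axes b (x) and c (z)
  v <- matrix(0, nRing * nTheta + 2L, 3L)
  v[1L, ] <- c(0, a[1], 0)                      # +Y pole
  for (i in seq_len(nRing)) {
    p <- ringPhi[i]
    rows <- 1L + (i - 1L) * nTheta + seq_len(nTheta)
    v[rows, 1] <- a[2] * sin(p) * cos(theta)
    v[rows, 2] <- a[1] * cos(p)
    v[rows, 3] <- a[3] * sin(p) * sin(theta)
  }
  v[nrow(v), ] <- c(0, -a[1], 0)                # -Y pole
  faces <- matrix(0L, 0L, 3L)
  topRing <- 1L + seq_len(nTheta)
  nxt <- c(seq_len(nTheta)[-1], 1L)
  faces <- rbind(faces, cbind(1L, topRing[nxt], topRing))
  for (i in seq_len(nRing - 1L)) {
    r1 <- 1L + (i - 1L) * nTheta + seq_len(nTheta)
    r2 <- r1 + nTheta
    faces <- rbind(faces,
                   cbind(r1, r1[nxt], r2),
                   cbind(r1[nxt], r2[nxt], r2))
  }
  bot <- 1L + (nRing - 1L) * nTheta + seq_len(nTheta)
  faces <- rbind(faces, cbind(nrow(v), bot, bot[nxt]))
  R <- rotZ(spec@inPlaneDeg) %*% rotX(spec@tiltDeg)
  TriangleMesh(v %*% t(R), faces)
}

# every edge of a watertight closed mesh is shared by exactly two faces
isWatertight <- function(mesh) {
  f <- mesh@faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

#' Deform an ellipsoid mesh by an end rotation
#'
#' One end of the ellipsoid is rotated by the deformation angle about the X
#' axis through the free-end pole while the other end stays fixed; interior
#' vertices follow a harmonic (graph-Laplacian) interpolation of the
#' displacement field with the two end caps as boundary conditions. This
#' bends the phantom like an irregularly shaped nucleus.
#'
#' @param mesh a watertight \linkS4class{TriangleMesh}.
#' @param deformationDeg end-rotation angle in degrees, [0, 90).
#' @param endFraction fraction of the half-extent beyond which vertices
#'   belong to an end cap (default 0.75).
#' @return The deformed \linkS4class{TriangleMesh}.
#' @export
deformEllipsoid <- function(mesh, deformationDeg, endFraction = 0.75) {
  stopifnot(is(mesh, "TriangleMesh"))
  if (deformationDeg < 0 || deformationDeg >= 90)
    stop("deformationDeg must be in [0, 90)")
  if (!isWatertight(mesh)) stop("mesh must be watertight")
  if (deformationDeg == 0) return(mesh)
  v <- mesh@vertices
  ctr <- colMeans(v)
  vc <- sweep(v, 2, ctr)
  ax <- eigen(stats::cov(vc), symmetric = TRUE)$vectors[, 1]
  if (ax[which.max(abs(ax))] < 0) ax <- -ax     # deterministic orientation
  proj <- vc %*% ax
  half <- max(abs(proj))
  freeEnd <- proj > endFraction * half
  fixedEnd <- proj < -endFraction * half
  pivot <- v[which.max(proj), ]             # free-end pole
  R <- rotX(deformationDeg)
  disp <- matrix(0, nrow(v), 3L)
  disp[freeEnd, ] <- sweep(sweep(v[freeEnd, , drop = FALSE], 2, pivot) %*% t(R),
                           2, pivot, "+") - v[freeEnd, , drop = FALSE]
  interior <- !(freeEnd | fixedEnd)
  if (any(interior)) {
    f <- mesh@faces
    e <- unique(rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)],
                      f[, 2:1], f[, 3:2], f[, c(1, 3)]))
    A <- Matrix::sparseMatrix(i = e[, 1], j = e[, 2], x = 1,
                              dims = c(nrow(v), nrow(v)))
    deg <- Matrix::rowSums(A)
    L <- Matrix::Diagonal(x = deg) - A
    ii <- which(interior)
    bb <- which(!interior)
    Lii <- L[ii, ii, drop = FALSE]
    Lib <- L[ii, bb, drop = FALSE]
    rhs <- -as.matrix(Lib %*% disp[bb, , drop = FALSE])
    disp[ii, ] <- as.matrix(Matrix::solve(Lii, rhs))
  }
  TriangleMesh(v + disp, mesh@faces)
}

# segments of the intersection of a mesh with the plane z = z0; returns a
# matrix with columns x1, y1, x2, y2 (one row per crossing triangle)
meshPlaneSections <- function(v, f, z0) {
  z <- matrix(v[f, 3], nrow(f), 3)
  above <- z > z0
  na <- rowSums(above)
  cross <- na == 1L | na == 2L
  if (!any(cross)) return(NULL)
  fc <- f[cross, , drop = FALSE]
  out <- matrix(NA_real_, nrow(fc), 4)
  # per crossing triangle exactly two edges cross the plane
  e1 <- cbind(fc[, 1], fc[, 2])
  e2 <- cbind(fc[, 2], fc[, 3])
  e3 <- cbind(fc[, 3], fc[, 1])
  fillP <- function(e) {
    za <- v[e[, 1], 3]; zb <- v[e[, 2], 3]
    hit <- (za > z0) != (zb > z0)
    t <- (z0 - za) / (zb - za)
    px <- v[e[, 1], 1] + t * (v[e[, 2], 1] - v[e[, 1], 1])
    py <- v[e[, 1], 2] + t * (v[e[, 2], 2] - v[e[, 1], 2])
    list(hit = hit, px = px, py = py)
  }
  ps <- lapply(list(e1, e2, e3), fillP)
  for (k in 1:3) {
    p <- ps[[k]]
    first <- p$hit & is.na(out[, 1])
    out[first, 1] <- p$px[first]; out[first, 2] <- p$py[first]
    second <- p$hit & !first & is.na(out[, 3])
    out[second, 3] <- p$px[second]; out[second, 4] <- p$py[second]
  }
  out[stats::complete.cases(out), , drop = FALSE]
}

#' Voxelize a surface mesh into a solid binary volume
#'
#' The mesh is centered in the grid and decomposed slice by slice: each z
#' plane's mesh cross-section is filled by even-odd scanline parity, giving
#' a solid object whose surface voxels lie within half a voxel of the mesh.
#'
#' @param mesh a closed \linkS4class{TriangleMesh} in voxel units.
#' @param gridShape integer length-3 grid dimensions.
#' @param spacing physical voxel size (micrometres), default isotropic 1.
#' @return A \linkS4class{BinaryVolume}.
#' @export
voxelizeMesh <- function(mesh, gridShape, spacing = c(1, 1, 1)) {
  stopifnot(is(mesh, "TriangleMesh"))
  gridShape <- as.integer(gridShape)
  v <- mesh@vertices
  ctr <- (colMeans(apply(v, 2, range)))
  offset <- (gridShape + 1) / 2 - ctr
  v <- sweep(v, 2, offset, "+")
  rng <- apply(v, 2, range)
  if (any(rng[1, ] < 0.5) || any(rng[2, ] > gridShape + 0.5))
    stop("mesh exceeds grid bounds (", paste(gridShape, collapse = "x"),
         "); enlarge gridShape")
  vox <- array(FALSE, gridShape)
  f <- mesh@faces
  # offset the plane a hair off integer z to dodge vertex-on-plane ties
  eps <- 1e-6
  for (z in seq_len(gridShape[3])) {
    segs <- meshPlaneSections(v, f, z + eps)
    if (is.null(segs) || nrow(segs) == 0) next
    vox[, , z] <- fillSegmentSoupMask(segs, gridShape[1], gridShape[2])
  }
  BinaryVolume(vox, spacing)
}

#' Render a phantom specification into a solid voxel volume
#'
#' Convenience wrapper: mesh generation, optional end-rotation deformation,
#' and voxelization in one call.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param spacing physical voxel size, default isotropic 1 um.
#' @return A list with elements \code{mesh} (the, possibly deformed,
#'   \linkS4class{TriangleMesh}) and \code{volume}
#'   (\linkS4class{BinaryVolume}).
#' @export
renderPhantom <- function(spec, spacing = c(1, 1, 1)) {
  mesh <- makeEllipsoidMesh(spec)
  if (spec@deformationDeg > 0)
    mesh <- deformEllipsoid(mesh, spec@deformationDeg)
  list(mesh = mesh, volume = voxelizeMesh(mesh, spec@gridShape, spacing))
}
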