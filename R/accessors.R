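#' @describeIn BinaryVolume voxel grid accessor
#' @param object object to access.
#' @export
setMethod("voxels", "BinaryVolume", function(object) object@voxels)

#' @describeIn BinaryVolume voxel spacing accessor
#' @export
setMethod("spacing", "BinaryVolume", function(object) object@spacing)

#' @describeIn SyntheticStack voxel spacing accessor
#' @export
setMethod("spacing", "SyntheticStack", function(object) object@spacing)

#' @describeIn TriangleMesh vertex accessor
#' @param object object to access.
#' @export
setMethod("meshVertices", "TriangleMesh", function(object) object@vertices)

#' @describeIn TriangleMesh face accessor
#' @export
setMethod("meshFaces", "TriangleMesh", function(object) object@faces)

#' @describeIn EdgeSegment pixel chain accessor
#' @param object object to access.
#' @export
setMethod("segmentPoints", "EdgeSegment", function(object) object@points)

#' @describeIn EdgeSegment class label accessor
#' @export
setMethod("edgeClass", "EdgeSegment", function(object) object@edgeClass)

#' @describeIn Boundary2D contour accessor
#' @param object object to access.
#' @export
setMethod("boundaryContour", "Boundary2D", function(object) object@contour)

#' @describeIn CellRecord morphometry accessor
#' @param object object to access.
#' @export
setMethod("morphometry", "CellRecord", function(object) object@morphometry)

#' @describeIn SyntheticStack ground-truth accessor
#' @param object object to access.
#' @export
setMethod("stackTruth", "SyntheticStack", function(object) object@truth)

#' Construct a TriangleMesh
#'
#' @param vertices n-by-3 numeric matrix.
#' @param faces m-by-3 integer matrix of 1-based indices.
#' @return A \linkS4class{TriangleMesh}.
#' @export
TriangleMesh <- function(vertices, faces) {
  new("TriangleMesh", vertices = as.matrix(vertices),
      faces = matrix(as.integer(as.matrix(faces)), ncol = 3L))
}

#' Construct a BinaryVolume
#'
#' @param voxels 3D logical (or coercible) array.
#' @param spacing numeric length-3 voxel size in micrometres, default 1 um
#'   isotropic.
#' @return A \linkS4class{BinaryVolume}.
#' @export
BinaryVolume <- function(voxels, spacing = c(1, 1, 1)) {
  v <- voxels
  if (!is.logical(v)) {
    storage.mode(v) <- "logical"
  }
  new("BinaryVolume", voxels = v, spacing = as.numeric(spacing))
}

#' Construct a PhantomSpec
#'
#' @param semiAxes numeric length-3 semi-axes (a >= b >= c) in voxels.
#' @param tiltDeg out-of-plane tilt in degrees, [0, 90).
#' @param inPlaneDeg in-plane rotation in degrees, [-90, 90).
#' @param deformationDeg end-rotation deformation in degrees, [0, 90).
#' @param gridShape integer length-3 grid dimensions; by default a cube with
#'   25\% margin around the rotated ellipsoid.
#' @return A \linkS4class{PhantomSpec}.
#' @export
PhantomSpec <- function(semiAxes, tiltDeg = 0, inPlaneDeg = 0,
                        deformationDeg = 0, gridShape = NULL) {
  if (is.null(gridShape)) {
    side <- 2L * ceiling(1.25 * max(semiAxes)) + 3L
    gridShape <- rep(side, 3L)
  }
  new("PhantomSpec", semiAxes = as.numeric(semiAxes),
      tiltDeg = as.numeric(tiltDeg), inPlaneDeg = as.numeric(inPlaneDeg),
      deformationDeg = as.numeric(deformationDeg),
      gridShape = as.integer(gridShape))
}

#' Construct an EdgeSegment
#'
#' @param points n-by-2 matrix of (x, y) pixels in chain order.
#' @param edgeClass,side,part label strings (default "unknown").
#' @param id integer identifier.
#' @return An \linkS4class{EdgeSegment}.
#' @export
EdgeSegment <- function(points, edgeClass = "unknown", side = "unknown",
                        part = "unknown", id = NA_integer_) {
  new("EdgeSegment", points = as.matrix(points), edgeClass = edgeClass,
      side = side, part = part, id = as.integer(id))
}

#' Construct a Boundary2D
#'
#' @param contour n-by-2 matrix of (x, y) points; the loop is normalized to
#'   clockwise orientation (negative signed area in the image frame).
#' @param provenance per-point source tags, recycled if length 1.
#' @param slice slice index.
#' @return A \linkS4class{Boundary2D}.
#' @export
Boundary2D <- function(contour, provenance = "edge", slice = NA_integer_) {
  contour <- as.matrix(contour)
  if (length(provenance) == 1L) provenance <- rep(provenance, nrow(contour))
  # normalize winding: clockwise in (x right, y down) image coordinates
  # corresponds to positive signed area in the mathematical frame
  a <- polygonSignedArea(contour)
  if (a < 0) {
    contour <- contour[rev(seq_len(nrow(contour))), , drop = FALSE]
    provenance <- rev(provenance)
  }
  new("Boundary2D", contour = contour, provenance = provenance,
      slice = as.integer(slice))
}
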