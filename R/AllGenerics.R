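#' @import methods
NULL

#' Voxel grid of a binary volume
#'
#' @param object a \linkS4class{BinaryVolume}.
#' @return A 3D logical array (x, y, z).
#' @export
setGeneric("voxels", function(object) standardGeneric("voxels"))

#' Physical voxel spacing
#'
#' @param object an object carrying per-axis voxel spacing.
#' @return Numeric vector of length 3 (x, y, z) in micrometres.
#' @export
setGeneric("spacing", function(object) standardGeneric("spacing"))

#' Mesh vertex coordinates
#'
#' @param object a \linkS4class{TriangleMesh}.
#' @return An n-by-3 numeric matrix.
#' @export
setGeneric("meshVertices", function(object) standardGeneric("meshVertices"))

#' Mesh face index triples
#'
#' @param object a \linkS4class{TriangleMesh}.
#' @return An m-by-3 integer matrix of 1-based vertex indices.
#' @export
setGeneric("meshFaces", function(object) standardGeneric("meshFaces"))

#' Ordered pixel chain of an edge segment
#'
#' @param object an \linkS4class{EdgeSegment}.
#' @return An n-by-2 matrix of (x, y) pixel coordinates.
#' @export
setGeneric("segmentPoints", function(object) standardGeneric("segmentPoints"))

#' Edge class label (A, B, C, inner or unknown)
#'
#' @param object an \linkS4class{EdgeSegment}.
#' @return A single character string.
#' @export
setGeneric("edgeClass", function(object) standardGeneric("edgeClass"))

#' Closed contour of a per-slice cell boundary
#'
#' @param object a \linkS4class{Boundary2D}.
#' @return An n-by-2 matrix of (x, y) points forming a closed loop.
#' @export
setGeneric("boundaryContour", function(object) standardGeneric("boundaryContour"))

#' Morphometry of a reconstructed cell
#'
#' @param object a \linkS4class{CellRecord}.
#' @return A one-row data.frame with L, W, T, slenderness, beta, alpha.
#' @export
setGeneric("morphometry", function(object) standardGeneric("morphometry"))

#' Ground-truth records of a synthetic stack
#'
#' @param object a \linkS4class{SyntheticStack}.
#' @return A list with one entry per generated cell.
#' @export
setGeneric("stackTruth", function(object) standardGeneric("stackTruth"))
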