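#' Triangle surface mesh
#'
#' Vertices are in voxel (or physical) coordinates, faces are 1-based vertex
#' index triples. Phantom ellipsoid meshes are watertight.
#'
#' @slot vertices n-by-3 numeric matrix.
#' @slot faces m-by-3 integer matrix.
#' @export
setClass("TriangleMesh",
  representation(vertices = "matrix", faces = "matrix"),
  validity = function(object) {
    v <- object@vertices; f <- object@faces
    if (ncol(v) != 3L) return("vertices must have 3 columns")
    if (ncol(f) != 3L) return("faces must have 3 columns")
    if (nrow(f) > 0 && (min(f) < 1L || max(f) > nrow(v)))
      return("face indices out of range")
    if (any(!is.finite(v))) return("non-finite vertex coordinates")
    TRUE
  })

#' Solid binary voxel volume
#'
#' A 3D logical grid indexed (x, y, z) with per-axis physical voxel spacing
#' in micrometres.
#'
#' @slot voxels 3D logical array.
#' @slot spacing numeric length-3, micrometres per voxel along x, y, z.
#' @export
setClass("BinaryVolume",
  representation(voxels = "array", spacing = "numeric"),
  validity = function(object) {
    if (length(dim(object@voxels)) != 3L) return("voxels must be a 3D array")
    if (!is.logical(object@voxels)) return("voxels must be logical")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      return("spacing must be 3 positive values")
    TRUE
  })

#' Virtual ellipsoid phantom specification
#'
#' Describes one phantom: semi-axes a >= b >= c (voxels), an out-of-plane
#' tilt, an in-plane rotation, an optional end-rotation deformation angle,
#' and the voxel grid it is rendered into. A deformation of 0 degrees keeps
#' the ellipsoid rigid.
#'
#' @slot semiAxes numeric length-3, a >= b >= c > 0, in voxels.
#' @slot tiltDeg out-of-plane tilt in degrees, in [0, 90).
#' @slot inPlaneDeg in-plane rotation in degrees, in [-90, 90).
#' @slot deformationDeg end-rotation deformation angle in degrees, [0, 90).
#' @slot gridShape integer length-3 voxel grid dimensions.
#' @export
setClass("PhantomSpec",
  representation(semiAxes = "numeric", tiltDeg = "numeric",
                 inPlaneDeg = "numeric", deformationDeg = "numeric",
                 gridShape = "integer"),
  validity = function(object) {
    a <- object@semiAxes
    if (length(a) != 3L || any(a <= 0)) return("semiAxes must be 3 positive values")
    if (is.unsorted(rev(a))) return("semiAxes must satisfy a >= b >= c")
    if (object@tiltDeg < 0 || object@tiltDeg >= 90) return("tiltDeg must be in [0, 90)")
    if (object@inPlaneDeg < -90 || object@inPlaneDeg >= 90)
      return("inPlaneDeg must be in [-90, 90)")
    if (object@deformationDeg < 0 || object@deformationDeg >= 90)
      return("deformationDeg must be in [0, 90)")
    if (length(object@gridShape) != 3L || any(object@gridShape < 3L))
      return("gridShape must be 3 integers >= 3")
    TRUE
  })

#' Synthetic two-channel fusiform-cell stack
#'
#' Cell (F-actin analogue) and nucleus intensity channels with per-cell
#' ground truth. Deterministic given its seed.
#'
#' @slot cellChannel 3D numeric array (x, y, z) in [0, 1] plus noise.
#' @slot nucleusChannel 3D numeric array, same shape.
#' @slot truth list of per-cell truth records (center, L, W, T, beta, alpha,
#'   per-slice contours).
#' @slot spacing numeric length-3, micrometres per voxel.
#' @slot seed integer RNG seed used for generation.
#' @export
setClass("SyntheticStack",
  representation(cellChannel = "array", nucleusChannel = "array",
                 truth = "list", spacing = "numeric", seed = "integer"),
  validity = function(object) {
    if (!identical(dim(object@cellChannel), dim(object@nucleusChannel)))
      return("channel dimensions differ")
    if (length(dim(object@cellChannel)) != 3L) return("channels must be 3D")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      return("spacing must be 3 positive values")
    TRUE
  })

#' Nucleus-derived seed geometry of one cell on one slice
#'
#' The nucleus centroid acts as the cell center c0, the pruned skeleton
#' carries exactly two endpoints, and the cell vector points from the center
#' toward one endpoint of the long axis.
#'
#' @slot center numeric length-2 (x, y) pixel coordinate.
#' @slot skeleton k-by-2 matrix, ordered skeleton pixel chain.
#' @slot endpoints 2-by-2 matrix, the two skeleton termini.
#' @slot cellVector numeric length-2 unit vector.
#' @slot lowAnisotropy logical; TRUE when the mask was near-circular and the
#'   vector came from image moments rather than the skeleton.
#' @export
setClass("NucleusGeometry",
  representation(center = "numeric", skeleton = "matrix",
                 endpoints = "matrix", cellVector = "numeric",
                 lowAnisotropy = "logical"),
  validity = function(object) {
    if (length(object@center) != 2L) return("center must be length 2")
    if (abs(sqrt(sum(object@cellVector^2)) - 1) > 1e-6)
      return("cellVector must be unit length")
    if (nrow(object@endpoints) != 2L) return("exactly two endpoints required")
    TRUE
  })

#' Single-pixel-wide edge chain
#'
#' An ordered, 8-connected chain of edge pixels with exactly two endpoints
#' (no bifurcations), plus its class (A/B/C/inner/unknown), side and part
#' labels.
#'
#' @slot points n-by-2 matrix of (x, y) pixels, in chain order.
#' @slot edgeClass one of "A", "B", "C", "inner", "unknown".
#' @slot side one of "left", "right", "unknown".
#' @slot part one of "trunk", "tail", "unknown".
#' @slot id integer segment identifier.
#' @export
setClass("EdgeSegment",
  representation(points = "matrix", edgeClass = "character",
                 side = "character", part = "character", id = "integer"),
  prototype(edgeClass = "unknown", side = "unknown", part = "unknown",
            id = NA_integer_),
  validity = function(object) {
    p <- object@points
    if (ncol(p) != 2L) return("points must have 2 columns")
    if (nrow(p) < 1L) return("empty chain")
    if (nrow(p) > 1L) {
      d <- abs(diff(p))
      if (any(pmax(d[, 1], d[, 2]) > 1 | (d[, 1] == 0 & d[, 2] == 0)))
        return("chain must be 8-connected with no repeated points")
    }
    if (!object@edgeClass %in% c("A", "B", "C", "inner", "unknown"))
      return("invalid edgeClass")
    if (!object@side %in% c("left", "right", "unknown")) return("invalid side")
    if (!object@part %in% c("trunk", "tail", "unknown")) return("invalid part")
    TRUE
  })

#' Ray-fan edge blocking result
#'
#' Per-ray ordered intersections, the retained (rank-1) segments, and the
#' typed angular gaps.
#'
#' @slot rays data.frame of cast rays (originX, originY, theta, l, dirX,
#'   dirY, extended).
#' @slot hits data.frame of intersections (ray, segment, distance, rank,
#'   x, y, withinBound).
#' @slot retained integer vector of retained segment ids.
#' @slot gaps data.frame of angular gap runs (thetaStart, thetaEnd, type,
#'   leftSegment, rightSegment).
#' @slot segments list of the input \linkS4class{EdgeSegment} objects,
#'   indexed by id.
#' @export
setClass("BlockingResult",
  representation(rays = "data.frame", hits = "data.frame",
                 retained = "integer", gaps = "data.frame",
                 segments = "list"))

#' Closed 2D cell boundary on one slice
#'
#' @slot contour n-by-2 matrix, closed clockwise loop (first point not
#'   repeated).
#' @slot provenance character per-point source tag: "edge", "interpolated",
#'   "pca" or "split".
#' @slot slice integer slice index.
#' @export
setClass("Boundary2D",
  representation(contour = "matrix", provenance = "character",
                 slice = "integer"),
  validity = function(object) {
    if (ncol(object@contour) != 2L) return("contour must have 2 columns")
    if (nrow(object@contour) < 3L) return("contour needs >= 3 points")
    if (length(object@provenance) != nrow(object@contour))
      return("provenance length must match contour")
    TRUE
  })

#' One reconstructed cell
#'
#' @slot id integer cell identifier.
#' @slot volume \linkS4class{BinaryVolume} of the reconstructed cell.
#' @slot mesh \linkS4class{TriangleMesh} of the smoothed surface (may be of
#'   zero size when surface extraction was skipped).
#' @slot morphometry one-row data.frame (L, W, T, slenderness, beta, alpha).
#' @slot flags character vector of non-fatal warnings raised during
#'   segmentation.
#' @export
setClass("CellRecord",
  representation(id = "integer", volume = "BinaryVolume",
                 mesh = "TriangleMesh", morphometry = "data.frame",
                 flags = "character"))

## show methods ---------------------------------------------------------------

setMethod("show", "TriangleMesh", function(object) {
  cat(sprintf("TriangleMesh: %d vertices, %d faces\n",
              nrow(object@vertices), nrow(object@faces)))
})

setMethod("show", "BinaryVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("BinaryVolume: %d x %d x %d voxels (%d foreground), spacing %s um\n",
              d[1], d[2], d[3], sum(object@voxels),
              paste(signif(object@spacing, 3), collapse = " x ")))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(
    "PhantomSpec: semi-axes (%s) vox, tilt %.1f deg, in-plane %.1f deg, deformation %.1f deg\n",
    paste(object@semiAxes, collapse = ", "), object@tiltDeg,
    object@inPlaneDeg, object@deformationDeg))
})

setMethod("show", "SyntheticStack", function(object) {
  d <- dim(object@cellChannel)
  cat(sprintf("SyntheticStack: %d x %d x %d, %d cells, seed %d\n",
              d[1], d[2], d[3], length(object@truth), object@seed))
})

setMethod("show", "EdgeSegment", function(object) {
  cat(sprintf("EdgeSegment #%s: %d px, class %s, side %s, part %s\n",
              object@id, nrow(object@points), object@edgeClass,
              object@side, object@part))
})

setMethod("show", "NucleusGeometry", function(object) {
  cat(sprintf("NucleusGeometry: center (%.1f, %.1f), cell vector (%.3f, %.3f)%s\n",
              object@center[1], object@center[2], object@cellVector[1],
              object@cellVector[2],
              if (object@lowAnisotropy) " [low anisotropy]" else ""))
})

setMethod("show", "BlockingResult", function(object) {
  cat(sprintf("BlockingResult: %d rays, %d hits, %d retained segments, %d gaps\n",
              nrow(object@rays), nrow(object@hits), length(object@retained),
              nrow(object@gaps)))
})

setMethod("show", "Boundary2D", function(object) {
  cat(sprintf("Boundary2D (slice %d): %d points (%s)\n", object@slice,
              nrow(object@contour),
              paste(names(table(object@provenance)), table(object@provenance),
                    sep = ":", collapse = ", ")))
})

setMethod("show", "CellRecord", function(object) {
  m <- object@morphometry
  cat(sprintf("CellRecord #%d: L %.1f, W %.1f, T %.1f um, beta %.1f, alpha %.1f deg%s\n",
              object@id, m$L, m$W, m$T, m$beta, m$alpha,
              if (length(object@flags)) paste0(" [", paste(object@flags, collapse = "; "), "]")
              else ""))
})
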