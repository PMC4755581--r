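# The ray-fan edge blocking model: rays emitted from the nucleus-derived
# cell center intersect candidate edge chains; only first (rank-1)
# intersections are retained, runs of hitless rays become typed gaps.

#' Scattering angle of an edge point
#'
#' The ray angle is the angle of the cell vector minus the angle of
#' (point - center), wrapped into [0, 360) degrees: a point along the cell
#' vector has theta = 0.
#'
#' @param point (x, y) edge point.
#' @param center cell center c0.
#' @param cellVector unit orientation vector (n_x, n_y).
#' @return theta in degrees, [0, 360).
#' @export
rayAngle <- function(point, center, cellVector) {
  dx <- point[1] - center[1]
  dy <- point[2] - center[2]
  if (abs(dx) < 1e-12 && abs(dy) < 1e-12)
    stop("point coincides with center")
  wrap360(rad2deg(atan2(cellVector[2], cellVector[1]) - atan2(dy, dx)))
}

#' Anisotropic emitting-length bound
#'
#' l(theta) = lc0 (1 + lc1 cos(theta)): largest along the cell vector and
#' smallest perpendicular to it. With the default lc1 = 5 the literal form
#' goes negative near theta = 180 degrees, so the bound is clamped into
#' [lc1, lc0 (1 + lc1)] by default, honoring lc1/lc0 as the minimal and
#' maximal emitting lengths; \code{clamp = FALSE} keeps the literal form
#' for fidelity experiments.
#'
#' @param theta scattering angle(s), degrees.
#' @param lc0 maximal emitting length scale in px (default 30).
#' @param lc1 minimal emitting length in px (default 5).
#' @param clamp clamp into [lc1, lc0 (1 + lc1)] (default TRUE).
#' @return Length bound(s) in px.
#' @export
rayLengthBound <- function(theta, lc0 = 30, lc1 = 5, clamp = TRUE) {
  if (lc0 <= 0 || lc1 <= 0) stop("lc0 and lc1 must be positive")
  l <- lc0 * (1 + lc1 * cos(deg2rad(theta)))
  if (clamp) l <- pmin(pmax(l, lc1), lc0 * (1 + lc1))
  l
}

#' Cast the ray fan of one cell
#'
#' Rays at a uniform angular step are emitted from the cell center over the
#' full circle. In the tail sectors - where rays run nearly parallel to the
#' near-axial edges of a fusiform cell (within \code{extendedRayTol} of
#' parallel) - additional extended rays are emitted from the two skeleton
#' endpoints so the tapering tails beyond the center rays' length bound are
#' still reached.
#'
#' @param geometry a \linkS4class{NucleusGeometry}.
#' @param angularStep fan resolution in degrees (default 1).
#' @param lc0,lc1 emitting-length parameters, px.
#' @param clamp clamped length bound flag.
#' @param trunkHalfAngle trunk sector half-width around the normal to the
#'   cell vector, degrees (default 60): ray angles outside the trunk
#'   sectors belong to the tails.
#' @param extendedRayTol parallelism tolerance triggering extended rays,
#'   degrees (default 15).
#' @return data.frame of rays: originX, originY, theta, l, dirX, dirY,
#'   extended.
#' @export
castRayFan <- function(geometry, angularStep = 1, lc0 = 30, lc1 = 5,
                       clamp = TRUE, trunkHalfAngle = 60,
                       extendedRayTol = 15) {
  if (angularStep <= 0) stop("angularStep must be positive")
  stopifnot(is(geometry, "NucleusGeometry"))
  theta <- seq(0, 360 - angularStep, by = angularStep)
  v <- geometry@cellVector
  base <- atan2(v[2], v[1])
  # theta measured clockwise from the cell vector (Eq-style subtraction)
  dirX <- cos(base - deg2rad(theta))
  dirY <- sin(base - deg2rad(theta))
  l <- rayLengthBound(theta, lc0, lc1, clamp)
  ctr <- geometry@center
  rays <- data.frame(originX = ctr[1], originY = ctr[2], theta = theta,
                     l = l, dirX = dirX, dirY = dirY, extended = FALSE)
  # tail sectors: angles farther than trunkHalfAngle from the normal
  # directions (90 and 270) -- there rays are within extendedRayTol of
  # parallel to the tail edge direction (the cell vector)
  distToNormal <- pmin(abs(fold90(theta - 90)), abs(fold90(theta - 270)))
  axisAngle <- abs(fold90(theta))            # angle between ray and cell axis
  tail <- distToNormal > trunkHalfAngle & axisAngle <= extendedRayTol
  if (any(tail)) {
    ep <- geometry@endpoints
    # forward tail (theta near 0) from the endpoint along +cellVector,
    # backward tail (theta near 180) from the opposite endpoint
    proj <- (ep[, 1] - ctr[1]) * v[1] + (ep[, 2] - ctr[2]) * v[2]
    fwd <- ep[which.max(proj), ]
    bwd <- ep[which.min(proj), ]
    near0 <- tail & (theta <= 90 | theta >= 270)
    ext <- rays[tail, , drop = FALSE]
    ext$originX <- ifelse(near0[tail], fwd[1], bwd[1])
    ext$originY <- ifelse(near0[tail], fwd[2], bwd[2])
    # extended rays run along the cell axis by construction; their length
    # bound uses the axis alignment |cos theta| so the backward tail is
    # reachable (the literal bound collapses to lc1 behind the center)
    extL <- lc0 * (1 + lc1 * abs(cos(deg2rad(ext$theta))))
    if (clamp) extL <- pmin(pmax(extL, lc1), lc0 * (1 + lc1))
    ext$l <- extL
    ext$extended <- TRUE
    rays <- rbind(rays, ext)
  }
  rays
}

#' Block edges by first ray intersections
#'
#' Every ray is intersected with every segment chain; intersections are
#' ranked by distance from the ray origin. Segments with at least one
#' rank-1 hit are retained; segments hit only at rank 2 or deeper are
#' blocked (rank >= 3 hits are noise). Maximal runs of at least
#' \code{gapMinRun} center rays with no hit inside their length bound
#' become gaps, Type I when both flanking retained segments are class A of
#' the current cell, else Type II.
#'
#' @param rays data.frame from \code{\link{castRayFan}}.
#' @param segments list of classified \linkS4class{EdgeSegment} objects
#'   (ids must be unique).
#' @param gapMinRun minimal hitless run length (default 3).
#' @return A \linkS4class{BlockingResult}.
#' @export
blockEdges <- function(rays, segments, gapMinRun = 3L) {
  ids <- vapply(segments, function(s) s@id, 1L)
  if (anyDuplicated(ids)) stop("segment ids must be unique")
  names(segments) <- as.character(ids)
  edges <- segmentEdgeTable(segments)
  hits <- vector("list", nrow(rays))
  for (i in seq_len(nrow(rays))) {
    o <- c(rays$originX[i], rays$originY[i])
    d <- c(rays$dirX[i], rays$dirY[i])
    h <- if (nrow(edges)) rayIntersections(o, d, edges) else
      data.frame(t = numeric(0), x = numeric(0), y = numeric(0),
                 id = integer(0))
    if (nrow(h)) {
      # one hit per segment per ray: the nearest crossing of that chain
      h <- h[!duplicated(h$id), , drop = FALSE]
      h <- h[order(h$t, h$id), , drop = FALSE]
      hits[[i]] <- data.frame(ray = i, segment = h$id, distance = h$t,
                              rank = seq_len(nrow(h)), x = h$x, y = h$y,
                              withinBound = h$t <= rays$l[i])
    }
  }
  hits <- if (any(!vapply(hits, is.null, TRUE)))
    do.call(rbind, hits) else
    data.frame(ray = integer(0), segment = integer(0), distance = numeric(0),
               rank = integer(0), x = numeric(0), y = numeric(0),
               withinBound = logical(0))
  # rank >= 3 intersections are noise
  hits <- hits[hits$rank <= 2L, , drop = FALSE]
  hitSegs <- unique(hits$segment)
  retained <- sort(unique(hits$segment[hits$rank == 1L]))
  gaps <- detectGaps(rays, hits, segments, retained, gapMinRun)
  new("BlockingResult", rays = rays, hits = hits,
      retained = as.integer(retained), gaps = gaps, segments = segments)
}

# angular gap runs over the center-ray fan (extended rays only fill tail
# coverage and do not open gaps on their own)
detectGaps <- function(rays, hits, segments, retained, gapMinRun) {
  centerIdx <- which(!rays$extended)
  ord <- centerIdx[order(rays$theta[centerIdx])]
  thetaOrd <- rays$theta[ord]
  n <- length(ord)
  empty <- data.frame(thetaStart = numeric(0), thetaEnd = numeric(0),
                      type = character(0), leftSegment = integer(0),
                      rightSegment = integer(0))
  if (!n) return(empty)
  # a ray angle is covered when any ray at that angle (center or extended)
  # has an in-bound rank-1 hit on a boundary-class segment, or when such a
  # retained chain subtends it: gaps mark missing boundary coverage, not
  # bound shortfalls of the anisotropic emitting length. Class-B (other
  # cell) edges never provide coverage - sectors occluded by them are the
  # Type II gaps.
  segClassOf <- function(id) segments[[as.character(id)]]@edgeClass
  bClass <- vapply(hits$segment, segClassOf, character(1))
  good <- hits[hits$withinBound & hits$rank == 1L & bClass != "B", ,
               drop = FALSE]
  coveredTheta <- unique(rays$theta[good$ray])
  retained <- retained[vapply(retained, segClassOf, character(1)) != "B"]
  step <- if (n > 1) thetaOrd[2] - thetaOrd[1] else 360
  org <- c(rays$originX[ord[1]], rays$originY[ord[1]])
  baseAng <- atan2(rays$dirY[ord[1]], rays$dirX[ord[1]]) +
    deg2rad(rays$theta[ord[1]])          # cell-vector angle
  for (id in retained) {
    P <- segments[[as.character(id)]]@points
    rel <- cbind(P[, 1] - org[1], P[, 2] - org[2])
    okp <- rowSums(rel^2) > 1e-12
    if (!any(okp)) next
    aPts <- wrap360(rad2deg(baseAng - atan2(rel[okp, 2], rel[okp, 1])))
    # mark every angular bin swept between consecutive chain points (the
    # points alone undersample chains far from the origin)
    cov <- floor(aPts / step) * step
    if (length(aPts) > 1) {
      for (k in 1:(length(aPts) - 1)) {
        dAng <- ((aPts[k + 1] - aPts[k] + 180) %% 360) - 180
        if (abs(dAng) < 90 && abs(dAng) > step) {
          fill <- seq(0, dAng, by = step * sign(dAng))
          cov <- c(cov, floor(wrap360(aPts[k] + fill) / step) * step)
        }
      }
    }
    coveredTheta <- union(coveredTheta, unique(cov))
  }
  miss <- !(thetaOrd %in% coveredTheta)
  if (!any(miss)) return(empty)
  if (all(miss)) {
    return(data.frame(thetaStart = thetaOrd[1], thetaEnd = thetaOrd[n],
                      type = "II", leftSegment = NA_integer_,
                      rightSegment = NA_integer_))
  }
  # runs of consecutive missing angles, circular
  r <- rle(miss)
  starts <- cumsum(c(1, r$lengths))[seq_along(r$lengths)]
  runs <- data.frame(start = starts, len = r$lengths, val = r$values)
  runs <- runs[runs$val, , drop = FALSE]
  # merge a wrap-around run
  if (nrow(runs) > 1 && miss[1] && miss[n]) {
    first <- runs[1, ]; last <- runs[nrow(runs), ]
    runs <- runs[-c(1, nrow(runs)), , drop = FALSE]
    runs <- rbind(runs, data.frame(start = last$start,
                                   len = last$len + first$len, val = TRUE))
  }
  runs <- runs[runs$len >= gapMinRun, , drop = FALSE]
  if (!nrow(runs)) return(empty)
  segClass <- function(id) {
    if (is.na(id) || !as.character(id) %in% names(segments)) return(NA_character_)
    segments[[as.character(id)]]@edgeClass
  }
  firstHitSeg <- function(rayPos, step = 1L) {
    # a flanking ray can be covered by chain subtension alone (bin
    # granularity, clamped backward bounds); walk a few rays outward until
    # a rank-1 hit names the flanking segment
    for (k in 0:3) {
      ray <- ord[(rayPos + k * step - 1) %% n + 1]
      h <- good[good$ray == ray, , drop = FALSE]
      if (nrow(h)) return(h$segment[1])
      h2 <- hits[hits$ray == ray & hits$rank == 1L, , drop = FALSE]
      if (nrow(h2)) return(h2$segment[1])
    }
    NA_integer_
  }
  out <- lapply(seq_len(nrow(runs)), function(k) {
    s <- runs$start[k]; len <- runs$len[k]
    leftSeg <- firstHitSeg(s - 1, step = -1L)
    rightSeg <- firstHitSeg(s + len, step = 1L)
    type <- if (!is.na(leftSeg) && !is.na(rightSeg) &&
                identical(segClass(leftSeg), "A") &&
                identical(segClass(rightSeg), "A")) "I" else "II"
    data.frame(thetaStart = thetaOrd[(s - 1) %% n + 1],
               thetaEnd = thetaOrd[(s + len - 2) %% n + 1],
               type = type, leftSegment = leftSeg, rightSegment = rightSeg)
  })
  do.call(rbind, out)
}
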