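# Stable-edge tracking across z slices: points that persist (within a
# pixel window) in neighboring slices mark stable edges; unstable chains
# are treated as noise and handed back to the gap-filling fallbacks.

#' Overlap score of a point against a seed edge
#'
#' O = 1 - min(d(e_i, e_0)) / w over all seed-edge points e_0, with
#' Euclidean d and neighbor window width w. O = 1 exactly at zero distance
#' and 0 at distance w; more distant points go negative (unclamped).
#'
#' @param point (x, y) candidate point e_i.
#' @param seedEdge \linkS4class{EdgeSegment} or n-by-2 point matrix E_0.
#' @param w neighbor window width in px (> 0).
#' @return Overlap score O in (-Inf, 1].
#' @export
pointOverlap <- function(point, seedEdge, w) {
  if (w <= 0) stop("w must be positive")
  P <- if (is(seedEdge, "EdgeSegment")) seedEdge@points else as.matrix(seedEdge)
  if (!nrow(P)) stop("empty seed edge")
  dmin <- sqrt(min((P[, 1] - point[1])^2 + (P[, 2] - point[2])^2))
  1 - dmin / w
}

# vectorized minimal distances from each row of A to the point set B
minDistances <- function(A, B) {
  vapply(seq_len(nrow(A)), function(i)
    sqrt(min((B[, 1] - A[i, 1])^2 + (B[, 2] - A[i, 2])^2)), numeric(1))
}

#' Stability of an edge across neighboring slices
#'
#' Per candidate point, the overlap score is averaged over the M seed
#' edges; per ray line the maximal-score point is marked stable, and the
#' edge is labeled stable when its stable-point ratio exceeds the
#' threshold (default 30\%).
#'
#' @param edge candidate \linkS4class{EdgeSegment} on the current slice.
#' @param seedEdges list of M seed edges (EdgeSegment or point matrix)
#'   from neighboring slices.
#' @param w neighbor window width, px (default 5).
#' @param center,cellVector cell geometry defining the ray lines; when
#'   center is NULL every point is its own ray and stability reduces to
#'   the per-point average score.
#' @param threshold stable-point ratio above which the edge is stable
#'   (default 0.30).
#' @return A list: \code{S} (mean stability over stable points),
#'   \code{perPoint} (per-point averaged O), \code{stableMask} (logical
#'   per point), \code{stableRatio}, \code{stable} (TRUE/FALSE).
#' @export
edgeStability <- function(edge, seedEdges, w = 5, center = NULL,
                          cellVector = c(0, 1), threshold = 0.30) {
  if (!length(seedEdges)) stop("need at least one seed edge (M >= 1)")
  P <- if (is(edge, "EdgeSegment")) edge@points else as.matrix(edge)
  M <- length(seedEdges)
  O <- matrix(0, nrow(P), M)
  for (j in seq_len(M)) {
    S0 <- if (is(seedEdges[[j]], "EdgeSegment")) seedEdges[[j]]@points
          else as.matrix(seedEdges[[j]])
    O[, j] <- 1 - minDistances(P, S0) / w
  }
  perPoint <- rowMeans(O)
  if (is.null(center)) {
    stableMask <- perPoint >= 0
    ratio <- mean(stableMask)
  } else {
    # one stable-point candidate per ray line (angle bin): the maximal-O
    # point; the edge's stable ratio is over the ray lines it spans
    ang <- vapply(seq_len(nrow(P)), function(i)
      rayAngle(P[i, ], center, cellVector), numeric(1))
    bin <- floor(ang)
    stableMask <- logical(nrow(P))
    nBins <- 0L
    nStable <- 0L
    for (b in unique(bin)) {
      i <- which(bin == b)
      best <- i[which.max(perPoint[i])]
      nBins <- nBins + 1L
      if (perPoint[best] > 0) {
        stableMask[best] <- TRUE
        nStable <- nStable + 1L
      }
    }
    ratio <- nStable / nBins
  }
  list(S = if (any(stableMask)) mean(perPoint[stableMask]) else mean(perPoint),
       perPoint = perPoint, stableMask = stableMask, stableRatio = ratio,
       stable = ratio > threshold)
}

#' Propagate a boundary to the next slice
#'
#' Segments on the current slice passing the stability test against the
#' previous slice's accepted boundary are accepted; unstable ones are
#' dropped (the caller fills the resulting gaps with the edge-growing
#' fallbacks). Abrupt position changes are prevented by capping the
#' per-point displacement to the nearest seed-boundary point.
#'
#' @param prev the previous slice's \linkS4class{Boundary2D} (or a list of
#'   recent boundaries, newest last, used as the M seed edges).
#' @param sliceSegments cleaned, classified \linkS4class{EdgeSegment}s of
#'   the current slice.
#' @param geometry current \linkS4class{NucleusGeometry}.
#' @param config a \linkS4class{PipelineConfig}.
#' @return A list: \code{accepted} (stable segments), \code{rejected},
#'   \code{fallback} (TRUE when nothing passed and the caller must fall
#'   back to interpolation/PCA or user input).
#' @export
propagateBoundary <- function(prev, sliceSegments, geometry, config) {
  seeds <- if (is(prev, "Boundary2D")) list(prev@contour)
           else lapply(prev, function(b)
             if (is(b, "Boundary2D")) b@contour else as.matrix(b))
  seeds <- utils::tail(seeds, config@stableSlices)
  accepted <- list()
  rejected <- list()
  for (s in sliceSegments) {
    st <- edgeStability(s, seeds, w = config@stableWindow,
                        center = geometry@center,
                        cellVector = geometry@cellVector,
                        threshold = config@stabilityThreshold)
    # displacement cap: no abrupt position changes along the slices (the
    # bulk of the chain must stay near the seed; tail growth beyond the
    # previous boundary's coverage is legitimate, so the cap is on the
    # median, not the maximum)
    disp <- stats::median(minDistances(s@points, seeds[[length(seeds)]]))
    if (st$stable && disp <= config@maxDisplacement * config@stableSlices) {
      accepted[[length(accepted) + 1]] <- s
    } else {
      rejected[[length(rejected) + 1]] <- s
    }
  }
  list(accepted = accepted, rejected = rejected,
       fallback = length(accepted) == 0L)
}
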