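# Gap filling and boundary assembly: bilateral spline interpolation with a
# curvature-minimizing junction, Laplace-verified PCA edge growing, the
# Type-C splitting approach, and closure of the per-slice boundary.

#' Discrete curvature metrics of a 2D curve
#'
#' The accumulated curvature is the total absolute turning angle over the
#' interior points (radians; a full circle accumulates 2*pi regardless of
#' sampling); the average curvature normalizes it by the curve length in
#' pixels (a circle of radius r averages 1/r).
#'
#' @param curve ordered n-by-2 point matrix, n >= 3.
#' @return Named numeric vector \code{c(accCurv, avgCurv)}.
#' @export
curvatureMetrics <- function(curve) {
  curve <- as.matrix(curve)
  n <- nrow(curve)
  if (n < 3) stop("need at least 3 points")
  d <- diff(curve)
  len <- sqrt(rowSums(d^2))
  keep <- len > 1e-12
  d <- d[keep, , drop = FALSE]
  len <- len[keep]
  m <- nrow(d)
  if (m < 2) return(c(accCurv = 0, avgCurv = 0))
  a1 <- atan2(d[-m, 2], d[-m, 1])
  a2 <- atan2(d[-1, 2], d[-1, 1])
  turn <- abs(atan2(sin(a2 - a1), cos(a2 - a1)))
  acc <- sum(turn)
  c(accCurv = acc, avgCurv = acc / sum(len))
}

# Catmull-Rom bridge between the last point of P1 and point j of P2,
# sampled at roughly unit arc spacing (endpoints excluded)
bridgeCurve <- function(P1, P2, j) {
  p1 <- P1[nrow(P1), ]
  p2 <- P2[j, ]
  p0 <- if (nrow(P1) > 1) P1[nrow(P1) - 1, ] else p1 + (p1 - p2) * 0.01
  p3 <- if (j < nrow(P2)) P2[j + 1, ] else p2 + (p2 - p1) * 0.01
  nSamp <- max(2L, ceiling(sqrt(sum((p2 - p1)^2))))
  t <- seq(0, 1, length.out = nSamp + 1L)[-c(1, nSamp + 1L)]
  if (!length(t)) return(NULL)
  catmullRom(p0, p1, p2, p3, t)
}

#' Bilateral spline interpolation across a Type I gap
#'
#' Interpolates twice - from edge 1 into edge 2 and from edge 2 into edge
#' 1 - sweeping the floating junction point over the receiving edge. For
#' each direction the junction minimizing the accumulated (and, as a second
#' variant, the average) curvature of the linked edge is kept, giving four
#' interpolation options. The final option is the one with the smallest
#' standard deviation of intersection-point lengths (distances of linked
#' edge points from the cell center, binned per ray angle).
#'
#' @param E1,E2 \linkS4class{EdgeSegment} objects flanking the gap, ordered
#'   so the gap lies between the end of E1 and the start of E2.
#' @param center cell center c0 used for the intersection lengths.
#' @param cellVector unit orientation vector for ray angles.
#' @param lc0 emitting length scale; gaps wider than
#'   \code{maxGapFactor * lc0} are rejected.
#' @param maxGapFactor widest admissible gap in units of lc0 (default 3).
#' @return A list of class \code{"GapFill"}: \code{gapType},
#'   \code{fillPoints} (the winning bridge curve), \code{option} (one of
#'   "12.acc", "12.avg", "21.acc", "21.avg"), \code{junction} (index into
#'   the receiving edge), \code{metrics} (per-option accCurv, avgCurv, sd),
#'   \code{linked} (full linked point chain).
#' @export
bilateralSplineInterpolate <- function(E1, E2, center, cellVector = c(0, 1),
                                       lc0 = 30, maxGapFactor = 3) {
  P1 <- E1@points
  P2 <- E2@points
  gapWidth <- sqrt(sum((P2[1, ] - P1[nrow(P1), ])^2))
  if (gapWidth > maxGapFactor * lc0)
    stop(sprintf("gap width %.1f px exceeds %g * lc0; likely mis-seeded",
                 gapWidth, maxGapFactor))
  sweepDir <- function(A, B) {
    # support: all of A plus B from the junction j onward
    nB <- nrow(B)
    res <- lapply(seq_len(nB), function(j) {
      fill <- bridgeCurve(A, B, j)
      linked <- rbind(A, fill, B[j:nB, , drop = FALSE])
      cm <- curvatureMetrics(linked)
      list(j = j, fill = fill, linked = linked, acc = cm[["accCurv"]],
           avg = cm[["avgCurv"]])
    })
    res
  }
  # direction 12: from edge 1 to edge 2; direction 21: reverse chains
  res12 <- sweepDir(P1, P2)
  res21 <- sweepDir(P2[rev(seq_len(nrow(P2))), , drop = FALSE],
                    P1[rev(seq_len(nrow(P1))), , drop = FALSE])
  pick <- function(res, what) {
    vals <- vapply(res, `[[`, numeric(1), what)
    res[[which.min(vals)]]                      # smallest index wins ties
  }
  cand <- list(`12.acc` = pick(res12, "acc"), `12.avg` = pick(res12, "avg"),
               `21.acc` = pick(res21, "acc"), `21.avg` = pick(res21, "avg"))
  sdLe <- function(linked) {
    ang <- vapply(seq_len(nrow(linked)), function(i)
      rayAngle(linked[i, ], center, cellVector), numeric(1))
    le <- sqrt((linked[, 1] - center[1])^2 + (linked[, 2] - center[2])^2)
    perRay <- tapply(le, floor(ang), mean)
    stats::sd(perRay)
  }
  metrics <- do.call(rbind, lapply(names(cand), function(nm) {
    cm <- curvatureMetrics(cand[[nm]]$linked)
    data.frame(option = nm, accCurv = cm[["accCurv"]],
               avgCurv = cm[["avgCurv"]], sd = sdLe(cand[[nm]]$linked))
  }))
  best <- metrics$option[which.min(metrics$sd)]
  win <- cand[[best]]
  structure(list(gapType = "I", fillPoints = win$fill, option = best,
                 junction = win$j, metrics = metrics, linked = win$linked),
            class = "GapFill")
}

#' @export
print.GapFill <- function(x, ...) {
  cat(sprintf("GapFill (Type %s): option %s, junction %d, %d fill points\n",
              x$gapType, x$option, x$junction,
              if (is.null(x$fillPoints)) 0L else nrow(x$fillPoints)))
  invisible(x)
}

#' Grow a missed edge by Laplace verification PCA
#'
#' Where the edge detector missed the true boundary (Type II gaps, Type B
#' regions), the second derivative of the intensity profile along each ray
#' still responds at the real edge. Candidate points with a one-signed
#' Laplacian response (restricted between the nucleus edge and the first
#' blocking hit) are collected; inside a sliding sampling window, principal
#' component analysis of their covariance gives the local edge direction,
#' and the edge is grown piecewise from the window centroid along the first
#' principal vector until the rays are exhausted.
#'
#' @param image intensity matrix of the slice.
#' @param rays data.frame of the rays spanning the gap (subset of a cast
#'   fan), processed in groups of \code{groupWidth} degrees.
#' @param nucleusMask logical nucleus mask (profiles start outside it).
#' @param blocking the slice's \linkS4class{BlockingResult} (profiles stop
#'   at the first hit of a ray, e.g. a Type B edge).
#' @param window sampling window side in px (default 5).
#' @param groupWidth ray group width in degrees (default 7).
#' @return An \linkS4class{EdgeSegment} with class "A" and the grown chain,
#'   or NULL when no qualifying points exist (caller falls back to
#'   interpolation).
#' @export
laplaceVerifyPca <- function(image, rays, nucleusMask, blocking,
                             window = 5L, groupWidth = 7) {
  if (!nrow(rays)) return(NULL)
  nx <- nrow(image); ny <- ncol(image)
  pts <- NULL
  rays <- rays[order(rays$theta), , drop = FALSE]
  # hits are keyed by row index into the originally cast fan; subsetting a
  # data.frame keeps those indices as rownames
  rayKey <- suppressWarnings(as.integer(rownames(rays)))
  hitD <- rep(Inf, nrow(rays))
  if (nrow(blocking@hits)) {
    for (i in seq_len(nrow(rays))) {
      if (is.na(rayKey[i])) next
      h <- blocking@hits$distance[blocking@hits$ray == rayKey[i]]
      if (length(h)) hitD[i] <- min(h)
    }
  }
  for (i in seq_len(nrow(rays))) {
    o <- c(rays$originX[i], rays$originY[i])
    d <- c(rays$dirX[i], rays$dirY[i])
    s <- seq(0.5, rays$l[i], by = 0.5)
    px <- o[1] + s * d[1]; py <- o[2] + s * d[2]
    ok <- px >= 1 & px <= nx & py >= 1 & py <= ny
    s <- s[ok]; px <- px[ok]; py <- py[ok]
    if (length(s) < 5) next
    prof <- image[cbind(pmin(pmax(round(px), 1), nx),
                        pmin(pmax(round(py), 1), ny))]
    lap <- c(NA, diff(diff(prof)), NA)          # discrete Laplacian along ray
    inNuc <- nucleusMask[cbind(pmin(pmax(round(px), 1), nx),
                               pmin(pmax(round(py), 1), ny))]
    lastNuc <- if (any(inNuc)) max(which(inNuc)) else 0L
    valid <- seq_along(s) > lastNuc & s < hitD[i] & !is.na(lap)
    if (!any(valid)) next
    # one-signed response; take the dominant sign over this ray
    pos <- valid & lap > 0
    neg <- valid & lap < 0
    sel <- if (sum(pos) >= sum(neg)) pos else neg
    # keep the strongest responses only
    if (any(sel)) {
      thr <- stats::quantile(abs(lap[sel]), 0.75)
      sel <- sel & abs(lap) >= thr
      pts <- rbind(pts, cbind(px[sel], py[sel]))
    }
  }
  if (is.null(pts) || nrow(pts) < 2) return(NULL)
  half <- window / 2
  # start at the candidate nearest the first ray
  o1 <- c(rays$originX[1], rays$originY[1])
  d1 <- c(rays$dirX[1], rays$dirY[1])
  side <- abs((pts[, 1] - o1[1]) * d1[2] - (pts[, 2] - o1[2]) * d1[1])
  cur <- pts[which.min(side), ]
  grown <- NULL
  for (iter in seq_len(50L)) {
    inWin <- abs(pts[, 1] - cur[1]) <= half & abs(pts[, 2] - cur[2]) <= half
    if (sum(inWin) < 2) break                    # degenerate window
    P <- pts[inWin, , drop = FALSE]
    ctr <- colMeans(P)
    C <- stats::cov(P)
    v1 <- eigen(C, symmetric = TRUE)$vectors[, 1]
    len <- max(sqrt(rowSums(sweep(P, 2, ctr)^2)))
    if (len < 1e-9) break
    # keep growing away from where we came from
    if (!is.null(grown)) {
      prev <- grown[nrow(grown), ]
      if (sum(v1 * (ctr - prev)) < 0) v1 <- -v1
    }
    newEnd <- ctr + v1 * len
    piece <- rbind(ctr, newEnd)
    grown <- rbind(grown, piece)
    pts <- pts[!inWin, , drop = FALSE]
    if (nrow(pts) < 2) break
    cur <- newEnd
  }
  if (is.null(grown) || nrow(grown) < 2) return(NULL)
  chain <- rasterizeChain(grown)
  if (nrow(chain) < 2) return(NULL)
  EdgeSegment(chain, edgeClass = "A", id = NA_integer_)
}

# turn a continuous polyline into an 8-connected integer pixel chain
rasterizeChain <- function(P) {
  fine <- resampleChain(P, step = 0.5)
  q <- round(fine)
  keep <- c(TRUE, rowSums(abs(diff(q))) > 0)
  q <- q[keep, , drop = FALSE]
  # enforce unit steps by inserting intermediates on rare 2-px jumps
  out <- q[1, , drop = FALSE]
  for (i in 2:nrow(q)) {
    prev <- out[nrow(out), ]
    step <- q[i, ] - prev
    while (max(abs(step)) > 1) {
      prev <- prev + sign(step)
      out <- rbind(out, prev)
      step <- q[i, ] - prev
    }
    if (max(abs(step)) > 0) out <- rbind(out, q[i, ])
  }
  out
}

#' Split a merged (Type C) tail edge between two adjacent cells
#'
#' Auxiliary lines perpendicular to each cell's orientation vector are
#' erected at the shared edge's two endpoints, closing a polygon with the
#' edge; the edge is split at its point of shortest distance to the line
#' joining the auxiliary line ends, and the two halves are assigned to
#' their cells.
#'
#' @param edge a class-C \linkS4class{EdgeSegment}.
#' @param geomA,geomB the two cells' \linkS4class{NucleusGeometry} objects;
#'   the edge's first endpoint is taken to lie on cell A's side.
#' @return List with elements \code{a} and \code{b}: the two half
#'   \linkS4class{EdgeSegment}s (concatenating their points reproduces the
#'   input chain).
#' @export
splitMergedEdge <- function(edge, geomA, geomB) {
  if (edge@edgeClass != "C") stop("splitMergedEdge expects a class-C edge")
  P <- edge@points
  n <- nrow(P)
  A <- P[1, ]
  E <- P[n, ]
  mid <- (geomA@center + geomB@center) / 2
  edgeMid <- P[ceiling(n / 2), ]
  w <- mid - edgeMid
  orient <- function(v) {
    perp <- c(-v[2], v[1])
    if (sum(perp * w) < 0) perp <- -perp
    perp
  }
  hLen <- sqrt(sum((E - A)^2)) / 2
  B <- A + orient(geomA@cellVector) * hLen
  D <- E + orient(geomB@cellVector) * hLen
  dists <- pointLineDistance(P, B, D)
  k <- which.min(dists)                          # smallest index wins ties
  if (k == n) k <- n - 1L
  half1 <- EdgeSegment(P[seq_len(k), , drop = FALSE], edgeClass = "A",
                       side = edge@side, part = "tail", id = edge@id)
  half2 <- EdgeSegment(P[(k + 1):n, , drop = FALSE], edgeClass = "A",
                       side = edge@side, part = "tail", id = edge@id + 10000L)
  list(a = half1, b = half2, splitIndex = k)
}

#' Assemble a closed 2D boundary from retained edges and gap fills
#'
#' Retained segments and fill curves are concatenated in clockwise ray
#' order into one closed loop enclosing the cell center; loops failing
#' simplicity are repaired by dropping the later-arriving crossing points.
#'
#' @param blocking a \linkS4class{BlockingResult}.
#' @param fills list of GapFill objects (and/or grown
#'   \linkS4class{EdgeSegment}s) bridging the gaps.
#' @param geometry the cell's \linkS4class{NucleusGeometry}.
#' @param slice slice index stored on the boundary.
#' @return A \linkS4class{Boundary2D}, or NULL (with a warning) when an
#'   unfillable gap spans more than 90 degrees.
#' @export
closeBoundary <- function(blocking, fills = list(), geometry,
                          slice = NA_integer_) {
  ctr <- geometry@center
  v <- geometry@cellVector
  # unfillable wide gap check
  if (nrow(blocking@gaps)) {
    g <- blocking@gaps
    span <- (g$thetaEnd - g$thetaStart) %% 360
    filled <- length(fills) > 0
    wide <- span > 90 & !filled
    if (any(wide)) {
      warning("unfillable gap spanning > 90 degrees; cell unsegmentable on this slice")
      return(NULL)
    }
  }
  pieces <- list()
  for (id in blocking@retained) {
    s <- blocking@segments[[as.character(id)]]
    if (s@edgeClass == "B") next        # other-cell edges never contribute
    pieces[[length(pieces) + 1]] <- list(P = s@points, src = "edge")
  }
  for (f in fills) {
    if (is.null(f)) next
    if (inherits(f, "GapFill")) {
      if (!is.null(f$fillPoints))
        pieces[[length(pieces) + 1]] <- list(P = f$fillPoints,
                                             src = "interpolated")
    } else if (is(f, "EdgeSegment")) {
      pieces[[length(pieces) + 1]] <- list(P = f@points, src = "pca")
    }
  }
  if (!length(pieces)) {
    warning("no boundary pieces; cell unsegmentable on this slice")
    return(NULL)
  }
  ang <- function(P) vapply(seq_len(nrow(P)), function(i)
    rayAngle(P[i, ], ctr, v), numeric(1))
  # orient every piece clockwise (increasing theta) and order pieces by
  # their median angle
  pieces <- lapply(pieces, function(pc) {
    a <- ang(pc$P)
    if (nrow(pc$P) > 1) {
      d <- diff(a)
      d <- (d + 180) %% 360 - 180
      if (sum(d) < 0) {
        pc$P <- pc$P[rev(seq_len(nrow(pc$P))), , drop = FALSE]
        a <- rev(a)
      }
    }
    pc$a0 <- a[1]
    pc
  })
  pieces <- pieces[order(vapply(pieces, `[[`, numeric(1), "a0"))]
  contour <- do.call(rbind, lapply(pieces, `[[`, "P"))
  prov <- unlist(lapply(pieces, function(pc) rep(pc$src, nrow(pc$P))))
  dup <- c(FALSE, rowSums(abs(diff(contour))) < 1e-9)
  contour <- contour[!dup, , drop = FALSE]
  prov <- prov[!dup]
  # simplicity repair: drop later-arriving crossing points
  for (rep in seq_len(20L)) {
    bad <- findCrossing(contour)
    if (is.null(bad)) break
    drop <- unique(pmin(pmax(bad, 1), nrow(contour)))
    contour <- contour[-drop, , drop = FALSE]
    prov <- prov[-drop]
    if (nrow(contour) < 4) break
  }
  # last-resort repair: collapse to a star-shaped loop around the center
  # (single-valued radius per polar-angle bin is simple by construction)
  if (nrow(contour) >= 3 && chainSelfIntersects(contour)) {
    phi <- atan2(contour[, 2] - ctr[2], contour[, 1] - ctr[1])
    r <- sqrt((contour[, 1] - ctr[1])^2 + (contour[, 2] - ctr[2])^2)
    bin <- floor(rad2deg(phi) / 2)
    rb <- tapply(r, bin, stats::median)
    pb <- tapply(prov, bin, `[`, 1)
    phiB <- (as.numeric(names(rb)) + 0.5) * 2
    ord <- order(phiB)
    contour <- cbind(ctr[1] + rb[ord] * cos(deg2rad(phiB[ord])),
                     ctr[2] + rb[ord] * sin(deg2rad(phiB[ord])))
    prov <- as.character(pb[ord])
  }
  if (nrow(contour) < 3) {
    warning("degenerate boundary")
    return(NULL)
  }
  b <- Boundary2D(contour, prov, slice)
  if (!pointInPolygon(ctr, b@contour))
    warning("assembled boundary does not enclose the cell center")
  b
}

#' Subpixel boundary refinement by mid-level crossing
#'
#' Moves each boundary point along its local outward normal to the crossing
#' of the local mid-intensity level (mean of the local minimum and maximum
#' within a small probe window). This removes the sub-pixel outward bias of
#' gradient-maximum edge localization on asymmetric profiles (e.g., where
#' the dimmer nucleus region sits just inside the cell boundary).
#'
#' @param boundary a \linkS4class{Boundary2D}.
#' @param image the slice intensity matrix.
#' @param center cell center (used to orient normals outward).
#' @param probe half-length of the probe in px (default 2.5).
#' @param maxShift maximal point displacement in px (default 1.5).
#' @return The refined \linkS4class{Boundary2D}.
#' @export
refineBoundary <- function(boundary, image, center, probe = 2.5,
                           maxShift = 1.5) {
  P <- boundary@contour
  nx <- nrow(image); ny <- ncol(image)
  ks <- seq(-probe, probe, by = 0.5)
  out <- P
  np <- nrow(P)
  for (i in seq_len(np)) {
    i1 <- if (i == 1) np else i - 1
    i2 <- if (i == np) 1 else i + 1
    tg <- P[i2, ] - P[i1, ]
    nt <- sqrt(sum(tg^2))
    u <- if (nt > 1e-6) c(-tg[2], tg[1]) / nt else P[i, ] - center
    nu <- sqrt(sum(u^2))
    if (nu < 1e-6) next
    u <- u / nu
    if (sum(u * (P[i, ] - center)) < 0) u <- -u   # outward
    sx <- P[i, 1] + ks * u[1]
    sy <- P[i, 2] + ks * u[2]
    ok <- sx >= 1 & sx <= nx & sy >= 1 & sy <= ny
    if (sum(ok) < 4) next
    v <- image[cbind(pmin(pmax(round(sx[ok]), 1), nx),
                     pmin(pmax(round(sy[ok]), 1), ny))]
    lmin <- min(v); lmax <- max(v)
    if (lmax - lmin < 0.2 * max(image)) next
    level <- (lmin + lmax) / 2
    d <- v - level
    cross <- which(d[-length(d)] * d[-1] <= 0)
    if (!length(cross)) next
    kk <- ks[ok]
    k0 <- kk[cross] - d[cross] * (kk[cross + 1] - kk[cross]) /
      (d[cross + 1] - d[cross])
    shift <- k0[which.min(abs(k0))]
    if (!is.finite(shift) || abs(shift) > maxShift) next
    out[i, ] <- P[i, ] + shift * u
  }
  # sub-pixel shifts can introduce micro-crossings; repair, and fall back
  # to the unrefined contour if the loop cannot be kept simple
  prov <- boundary@provenance
  for (rep in seq_len(10L)) {
    bad <- findCrossing(out)
    if (is.null(bad)) break
    drop <- unique(pmin(pmax(bad, 1), nrow(out)))
    out <- out[-drop, , drop = FALSE]
    prov <- prov[-drop]
    if (nrow(out) < 4) break
  }
  if (nrow(out) < 3 || chainSelfIntersects(out)) return(boundary)
  boundary@contour <- out
  boundary@provenance <- prov
  boundary
}

# indices of the later segment's endpoints at the first self-crossing of
# the closed loop, or NULL when simple
findCrossing <- function(P) {
  n <- nrow(P)
  if (n < 4) return(NULL)
  idx <- cbind(seq_len(n), c(2:n, 1))
  A <- P[idx[, 1], , drop = FALSE]
  B <- P[idx[, 2], , drop = FALSE]
  for (i in seq_len(n - 2)) {
    js <- (i + 2):n
    if (i == 1) js <- js[js != n]
    if (!length(js)) next
    d <- B[i, ] - A[i, ]
    ex <- B[js, 1] - A[js, 1]; ey <- B[js, 2] - A[js, 2]
    den <- d[1] * ey - d[2] * ex
    wx <- A[js, 1] - A[i, 1]; wy <- A[js, 2] - A[i, 2]
    t <- (wx * ey - wy * ex) / den
    u <- (wx * d[2] - wy * d[1]) / den
    hit <- which(is.finite(t) & is.finite(u) &
                   t > 1e-9 & t < 1 - 1e-9 & u > 1e-9 & u < 1 - 1e-9)
    if (length(hit)) {
      j <- js[hit[1]]
      return(c(j, j %% n + 1))
    }
  }
  NULL
}
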