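# Per-slice preprocessing: coherence filtering, Canny edge detection, edge
# cleanup into single-pixel chains, nucleus geometry, and A/B/C edge
# classification.

#' Coherence-enhancing anisotropic diffusion
#'
#' Edge-preserving smoothing that diffuses strongly along the local
#' coherence (edge) direction and weakly across it, driven by the structure
#' tensor. Output intensities are kept inside the input range (diffusion
#' maximum principle).
#'
#' @param image 2D numeric matrix.
#' @param iterations diffusion steps (default 5).
#' @param dt time step (default 0.15).
#' @param alpha residual isotropic diffusivity (default 0.03).
#' @param rho structure-tensor integration scale in px (default 3).
#' @return Filtered matrix, same dimensions.
#' @export
coherenceFilter <- function(image, iterations = 5L, dt = 0.15, alpha = 0.03,
                            rho = 3) {
  stopifnot(length(dim(image)) == 2, all(dim(image) > 0))
  I <- image
  lo <- min(I); hi <- max(I)
  if (hi - lo < 1e-12) return(image)   # constant image: no gradients
  for (iter in seq_len(iterations)) {
    Is <- EBImage::gblur(I, sigma = 1)
    Ix <- (shiftMat(Is, 1, 0, 0) - shiftMat(Is, -1, 0, 0)) / 2
    Iy <- (shiftMat(Is, 0, 1, 0) - shiftMat(Is, 0, -1, 0)) / 2
    J11 <- EBImage::gblur(Ix * Ix, sigma = rho)
    J12 <- EBImage::gblur(Ix * Iy, sigma = rho)
    J22 <- EBImage::gblur(Iy * Iy, sigma = rho)
    tmp <- sqrt((J11 - J22)^2 + 4 * J12^2)
    coh <- tmp^2                       # (mu1 - mu2)^2
    mcoh <- mean(coh)
    if (mcoh < 1e-24) mcoh <- 1e-24
    c2 <- alpha + (1 - alpha) * exp(-1 / (coh / mcoh + 1e-12))
    c1 <- alpha
    # gradient-direction angle of the structure tensor
    phi <- 0.5 * atan2(2 * J12, J11 - J22)
    cs <- cos(phi); sn <- sin(phi)
    a <- c1 * cs * cs + c2 * sn * sn
    b <- (c1 - c2) * cs * sn
    d <- c1 * sn * sn + c2 * cs * cs
    gx <- (shiftMat(I, 1, 0, 0) - shiftMat(I, -1, 0, 0)) / 2
    gy <- (shiftMat(I, 0, 1, 0) - shiftMat(I, 0, -1, 0)) / 2
    F1 <- a * gx + b * gy
    F2 <- b * gx + d * gy
    div <- (shiftMat(F1, 1, 0, 0) - shiftMat(F1, -1, 0, 0)) / 2 +
      (shiftMat(F2, 0, 1, 0) - shiftMat(F2, 0, -1, 0)) / 2
    I <- I + dt * div
    I[I < lo] <- lo
    I[I > hi] <- hi
  }
  I
}

#' Canny edge detection
#'
#' Gaussian smoothing, Sobel gradients, non-maximum suppression and
#' hysteresis thresholding; the result is thinned to single-pixel width.
#'
#' @param image 2D numeric matrix (typically coherence-filtered).
#' @param sigma Gaussian sigma in px (default 1.5).
#' @param low,high hysteresis thresholds as fractions of the maximal
#'   gradient magnitude (defaults 0.1 and 0.2).
#' @return Logical edge map, same dimensions.
#' @export
detectEdges <- function(image, sigma = 1.5, low = 0.1, high = 0.2) {
  stopifnot(high > low)
  if (max(image) - min(image) < 1e-12)
    return(matrix(FALSE, nrow(image), ncol(image)))
  Is <- EBImage::gblur(image, sigma = sigma)
  gx <- shiftMat(Is, 1, -1) + 2 * shiftMat(Is, 1, 0) + shiftMat(Is, 1, 1) -
    shiftMat(Is, -1, -1) - 2 * shiftMat(Is, -1, 0) - shiftMat(Is, -1, 1)
  gy <- shiftMat(Is, -1, 1) + 2 * shiftMat(Is, 0, 1) + shiftMat(Is, 1, 1) -
    shiftMat(Is, -1, -1) - 2 * shiftMat(Is, 0, -1) - shiftMat(Is, 1, -1)
  mag <- sqrt(gx^2 + gy^2)
  mx <- max(mag)
  if (mx < 1e-12) return(matrix(FALSE, nrow(image), ncol(image)))
  # non-maximum suppression along the quantized gradient direction
  ang <- atan2(gy, gx)
  sector <- (round(ang / (pi / 4)) %% 4)   # 0:E-W 1:NE-SW 2:N-S 3:NW-SE
  n1 <- matrix(0, nrow(image), ncol(image)); n2 <- n1
  pick <- function(dx, dy) list(shiftMat(mag, dx, dy, 0), shiftMat(mag, -dx, -dy, 0))
  for (s in 0:3) {
    o <- switch(as.character(s), "0" = c(1, 0), "1" = c(1, 1),
                "2" = c(0, 1), "3" = c(-1, 1))
    nb <- pick(o[1], o[2])
    sel <- sector == s
    n1[sel] <- nb[[1]][sel]
    n2[sel] <- nb[[2]][sel]
  }
  nms <- mag >= n1 & mag >= n2 & mag > 0
  strong <- nms & mag >= high * mx
  weak <- nms & mag >= low * mx
  if (!any(strong)) return(matrix(FALSE, nrow(image), ncol(image)))
  # hysteresis: keep weak components connected to a strong pixel; bwlabel is
  # 4-connected, so label a one-pixel dilation to bridge diagonal steps
  grown <- EBImage::dilate(weak * 1, EBImage::makeBrush(3, "box"))
  lab <- EBImage::bwlabel(grown)
  keepLabels <- unique(lab[strong])
  edges <- weak & lab %in% keepLabels
  dim(edges) <- dim(image)
  thinBinary(edges)
}

#' Clean an edge map into single-pixel chains
#'
#' Prunes short spurs, removes bifurcation (junction) pixels so that every
#' chain has exactly two endpoints, and traces ordered pixel chains. When a
#' center is supplied, segments are ordered by their clockwise ray angle.
#'
#' @param edgeMap logical matrix.
#' @param minSpur spurs up to this length (px) are pruned (default 3).
#' @param center optional (x, y) cell center used for ordering.
#' @param cellVector optional unit vector for the ray-angle origin
#'   (defaults to +Y when only a center is given).
#' @return List of \linkS4class{EdgeSegment} objects with sequential ids.
#' @export
cleanEdges <- function(edgeMap, minSpur = 3L, center = NULL,
                       cellVector = c(0, 1)) {
  m <- edgeMap != 0
  if (!any(m)) return(list())
  m <- thinBinary(m)
  # spur pruning: walk back from each endpoint; if a junction is reached
  # within minSpur steps, delete the walked pixels (junction kept)
  for (pass in 1:2) {
    nb <- neighborCount8(m)
    branch <- branchPointMask(m)
    endpoints <- which(m & nb == 1)
    if (!length(endpoints)) break
    nx <- nrow(m)
    for (e in endpoints) {
      if (!m[e]) next
      path <- integer(0)
      cur <- e
      hitJunction <- FALSE
      for (step in seq_len(minSpur)) {
        path <- c(path, cur)
        cx <- (cur - 1L) %% nx + 1L; cy <- (cur - 1L) %/% nx + 1L
        nxt <- NA_integer_
        for (dd in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1), c(1, 1),
                        c(1, -1), c(-1, 1), c(-1, -1))) {
          qx <- cx + dd[1]; qy <- cy + dd[2]
          if (qx < 1 || qx > nx || qy < 1 || qy > ncol(m)) next
          q <- (qy - 1L) * nx + qx
          if (m[q] && !(q %in% path)) {
            if (branch[q]) { hitJunction <- TRUE } else { nxt <- q }
            if (hitJunction) break
          }
        }
        if (hitJunction || is.na(nxt)) break
        cur <- nxt
      }
      if (hitJunction) m[path] <- FALSE
    }
  }
  # bifurcation removal: delete remaining junction pixels
  branch <- branchPointMask(m)
  junctions <- which(branch, arr.ind = TRUE)
  m[branch] <- FALSE
  # residual pixels with > 2 chain neighbors (rare diagonal double links)
  m[neighborCount8(m) > 3 & m] <- FALSE
  chains <- traceChains(m)
  # arms of a removed junction can stay diagonally linked; split chains at
  # diagonal steps that skirt a deleted junction pixel
  if (nrow(junctions)) {
    nearJunction <- function(p)
      any(abs(junctions[, 1] - p[1]) <= 1 & abs(junctions[, 2] - p[2]) <= 1)
    split1 <- function(P) {
      if (nrow(P) < 2) return(list(P))
      d <- abs(diff(P))
      cut <- which(d[, 1] == 1 & d[, 2] == 1)
      cut <- cut[vapply(cut, function(i)
        nearJunction(P[i, ]) && nearJunction(P[i + 1, ]), logical(1))]
      if (!length(cut)) return(list(P))
      bounds <- c(0, cut, nrow(P))
      lapply(seq_len(length(bounds) - 1), function(k)
        P[(bounds[k] + 1):bounds[k + 1], , drop = FALSE])
    }
    chains <- unlist(lapply(chains, split1), recursive = FALSE)
  }
  chains <- chains[vapply(chains, nrow, 1L) >= 2L]
  if (!length(chains)) return(list())
  if (!is.null(center)) {
    mids <- t(vapply(chains, function(p) p[ceiling(nrow(p) / 2), ], numeric(2)))
    ang <- vapply(seq_len(nrow(mids)), function(i)
      rayAngle(mids[i, ], center, cellVector), numeric(1))
    chains <- chains[order(ang)]
  }
  lapply(seq_along(chains), function(i) EdgeSegment(chains[[i]], id = i))
}

#' Extract nucleus geometry from a binary mask
#'
#' The nucleus is thinned to a skeleton which is pruned to its longest
#' endpoint-to-endpoint path; the mask centroid becomes the cell center c0
#' and the cell vector points from the center to the long-axis endpoint.
#' Near-circular masks fall back to the image-moment principal axis (with
#' \code{lowAnisotropy = TRUE}).
#'
#' @param mask logical matrix containing exactly one connected nucleus.
#' @return A \linkS4class{NucleusGeometry}.
#' @export
extractNucleusGeometry <- function(mask) {
  m <- mask != 0
  if (!any(m)) stop("empty nucleus mask")
  lab <- EBImage::bwlabel(m * 1)
  if (max(lab) > 1) stop("mask has multiple components; label first")
  idx <- which(m, arr.ind = TRUE)
  ctr <- colMeans(idx)
  cc <- sweep(idx, 2, ctr)
  C <- crossprod(cc) / nrow(cc) + diag(2) / 12
  ev <- eigen(C, symmetric = TRUE)
  momentAxis <- ev$vectors[, 1]
  anisotropy <- sqrt(ev$values[1] / max(ev$values[2], 1e-12))
  skel <- thinBinary(m)
  path <- longestSkeletonPath(skel)
  low <- anisotropy < 1.2 || is.null(path) || nrow(path) < 3
  if (low) {
    if (anisotropy < 1.2)
      warning("low-anisotropy nucleus: using image-moment principal axis")
    half <- sqrt(ev$values[1]) * 2
    e1 <- ctr + momentAxis * half
    e2 <- ctr - momentAxis * half
    path <- rbind(e1, ctr, e2)
  }
  endpoints <- path[c(1, nrow(path)), , drop = FALSE]
  # cell vector: toward the endpoint farther along the principal axis
  proj <- (endpoints[, 1] - ctr[1]) * momentAxis[1] +
    (endpoints[, 2] - ctr[2]) * momentAxis[2]
  tip <- endpoints[which.max(proj), ]
  v <- tip - ctr
  nv <- sqrt(sum(v^2))
  if (nv < 1e-9) { v <- momentAxis; nv <- 1 }
  new("NucleusGeometry", center = as.numeric(ctr), skeleton = path,
      endpoints = endpoints, cellVector = as.numeric(v / nv),
      lowAnisotropy = low)
}

# longest endpoint-to-endpoint path of a skeleton (tree assumption):
# double-BFS over the 8-connected pixel graph
longestSkeletonPath <- function(skel) {
  idx <- which(skel)
  if (length(idx) < 2) return(NULL)
  nx <- nrow(skel)
  bfs <- function(start) {
    parent <- new.env(hash = TRUE)
    assign(as.character(start), 0L, envir = parent)
    frontier <- start
    last <- start
    while (length(frontier)) {
      nextF <- integer(0)
      for (cur in frontier) {
        cx <- (cur - 1L) %% nx + 1L; cy <- (cur - 1L) %/% nx + 1L
        for (dd in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1), c(1, 1),
                        c(1, -1), c(-1, 1), c(-1, -1))) {
          qx <- cx + dd[1]; qy <- cy + dd[2]
          if (qx < 1 || qx > nx || qy < 1 || qy > ncol(skel)) next
          q <- (qy - 1L) * nx + qx
          if (skel[q] && !exists(as.character(q), envir = parent)) {
            assign(as.character(q), cur, envir = parent)
            nextF <- c(nextF, q)
          }
        }
      }
      if (length(nextF)) last <- nextF[length(nextF)]
      frontier <- nextF
    }
    list(last = last, parent = parent)
  }
  b1 <- bfs(idx[1])
  b2 <- bfs(b1$last)
  # walk back from farthest node
  path <- integer(0)
  cur <- b2$last
  while (cur != 0L) {
    path <- c(path, cur)
    cur <- get(as.character(cur), envir = b2$parent)
  }
  cbind((path - 1L) %% nx + 1L, (path - 1L) %/% nx + 1L)
}

#' Classify an edge segment as real (A), false (B) or touching (C)
#'
#' A: the mean intensity gradient along the segment points toward the cell
#' interior (the nucleus-centered side has higher intensity) and the
#' second-derivative sign just outside the segment is consistent with an
#' outer intensity falloff. B: the gradient points away from the current
#' cell (edge of another cell). C: gradient consistent with the current
#' cell, but the far side of the segment is also foreground (a shared edge
#' with an adjacent cell).
#'
#' @param segment an \linkS4class{EdgeSegment}.
#' @param image the same-slice (filtered) intensity matrix.
#' @param geometry the current cell's \linkS4class{NucleusGeometry}.
#' @param fgThreshold intensity above which a pixel counts as cell
#'   foreground; default Otsu's threshold of the slice.
#' @return The segment with \code{edgeClass} and \code{side} filled in.
#' @export
classifyEdge <- function(segment, image, geometry, fgThreshold = NULL) {
  p <- segment@points
  if (nrow(p) < 3) {
    segment@edgeClass <- "unknown"
    return(segment)
  }
  if (is.null(fgThreshold)) {
    rng <- range(image)
    fgThreshold <- if (rng[2] > rng[1])
      otsuThreshold(image) else rng[2]
  }
  Is <- EBImage::gblur(image, sigma = 1)
  nx <- nrow(image); ny <- ncol(image)
  cl <- function(x, lim) pmin(pmax(round(x), 1), lim)
  at <- function(M, q) M[cbind(cl(q[, 1], nx), cl(q[, 2], ny))]
  gx <- (shiftMat(Is, 1, 0) - shiftMat(Is, -1, 0)) / 2
  gy <- (shiftMat(Is, 0, 1) - shiftMat(Is, 0, -1)) / 2
  ctr <- geometry@center
  ux <- ctr[1] - p[, 1]; uy <- ctr[2] - p[, 2]
  nrm <- sqrt(ux^2 + uy^2); nrm[nrm < 1e-9] <- 1
  ux <- ux / nrm; uy <- uy / nrm
  dp <- mean(at(gx, p) * ux + at(gy, p) * uy)
  # side label from the sign of cross(cellVector, point - center)
  v <- geometry@cellVector
  crossSign <- mean(v[1] * (p[, 2] - ctr[2]) - v[2] * (p[, 1] - ctr[1]))
  segment@side <- if (crossSign > 0) "left" else "right"
  # second derivative (3-px Laplacian of the smoothed intensity) sampled
  # just outside the segment: an outer falloff is convex there (lap >= 0);
  # a strongly negative response marks the concave inside of another cell
  lap <- shiftMat(Is, 1, 0) + shiftMat(Is, -1, 0) + shiftMat(Is, 0, 1) +
    shiftMat(Is, 0, -1) - 4 * Is
  outLap <- mean(at(lap, cbind(p[, 1] - 1.5 * ux, p[, 2] - 1.5 * uy)))
  lapScale <- stats::sd(lap) + 1e-12
  if (dp < 0 || outLap < -0.5 * lapScale) {
    segment@edgeClass <- "B"
    return(segment)
  }
  # far (outward) side probe, 3 px beyond the edge
  far <- cbind(p[, 1] - 3 * ux, p[, 2] - 3 * uy)
  farFg <- mean(at(image, far) > fgThreshold)
  segment@edgeClass <- if (farFg > 0.5) "C" else "A"
  segment
}

# scalar Otsu threshold over all values of a numeric array
otsuThreshold <- function(image, breaks = 256L) {
  v <- as.numeric(image)
  rng <- range(v)
  if (rng[2] - rng[1] < 1e-12) return(rng[2])
  h <- tabulate(pmin(as.integer((v - rng[1]) / (rng[2] - rng[1]) *
                                  breaks) + 1L, breaks), breaks)
  p <- h / sum(h)
  mids <- rng[1] + (seq_len(breaks) - 0.5) / breaks * (rng[2] - rng[1])
  w1 <- cumsum(p)
  mu1 <- cumsum(p * mids)
  muT <- mu1[breaks]
  between <- (muT * w1 - mu1)^2 / (w1 * (1 - w1))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

#' Remove inner edges connected to the nucleus region
#'
#' Edges inside the cell body (lower-intensity nucleus region) are reachable
#' from the nucleus by region growing over edge pixels; those chains are
#' dropped.
#'
#' @param segments list of \linkS4class{EdgeSegment} objects.
#' @param nucleusMask logical matrix of the nucleus region.
#' @return The surviving segments.
#' @export
removeInnerEdges <- function(segments, nucleusMask) {
  if (!length(segments)) return(segments)
  m <- matrix(FALSE, nrow(nucleusMask), ncol(nucleusMask))
  for (s in segments) m[s@points] <- TRUE
  # 8-connected region growing over edge pixels, seeded at the edge pixels
  # lying inside the nucleus region (the trunk boundary runs close to the
  # nucleus, so seeding from a dilated mask would leak onto it)
  box <- EBImage::makeBrush(3, "box")
  reach <- m & (nucleusMask != 0)
  if (any(reach)) {
    repeat {
      grown <- (EBImage::dilate(reach * 1, box) > 0) & m
      if (sum(grown) == sum(reach)) break
      reach <- grown
    }
  }
  keep <- vapply(segments, function(s) !any(reach[s@points]), logical(1))
  segments[keep]
}
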