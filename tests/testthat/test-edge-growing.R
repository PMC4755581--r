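test_that("discrete curvature matches its analytic limits", {
  straight <- cbind(1:10, rep(5, 10))
  cm <- curvatureMetrics(straight)
  expect_equal(unname(cm), c(0, 0))

  th <- seq(0, 2 * pi, length.out = 400)
  circ <- cbind(20 * cos(th), 20 * sin(th))
  cmc <- curvatureMetrics(circ)
  expect_equal(cmc[["accCurv"]], 2 * pi, tolerance = 0.01)
  expect_equal(cmc[["avgCurv"]], 1 / 20, tolerance = 0.01)

  arc <- circ[1:100, ]
  expect_equal(curvatureMetrics(arc), curvatureMetrics(arc[100:1, ]))
  expect_error(curvatureMetrics(straight[1:2, ]), "3 points")
})

test_that("bilateral spline interpolation bridges gaps minimally", {
  # collinear chains: the bridge is straight and all options agree
  E1 <- EdgeSegment(cbind(10:20, 30), id = 1L)
  E2 <- EdgeSegment(cbind(28:38, 30), id = 2L)
  gf <- bilateralSplineInterpolate(E1, E2, center = c(24, 40))
  expect_s3_class(gf, "GapFill")
  expect_lt(curvatureMetrics(gf$linked)[["accCurv"]], 0.05)
  expect_lt(max(abs(gf$fillPoints[, 2] - 30)), 0.01)
  # the chosen option's SD is minimal among the four
  expect_equal(min(gf$metrics$sd), gf$metrics$sd[gf$metrics$option == gf$option])

  # gap wider than maxGapFactor * lc0 is rejected
  E3 <- EdgeSegment(cbind(150:160, 30), id = 3L)
  expect_error(bilateralSplineInterpolate(E1, E3, center = c(80, 40)),
               "gap width")
})

test_that("the junction index equals the brute-force curvature scan", {
  set.seed(21)
  for (rep in 1:4) {
    n1 <- sample(6:12, 1); n2 <- sample(6:12, 1)
    P1 <- chainFromPoints(round(cbind(cumsum(c(10, runif(n1, 0.5, 1.5))),
                                      30 + cumsum(c(0, rnorm(n1, 0, 0.8))))))
    P2 <- chainFromPoints(round(cbind(cumsum(c(30, runif(n2, 0.5, 1.5))),
                                      32 + cumsum(c(0, rnorm(n2, 0, 0.8))))))
    E1 <- EdgeSegment(P1, id = 1L)
    E2 <- EdgeSegment(P2, id = 2L)
    gf <- bilateralSplineInterpolate(E1, E2, center = c(25, 45))
    if (startsWith(gf$option, "12")) {
      metric <- sub("12.", "", gf$option, fixed = TRUE)
      expect_equal(gf$junction, oracleJunction(P1, P2, metric))
    } else {
      metric <- sub("21.", "", gf$option, fixed = TRUE)
      expect_equal(gf$junction,
                   oracleJunction(P2[nrow(P2):1, ], P1[nrow(P1):1, ], metric))
    }
  }
})

test_that("Laplace-verified PCA recovers a straight missed edge", {
  # vertical step edge at x = 60; rays fan across it
  img <- matrix(0, 100, 100)
  img[1:60, ] <- 1
  img <- EBImage::gblur(img, 1.5)
  g <- simpleGeometry(center = c(40, 50), vector = c(0, 1))
  rays <- castRayFan(g, angularStep = 1)
  sector <- rays$theta >= 60 & rays$theta <= 120 & !rays$extended
  blocking <- blockEdges(rays[FALSE, ], list())
  grown <- laplaceVerifyPca(img, rays[sector, ], matrix(FALSE, 100, 100),
                            blocking)
  expect_s4_class(grown, "EdgeSegment")
  P <- segmentPoints(grown)
  expect_lt(sqrt(mean((P[, 1] - 60)^2)), 2)

  # no qualifying points -> failure reported as NULL
  flat <- matrix(0.5, 100, 100)
  expect_null(laplaceVerifyPca(flat, rays[sector, ],
                               matrix(FALSE, 100, 100), blocking))
})

test_that("merged Type C edges split at the point nearest line BD", {
  # symmetric edge between two mirrored cells
  P <- chainFromPoints(cbind(30:70, 50))
  edge <- EdgeSegment(P, edgeClass = "C", id = 1L)
  gA <- simpleGeometry(center = c(35, 40), vector = c(0, 1))
  gB <- simpleGeometry(center = c(65, 40), vector = c(0, 1))
  sp <- splitMergedEdge(edge, gA, gB)
  n <- nrow(P)
  expect_equal(sp$splitIndex, ceiling(n / 2), tolerance = 1)
  # concatenation reproduces the input chain exactly
  expect_equal(rbind(segmentPoints(sp$a), segmentPoints(sp$b)), P)
  # brute-force shortest-distance oracle
  A <- P[1, ]; E <- P[n, ]
  mid <- (gA@center + gB@center) / 2
  w <- mid - P[ceiling(n / 2), ]
  orient <- function(v) { p <- c(-v[2], v[1]); if (sum(p * w) < 0) -p else p }
  h <- sqrt(sum((E - A)^2)) / 2
  B <- A + orient(gA@cellVector) * h
  D <- E + orient(gB@cellVector) * h
  dd <- vapply(seq_len(n), function(i) {
    v <- D - B
    abs((P[i, 1] - B[1]) * v[2] - (P[i, 2] - B[2]) * v[1]) / sqrt(sum(v^2))
  }, numeric(1))
  expect_equal(sp$splitIndex, min(which.min(dd), n - 1L))
  expect_error(splitMergedEdge(EdgeSegment(P, edgeClass = "A", id = 1L),
                               gA, gB), "class-C")
})

test_that("boundaries close cleanly around the cell center", {
  g <- simpleGeometry(center = c(50, 50))
  rays <- castRayFan(g)
  # full contour: boundary is the retained contour
  full <- circleSegment(r = 18, id = 1L)
  bl <- blockEdges(rays, list(full))
  b <- closeBoundary(bl, list(), g, 1L)
  expect_s4_class(b, "Boundary2D")
  expect_true(vsmcseg:::pointInPolygon(c(50, 50), boundaryContour(b)))
  aFull <- abs(vsmcseg:::polygonSignedArea(boundaryContour(b)))
  expect_equal(aFull, pi * 18^2, tolerance = 0.05 * pi * 18^2)

  # contour with a ~10 degree gap plus its interpolated fill
  th <- seq(0.1, 2 * pi - 0.1, length.out = 110)
  P <- chainFromPoints(round(cbind(50 + 18 * cos(th), 50 + 18 * sin(th))))
  seg <- EdgeSegment(P, edgeClass = "A", id = 1L)
  bl2 <- blockEdges(rays, list(seg))
  or <- vsmcseg:::.orientForGap(seg, seg, g)
  fill <- bilateralSplineInterpolate(or$E1, or$E2, g@center, g@cellVector)
  b2 <- closeBoundary(bl2, list(fill), g, 1L)
  a2 <- abs(vsmcseg:::polygonSignedArea(boundaryContour(b2)))
  expect_lt(abs(a2 - pi * 18^2) / (pi * 18^2), 0.02)

  # winding is normalized regardless of input order
  expect_gt(vsmcseg:::polygonSignedArea(boundaryContour(b)), 0)
  expect_gt(vsmcseg:::polygonSignedArea(boundaryContour(b2)), 0)
})
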