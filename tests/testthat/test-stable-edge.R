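test_that("point overlap follows the window-normalized distance", {
  seed <- cbind(10:20, 5)
  expect_equal(pointOverlap(c(15, 5), seed, w = 5), 1)
  expect_equal(pointOverlap(c(15, 10), seed, w = 5), 0)
  expect_equal(pointOverlap(c(15, 7), seed, w = 5), 0.6)
  # translation invariance
  expect_equal(pointOverlap(c(115, 207), seed + cbind(rep(100, 11), 200), 5),
               pointOverlap(c(15, 7), seed, 5))
  expect_error(pointOverlap(c(0, 0), seed[0, , drop = FALSE], 5), "empty")
})

test_that("edge stability averages overlaps across neighboring slices", {
  edge <- EdgeSegment(cbind(10:40, 20), id = 1L)
  seeds <- list(cbind(10:40, 20), cbind(10:40, 20), cbind(10:40, 20))
  st <- edgeStability(edge, seeds, w = 5)
  expect_equal(st$S, 1)
  expect_true(st$stable)

  far <- lapply(seeds, function(s) s + cbind(rep(0, 31), 8))
  stFar <- edgeStability(edge, far, w = 5)
  expect_true(all(stFar$perPoint <= 0))
  expect_false(stFar$stable)

  set.seed(4)
  jit <- lapply(1:3, function(i)
    cbind(10:40, 20) + matrix(sample(-1:1, 62, TRUE), ncol = 2))
  stJ <- edgeStability(edge, jit, w = 5, center = c(25, 60),
                       cellVector = c(1, 0))
  expect_gte(stJ$S, 0.8)
  expect_true(stJ$stable)
  # brute-force Eq recomputation
  expect_equal(stJ$perPoint, oracleStability(segmentPoints(edge), jit, 5))
  expect_error(edgeStability(edge, list(), 5), "M >= 1")
})

test_that("stability never rises when points move away from the seed", {
  edge <- cbind(10:30, 15)
  seeds <- list(cbind(10:30, 15))
  base <- edgeStability(EdgeSegment(edge, id = 1L), seeds, w = 5)
  for (shift in c(1, 2, 4)) {
    moved <- edge
    moved[5, 2] <- moved[5, 2] + shift
    st <- edgeStability(EdgeSegment(chainFromPoints(moved), id = 1L),
                        seeds, w = 5)
    expect_lte(mean(st$perPoint), mean(base$perPoint) + 1e-12)
  }
})

test_that("boundary propagation accepts stable edges and requests fallback", {
  th <- seq(0, 2 * pi, length.out = 90)[-1]
  contour <- cbind(50 + 15 * cos(th), 50 + 15 * sin(th))
  prev <- Boundary2D(contour, slice = 1L)
  g <- simpleGeometry(center = c(50, 50))
  cfg <- pipelineConfig()

  same <- list(circleSegment(r = 15, id = 1L))
  pr <- propagateBoundary(prev, same, g, cfg)
  expect_equal(length(pr$accepted), 1L)
  expect_false(pr$fallback)

  # drifting boundary: 1 px/slice stays within the cap
  drift <- list(circleSegment(center = c(51, 50), r = 15, id = 1L))
  pr2 <- propagateBoundary(prev, drift, g, cfg)
  expect_equal(length(pr2$accepted), 1L)

  # far-away segments: nothing stable, fallback requested
  off <- list(circleSegment(center = c(90, 90), r = 6, id = 1L))
  pr3 <- propagateBoundary(prev, off, g, cfg)
  expect_true(pr3$fallback)
})

test_that("a drifting cell is tracked across slices within 2 px RMS", {
  # stack of slices whose true circle drifts 1 px per slice
  cfg <- pipelineConfig()
  prev <- Boundary2D(cbind(40 + 12 * cos(seq(0, 2 * pi, length.out = 80)[-1]),
                           40 + 12 * sin(seq(0, 2 * pi, length.out = 80)[-1])),
                     slice = 1L)
  rmse <- c()
  for (k in 1:10) {
    ctr <- c(40 + k, 40)
    g <- simpleGeometry(center = ctr)
    segs <- list(circleSegment(center = ctr, r = 12, id = 1L))
    pr <- propagateBoundary(prev, segs, g, cfg)
    expect_false(pr$fallback)
    bl <- blockEdges(castRayFan(g), pr$accepted)
    b <- closeBoundary(bl, list(), g, as.integer(k + 1))
    P <- boundaryContour(b)
    d <- sqrt((P[, 1] - ctr[1])^2 + (P[, 2] - ctr[2])^2) - 12
    rmse <- c(rmse, sqrt(mean(d^2)))
    prev <- b
  }
  expect_lt(max(rmse), 2)
})
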