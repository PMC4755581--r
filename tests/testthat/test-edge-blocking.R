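test_that("ray angles follow the cell-vector convention", {
  expect_equal(rayAngle(c(0, 5), c(0, 0), c(0, 1)), 0)
  expect_equal(rayAngle(c(0, -5), c(0, 0), c(0, 1)), 180)
  expect_equal(rayAngle(c(1, 0), c(0, 0), c(0, 1)), 90)
  # independent check through rotation: a point at clockwise angle a from
  # the cell vector must report theta = a
  for (a in c(10, 37, 123, 305)) {
    ar <- a * pi / 180
    p <- 7 * c(sin(ar), cos(ar))          # +Y rotated clockwise by a
    expect_equal(rayAngle(p, c(0, 0), c(0, 1)), a, tolerance = 1e-9)
  }
  expect_error(rayAngle(c(0, 0), c(0, 0), c(0, 1)), "coincides")
})

test_that("emitting-length bound is clamped into its min/max range", {
  expect_equal(rayLengthBound(90), 30)
  expect_equal(rayLengthBound(0), 180)
  expect_equal(rayLengthBound(180), 5)                     # clamped
  expect_equal(rayLengthBound(180, clamp = FALSE), -120)   # literal form
  expect_error(rayLengthBound(0, lc0 = -1), "positive")
})

test_that("ray fans cover the circle with symmetric tail extensions", {
  g <- simpleGeometry(center = c(50, 50), vector = c(0, 1), len = 15)
  rays <- castRayFan(g, angularStep = 1)
  expect_equal(sum(!rays$extended), 360L)
  ext <- rays[rays$extended, ]
  expect_gt(nrow(ext), 0)
  # mirror symmetry of the two tail sectors
  fwd <- sort(ext$theta[ext$theta <= 90 | ext$theta >= 270])
  bwd <- sort(ext$theta[ext$theta > 90 & ext$theta < 270])
  expect_equal(length(fwd), length(bwd))
  expect_error(castRayFan(g, angularStep = 0), "positive")
})

test_that("a distant tail edge is reachable only by extended rays", {
  g <- simpleGeometry(center = c(50, 50), vector = c(0, 1), len = 20)
  tailEdge <- EdgeSegment(chainFromPoints(cbind(c(45, 55), 90)), id = 1L,
                          edgeClass = "A")
  rays <- castRayFan(g, angularStep = 1, lc0 = 6, lc1 = 4)  # center max 30
  bl <- blockEdges(rays, list(tailEdge))
  hits <- bl@hits[bl@hits$withinBound, ]
  expect_true(all(rays$extended[hits$ray]))
  expect_gt(nrow(hits), 0)
})

test_that("blocking keeps first intersections and types gaps", {
  g <- simpleGeometry(center = c(50, 50))
  inner <- circleSegment(r = 12, id = 1L)
  outer <- circleSegment(r = 25, id = 2L)
  rays <- castRayFan(g)
  one <- blockEdges(rays, list(inner))
  expect_equal(one@retained, 1L)
  expect_equal(nrow(one@gaps), 0L)
  both <- blockEdges(rays, list(inner, outer))
  expect_equal(both@retained, 1L)       # outer fully blocked

  # a gap opens where the contour is missing, Type I between A edges
  th <- seq(0, 2 * pi, length.out = 120)
  keep <- th > 0.6 & th < 2 * pi - 0.6
  P <- chainFromPoints(round(cbind(50 + 15 * cos(th[keep]),
                                   50 + 15 * sin(th[keep]))))
  seg <- EdgeSegment(P, edgeClass = "A", id = 1L)
  bl <- blockEdges(rays, list(seg))
  expect_gt(nrow(bl@gaps), 0)
  expect_true(all(bl@gaps$type == "I"))

  empty <- blockEdges(rays, list())
  expect_equal(length(empty@retained), 0L)
  expect_equal(nrow(empty@gaps), 1L)
})

test_that("blocking matches the exhaustive intersection oracle", {
  set.seed(3)
  g <- simpleGeometry(center = c(50, 50))
  rays <- castRayFan(g, angularStep = 2)
  for (rep in 1:3) {
    segs <- lapply(1:50, function(i) {
      p0 <- runif(2, 20, 80)
      dir <- runif(2, -1, 1)
      n <- sample(3:8, 1)
      P <- chainFromPoints(round(rbind(p0, p0 + dir / max(abs(dir)) * n)))
      EdgeSegment(P, id = i)
    })
    bl <- blockEdges(rays, segs)
    expect_equal(bl@retained, oracleRetained(rays, segs))
    # order independence
    perm <- sample(seq_along(segs))
    bl2 <- blockEdges(rays, segs[perm])
    expect_equal(sort(bl2@retained), sort(bl@retained))
    # monotonicity: dropping a blocked segment leaves retention unchanged
    blocked <- setdiff(vapply(segs, function(s) s@id, 1L), bl@retained)
    blockedHit <- intersect(blocked, unique(bl@hits$segment))
    if (length(blockedHit)) {
      keep <- segs[vapply(segs, function(s) s@id != blockedHit[1],
                          logical(1))]
      bl3 <- blockEdges(rays, keep)
      expect_equal(bl3@retained, bl@retained)
    }
  }
})
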