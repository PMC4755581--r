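test_that("coherence filtering smooths along bands and preserves range", {
  const <- matrix(0.5, 40, 40)
  expect_identical(coherenceFilter(const), const)

  set.seed(1)
  img <- bandImage(noise = 0.05)
  out <- coherenceFilter(img)
  expect_gte(min(out), min(img))
  expect_lte(max(out), max(img))
  # along-band variance inside the band strictly decreases
  inside <- 10:70
  vIn <- mean(apply(img[inside, 39:42], 2, var))
  vOut <- mean(apply(out[inside, 39:42], 2, var))
  expect_lt(vOut, vIn)
  # cross-band gradient magnitude at the edge drops by < 20%
  gradAt <- function(m) mean(abs(m[inside, 36] - m[inside, 33]))
  expect_gt(gradAt(out), 0.8 * gradAt(img))
})

test_that("Canny detection localizes a disk boundary and ignores flats", {
  img <- diskImage(r = 30)
  edges <- detectEdges(img)
  idx <- which(edges, arr.ind = TRUE)
  d <- sqrt((idx[, 1] - 50)^2 + (idx[, 2] - 50)^2)
  expect_true(all(abs(d - 30) <= 1.5))
  # the ring is closed: edge pixels cover all polar angles
  ang <- floor(((atan2(idx[, 2] - 50, idx[, 1] - 50) * 180 / pi) %% 360) / 10)
  expect_equal(length(unique(ang)), 36)

  expect_equal(sum(detectEdges(matrix(1, 50, 50))), 0)
})

test_that("edge recall on a synthetic fusiform cell exceeds 90%", {
  st <- oneCellStack()
  tr <- stackTruth(st)[[1]]
  z <- as.integer(round(tr$center[3] / spacing(st)[3]))
  img <- coherenceFilter(st@cellChannel[, , z])
  edges <- detectEdges(img)
  contour <- tr$contours[[as.character(z)]]
  idx <- which(edges, arr.ind = TRUE)
  hit <- vapply(seq_len(nrow(contour)), function(i)
    min(sqrt((idx[, 1] - contour[i, 1])^2 +
               (idx[, 2] - contour[i, 2])^2)) <= 2, logical(1))
  expect_gt(mean(hit), 0.9)
})

test_that("edge cleanup removes bifurcations and spurs", {
  m <- matrix(FALSE, 40, 40)
  m[10:30, 20] <- TRUE                  # main chain
  m[20, 21:28] <- TRUE                  # orthogonal branch -> Y shape
  segs <- cleanEdges(m, minSpur = 3L)
  expect_equal(length(segs), 3L)

  m2 <- matrix(FALSE, 40, 40)
  m2[5:35, 20] <- TRUE
  m2[21:23, 21] <- FALSE
  m2[20, 21:23] <- TRUE                 # 3-px spur
  segs2 <- cleanEdges(m2, minSpur = 3L)
  expect_equal(length(segs2), 1L)
  expect_gte(nrow(segmentPoints(segs2[[1]])), 29)

  # random maps: every chain has exactly two endpoints and no bifurcations
  set.seed(11)
  for (rep in 1:5) {
    mr <- matrix(runif(1600) < 0.12, 40, 40)
    for (s in cleanEdges(mr)) {
      P <- segmentPoints(s)
      sub <- matrix(FALSE, 40, 40)
      sub[P] <- TRUE
      nb <- vsmcseg:::neighborCount8(sub)
      expect_true(all(nb[P] <= 2))
      # open chains have two endpoint pixels; traced cycles have none
      expect_true(sum(nb[P] == 1) %in% c(0L, 2L))
    }
  }
})

test_that("nucleus geometry follows the mask's principal axis", {
  g <- extractNucleusGeometry(ellipseMask(angleDeg = 25))
  ang <- atan2(g@cellVector[1], g@cellVector[2]) * 180 / pi
  ang <- ((ang + 90) %% 180) - 90
  expect_lt(abs(ang - 25), 3)
  expect_false(g@lowAnisotropy)
  # moment-oracle agreement within 5 degrees on elongated masks
  expect_lt(abs(ang - oracleMomentAngle(ellipseMask(angleDeg = 25))), 5)

  circ <- ellipseMask(a = 10, b = 10)
  expect_warning(gc1 <- extractNucleusGeometry(circ), "anisotropy")
  expect_true(gc1@lowAnisotropy)

  expect_error(extractNucleusGeometry(matrix(FALSE, 10, 10)), "empty")
  two <- matrix(FALSE, 30, 30)
  two[5:8, 5:8] <- TRUE; two[20:23, 20:23] <- TRUE
  expect_error(extractNucleusGeometry(two), "components")
})

test_that("edge classification separates real, false and touching edges", {
  # one bright band centered at y = 40, cell center inside
  img <- bandImage(nx = 80, ny = 80, y1 = 34, y2 = 46)
  g <- simpleGeometry(center = c(40, 40), vector = c(1, 0))
  edgeLow <- EdgeSegment(cbind(20:60, 33), id = 1L)   # band edge, low y side
  edgeHigh <- EdgeSegment(cbind(20:60, 47), id = 2L)
  clLow <- classifyEdge(edgeLow, img, g)
  clHigh <- classifyEdge(edgeHigh, img, g)
  expect_equal(edgeClass(clLow), "A")
  expect_equal(edgeClass(clHigh), "A")
  expect_true(clLow@side != clHigh@side)

  # a second band beyond the first: its near edge's gradient points into
  # that band, i.e. away from the current center -> B
  img2 <- pmax(img, bandImage(nx = 80, ny = 80, y1 = 54, y2 = 66))
  near <- EdgeSegment(cbind(20:60, 53), id = 3L)
  expect_equal(edgeClass(classifyEdge(near, img2, g)), "B")

  # two abutting bands: the shared edge has foreground on both sides -> C
  img3 <- pmax(bandImage(nx = 80, ny = 80, y1 = 30, y2 = 46),
               bandImage(nx = 80, ny = 80, y1 = 47, y2 = 62))
  shared <- EdgeSegment(cbind(20:60, 46), id = 4L)
  expect_equal(edgeClass(classifyEdge(shared, img3, g)), "C")

  # short segments are unknown
  expect_equal(edgeClass(classifyEdge(EdgeSegment(cbind(5:6, 5), id = 9L),
                                      img, g)), "unknown")
})

test_that("classification is side-consistent under mirroring", {
  img <- bandImage(nx = 80, ny = 80, y1 = 34, y2 = 46)
  g <- simpleGeometry(center = c(40, 40), vector = c(1, 0))
  e1 <- classifyEdge(EdgeSegment(cbind(20:60, 33), id = 1L), img, g)
  # mirror x -> 81 - x: image is x-symmetric; vector flips
  gM <- simpleGeometry(center = c(41, 40), vector = c(-1, 0))
  e1m <- classifyEdge(EdgeSegment(cbind(rev(81 - (20:60)), 33), id = 1L),
                      img, gM)
  expect_equal(edgeClass(e1), edgeClass(e1m))
  expect_true(e1@side != e1m@side)
})

test_that("inner edges connected to the nucleus are removed", {
  nuc <- ellipseMask(nx = 60, ny = 60, a = 8, b = 5, cx = 30, cy = 30)
  touching <- EdgeSegment(cbind(30, 25:40), id = 1L)      # crosses the mask
  outside <- EdgeSegment(cbind(50, 20:40), id = 2L)
  kept <- removeInnerEdges(list(touching, outside), nuc)
  expect_equal(length(kept), 1L)
  expect_equal(kept[[1]]@id, 2L)
  # a chain of touching segments bridging outward is removed entirely
  bridge1 <- EdgeSegment(cbind(30, 33:42), id = 3L)
  bridge2 <- EdgeSegment(cbind(30, 43:52), id = 4L)
  kept2 <- removeInnerEdges(list(bridge1, bridge2, outside), nuc)
  expect_equal(vapply(kept2, function(s) s@id, 1L), 2L)
})
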