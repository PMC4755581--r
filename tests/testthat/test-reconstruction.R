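test_that("stacked boundaries form solid volumes with correct geometry", {
  th <- seq(0, 2 * pi, length.out = 160)[-1]
  circ <- cbind(35 + 16 * cos(th), 35 + 16 * sin(th))
  bs <- lapply(1:10, function(z) Boundary2D(circ, slice = z))
  vol <- stackBoundaries(bs, zStep = 1, xyPixel = 1, gridShape = c(70, 70, 12),
                         close = FALSE)
  expect_lt(abs(sum(voxels(vol)) - pi * 256 * 10) / (pi * 2560), 0.03)

  slab <- stackBoundaries(bs[1], zStep = 1, xyPixel = 1,
                          gridShape = c(60, 60, 3))
  zs <- apply(voxels(slab), 3, sum)
  expect_equal(sum(zs > 0), 1L)

  bad <- Boundary2D(cbind(c(0, 10, 10, 0), c(0, 10, 0, 10)) + 5, slice = 1L)
  expect_error(stackBoundaries(list(bad), gridShape = c(30, 30, 2)),
               "non-simple")
})

test_that("phantom volumes survive the 2D-to-3D round trip", {
  ph <- renderPhantom(PhantomSpec(c(20, 6, 6), tiltDeg = 20))
  bs <- volumeSliceBoundaries(ph$volume)
  rec <- stackBoundaries(bs, zStep = 1, xyPixel = 1,
                         gridShape = dim(voxels(ph$volume)))
  a <- voxels(ph$volume); b <- voxels(rec)
  dice <- 2 * sum(a & b) / (sum(a) + sum(b))
  expect_gte(dice, 0.95)
  # tilt from the reconstruction tracks the direct voxel measurement
  expect_lt(abs(as.numeric(tiltAngleOfVolume(rec)) -
                  as.numeric(tiltAngleOfVolume(ph$volume))), 1)
})

test_that("surface extraction yields closed, accurate meshes", {
  single <- array(FALSE, c(5, 5, 5)); single[3, 3, 3] <- TRUE
  m1 <- extractSurface(BinaryVolume(single))
  expect_gt(meshArea(m1), 0)
  expect_true(vsmcseg:::isWatertight(m1))

  sph <- voxelizeMesh(makeEllipsoidMesh(PhantomSpec(c(10, 10, 10))),
                      c(27, 27, 27))
  m <- extractSurface(sph)
  expect_lt(abs(meshArea(m) - 4 * pi * 100) / (4 * pi * 100), 0.10)
  expect_true(vsmcseg:::isWatertight(m))
  # Euler characteristic of a sphere
  V <- nrow(meshVertices(m)); F <- nrow(meshFaces(m))
  E <- F * 3 / 2
  expect_equal(V - E + F, 2)
  expect_error(extractSurface(BinaryVolume(array(FALSE, c(3, 3, 3)))),
               "empty")
})

test_that("Laplacian smoothing relaxes staircases without changing topology", {
  sph <- voxelizeMesh(makeEllipsoidMesh(PhantomSpec(c(10, 10, 10))),
                      c(27, 27, 27))
  m <- extractSurface(sph, smoothSigma = 0)   # raw marching surface
  expect_identical(laplacianSmooth(m, iterations = 0L)@vertices, m@vertices)

  sm <- laplacianSmooth(m, iterations = 5L, strength = 0.3)
  expect_equal(dim(sm@vertices), dim(m@vertices))
  expect_identical(sm@faces, m@faces)
  ctr <- colMeans(m@vertices)
  dev <- function(mm) {
    r <- sqrt(rowSums(sweep(mm@vertices, 2, ctr)^2))
    max(abs(r - 10))
  }
  expect_lt(dev(sm), dev(m))
  # modest shrinkage at default settings
  expect_gt(meshVolume(laplacianSmooth(m, 5L, 0.3)),
            0.9 * meshVolume(m))
})

test_that("z-majority volume filtering removes single-slice jitter", {
  v <- array(FALSE, c(10, 10, 7))
  v[3:7, 3:7, 2:6] <- TRUE
  v[9, 9, 4] <- TRUE                 # isolated single-slice voxel
  out <- voxels(smoothVolume(BinaryVolume(v)))
  expect_false(out[9, 9, 4])
  expect_true(all(out[3:7, 3:7, 3:5]))
})
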