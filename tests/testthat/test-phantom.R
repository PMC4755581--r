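test_that("ellipsoid mesh is watertight with the requested long axis", {
  m0 <- makeEllipsoidMesh(PhantomSpec(c(35, 10, 10)))
  expect_true(vsmcseg:::isWatertight(m0))
  # tilt 0, in-plane 0: long axis along Y
  ax <- eigen(cov(meshVertices(m0)), symmetric = TRUE)$vectors[, 1]
  expect_lt(abs(abs(ax[2]) - 1), 1e-8)

  m30 <- makeEllipsoidMesh(PhantomSpec(c(35, 10, 10), tiltDeg = 30))
  ax30 <- eigen(cov(meshVertices(m30)), symmetric = TRUE)$vectors[, 1]
  outAngle <- asin(abs(ax30[3])) * 180 / pi
  expect_equal(outAngle, 30, tolerance = 1e-6)

  # both phantom sizes (70 and 40 px long axes) are supported
  for (axes in list(c(35, 10, 10), c(20, 6, 6))) {
    m <- makeEllipsoidMesh(PhantomSpec(axes))
    ext <- apply(meshVertices(m), 2, function(v) diff(range(v)))
    expect_equal(ext[2], 2 * axes[1], tolerance = 1e-6)
  }
  expect_error(PhantomSpec(c(10, 10, -1)), "positive")
})

test_that("end-rotation deformation is harmonic with fixed-end boundary", {
  m <- makeEllipsoidMesh(PhantomSpec(c(35, 10, 10)), nTheta = 32L, nPhi = 16L)
  expect_identical(deformEllipsoid(m, 0)@vertices, m@vertices)

  d25 <- deformEllipsoid(m, 25)
  disp <- d25@vertices - m@vertices
  # fixed-end vertices unmoved
  proj <- meshVertices(m)[, 2]
  fixedEnd <- proj < -0.75 * max(abs(proj))
  expect_lt(max(abs(disp[fixedEnd, ])), 1e-9)
  # interior displacements equal the mean of their neighbors (Laplace)
  f <- meshFaces(m)
  e <- unique(rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)],
                    f[, 2:1], f[, 3:2], f[, c(1, 3)]))
  freeEnd <- proj > 0.75 * max(abs(proj))
  interior <- which(!(fixedEnd | freeEnd))
  resid <- 0
  for (v in interior[seq(1, length(interior), by = 7)]) {
    nb <- e[e[, 1] == v, 2]
    resid <- max(resid, max(abs(colMeans(disp[nb, , drop = FALSE]) - disp[v, ])))
  }
  expect_lt(resid, 1e-6)
  # continuity: displacement shrinks with the deformation angle
  d2 <- deformEllipsoid(m, 2)
  expect_lt(max(abs(d2@vertices - m@vertices)),
            max(abs(disp)) / 4)
})

test_that("voxelization fills the solid interior accurately", {
  sph <- makeEllipsoidMesh(PhantomSpec(c(10, 10, 10)))
  vol <- voxelizeMesh(sph, c(27, 27, 27))
  expect_lt(abs(sum(voxels(vol)) - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000),
            0.05)
  # axis-aligned ellipsoid: bounding box 2a x 2b x 2c within 1 voxel per side
  el <- makeEllipsoidMesh(PhantomSpec(c(20, 8, 6)))
  ev <- voxelizeMesh(el, c(45, 45, 45))
  idx <- which(voxels(ev), arr.ind = TRUE)
  ext <- apply(idx, 2, function(v) diff(range(v)) + 1)
  expect_true(all(abs(ext - c(16, 40, 12)) <= 2))
  # volume error shrinks as the object doubles
  sph2 <- makeEllipsoidMesh(PhantomSpec(c(5, 5, 5)))
  v5 <- sum(voxels(voxelizeMesh(sph2, c(15, 15, 15))))
  err5 <- abs(v5 - 4 / 3 * pi * 125) / (4 / 3 * pi * 125)
  err10 <- abs(sum(voxels(vol)) - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000)
  expect_lt(err10, err5)
  expect_error(voxelizeMesh(sph, c(10, 10, 10)), "grid")
})

test_that("voxelized tilted phantom recovers its predefined angle", {
  ph <- renderPhantom(PhantomSpec(c(35, 10, 10), tiltDeg = 20))
  a <- as.numeric(tiltAngleOfVolume(ph$volume))
  expect_lt(abs(a - 20) / 20, 0.10)
})

test_that("synthetic stacks are deterministic with consistent truth", {
  s1 <- makeCellStack(2, noiseSd = 0.02, seed = 42,
                      gridShape = c(160, 160, 48))
  s2 <- makeCellStack(2, noiseSd = 0.02, seed = 42,
                      gridShape = c(160, 160, 48))
  expect_identical(s1@cellChannel, s2@cellChannel)
  expect_identical(s1@nucleusChannel, s2@nucleusChannel)
  # nuclei lie inside their cells: nucleus foreground is cell foreground
  nuc <- s1@nucleusChannel > 0.5
  expect_gt(mean(s1@cellChannel[nuc] > 0.2), 0.98)
  # every truth cell overlaps the cell channel foreground
  for (tr in stackTruth(s1)) {
    cv <- round(tr$center / spacing(s1))
    expect_gt(s1@cellChannel[cv[1], cv[2], cv[3]], 0.3)
  }
  expect_error(makeCellStack(2, gridShape = c(40, 40, 10), seed = 1),
               "infeasible")
})

test_that("a forced crossing produces a Type II gap on some slice", {
  st <- makeCellStack(2, noiseSd = 0.02, overlapFraction = 1, seed = 9,
                      gridShape = c(220, 220, 56))
  tru <- stackTruth(st)
  # scan slices around both cells' z centers
  zmid <- as.integer(round(mean(c(tru[[1]]$center[3], tru[[2]]$center[3])) /
                             spacing(st)[3]))
  foundII <- FALSE
  for (z in zmid + c(-3L, 0L, 3L)) {
  img <- coherenceFilter(st@cellChannel[, , z], iterations = 3)
  edges <- detectEdges(img)
  for (ci in 1:2) {
    ctr <- tru[[ci]]$center[1:2] / spacing(st)[1:2]
    beta <- tru[[ci]]$beta
    g <- simpleGeometry(ctr, c(sin(beta * pi / 180), cos(beta * pi / 180)))
    segs <- cleanEdges(edges, center = g@center, cellVector = g@cellVector)
    segs <- lapply(segs, classifyEdge, image = img, geometry = g)
    keep <- vapply(segs, function(s) edgeClass(s) %in% c("A", "B", "C"),
                   logical(1))
    segs <- segs[keep]
    if (!length(segs)) next
    for (i in seq_along(segs)) segs[[i]]@id <- i
    bl <- blockEdges(castRayFan(g), segs)
    if (nrow(bl@gaps) && any(bl@gaps$type == "II")) foundII <- TRUE
  }
  }
  expect_true(foundII)
})
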