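test_that("projection ellipse fitting recovers axes and orientation", {
  box <- array(FALSE, c(40, 40, 4))
  box[11:30, 19:22, 2:3] <- TRUE
  reg <- projectAndFit(BinaryVolume(box))
  expect_lt(abs(abs(reg$majorAxis[1]) - 1), 1e-9)
  expect_false(reg$indeterminate)

  for (ang in c(-40, 10, 25)) {
    m <- ellipseMask(angleDeg = ang)
    v <- array(FALSE, c(80, 80, 3)); v[, , 2] <- m
    reg2 <- projectAndFit(BinaryVolume(v))
    got <- atan2(reg2$majorAxis[1], reg2$majorAxis[2]) * 180 / pi
    got <- ((got + 90) %% 180) - 90
    expect_lt(abs(got - ang), 1)
  }

  sph <- voxelizeMesh(makeEllipsoidMesh(PhantomSpec(c(10, 10, 10))),
                      c(25, 25, 25))
  regS <- projectAndFit(sph)
  expect_true(regS$indeterminate)
  expect_warning(inPlaneAngle(regS), "indeterminate")
})

test_that("in-plane angle uses the circumferential-zero convention", {
  mkreg <- function(ang) {
    v <- array(FALSE, c(80, 80, 3))
    v[, , 2] <- ellipseMask(angleDeg = ang)
    projectAndFit(BinaryVolume(v))
  }
  expect_lt(abs(inPlaneAngle(mkreg(0))), 0.5)
  expect_equal(inPlaneAngle(mkreg(-90)), -90, tolerance = 0.5)
  expect_equal(inPlaneAngle(mkreg(25)), 25, tolerance = 1)
})

test_that("length, width and thickness scale with voxel spacing", {
  box <- array(FALSE, c(70, 12, 10))
  box[4:63, 4:8, 3:8] <- TRUE
  lwt <- lengthWidthThickness(BinaryVolume(box, c(1, 1, 1)))
  expect_equal(unname(lwt), c(60, 5, 6))
  lwt2 <- lengthWidthThickness(BinaryVolume(box, c(2, 2, 2)))
  expect_equal(unname(lwt2), c(120, 10, 12))
  expect_error(lengthWidthThickness(BinaryVolume(box, c(1, 2, 1))),
               "anisotropic")
})

test_that("the tilt estimator matches PCA geometry and its oracle", {
  flat <- renderPhantom(PhantomSpec(c(20, 6, 6)))
  expect_lt(as.numeric(tiltAngleOfVolume(flat$volume)), 1)

  ph <- renderPhantom(PhantomSpec(c(35, 10, 10), tiltDeg = 30))
  a <- as.numeric(tiltAngleOfVolume(ph$volume))
  expect_lt(abs(a - 30) / 30, 0.10)

  # eigenvector equals an independent power iteration
  xyz <- vsmcseg:::surfaceVoxelCoords(voxels(ph$volume))
  C <- cov(xyz)
  v1 <- attr(tiltAngle(xyz), "axis")
  vp <- oraclePowerIteration(C)
  expect_gt(abs(sum(v1 * vp)), 1 - 1e-6)

  # invariance under rotation about Z
  thz <- 40 * pi / 180
  R <- matrix(c(cos(thz), sin(thz), 0, -sin(thz), cos(thz), 0, 0, 0, 1), 3, 3)
  aR <- as.numeric(tiltAngle(xyz %*% t(R)))
  expect_lt(abs(aR - as.numeric(tiltAngle(xyz))), 0.5)

  # degenerate isotropic cloud is flagged
  sph <- renderPhantom(PhantomSpec(c(10, 10, 10)))
  expect_warning(tiltAngleOfVolume(sph$volume), "indeterminate")
  expect_error(tiltAngle(cbind(1:3, 1:3, 1:3)[1:3, ]), "4 points")
})

test_that("orientation mixture fitting recovers the two modes", {
  betas <- sampleInPlaneAngles(5000, seed = 2)
  fit <- fitOrientationMixture(betas, seed = 2)
  expect_true(fit$converged)
  expect_lt(abs(fit$means[1] - (-19.4)), 1)
  expect_lt(abs(fit$means[2] - 10.9), 1)
  # order invariance
  fit2 <- fitOrientationMixture(rev(betas), seed = 2)
  expect_equal(fit$means, fit2$means, tolerance = 1e-2)
  # degenerate single value collapses to one component
  fitD <- fitOrientationMixture(rep(12, 50))
  expect_true(fitD$degenerate)
  expect_error(fitOrientationMixture(1:5), "at least 20")
})

test_that("population summaries match direct recomputation", {
  df <- data.frame(L = c(60, 65, 70), W = c(4, 5, 6), T = c(6, 6, 7),
                   slenderness = c(15, 13, 11.7), beta = c(-20, 11, 9),
                   alpha = c(5, 8, 2))
  s <- summarizePopulation(df)
  expect_equal(s$mean[s$parameter == "L"], mean(df$L))
  expect_equal(s$sd[s$parameter == "W"], sd(df$W))
  one <- summarizePopulation(df[1, ])
  expect_equal(one$sd, rep(0, 6))
  expect_equal(one$mean[one$parameter == "L"], 60)

  expect_equal(round(relativeDifference(75.3, 63.1), 1), 19.3)
})
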