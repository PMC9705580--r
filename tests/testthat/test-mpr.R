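# Centerline resampling, MPR reconstruction and intensity normalization.

test_that("centerline resampling yields exact 0.5 mm steps", {
  # straight 10 mm polyline: 21 points
  cl <- resampleCenterline(cbind(0, 0, c(0, 4, 10)))
  expect_equal(nrow(clPoints(cl)), 21L)
  d <- diff(clPoints(cl)[, 3])
  expect_lt(max(abs(d - 0.5)), 1e-9)

  # an already 0.5 mm-spaced input is returned unchanged
  pts <- cbind(0, 0, seq(0, 8, by = 0.5))
  cl2 <- resampleCenterline(pts)
  expect_lt(max(abs(clPoints(cl2) - pts)), 1e-9)

  # circular arc: chord spacing exactly 0.5 mm, points on the circle
  R <- 20
  th <- seq(0, pi / 3, length.out = 400)
  arc <- cbind(R * cos(th), R * sin(th), 0)
  cl3 <- resampleCenterline(arc)
  p <- clPoints(cl3)
  chord <- sqrt(rowSums((p[-1, ] - p[-nrow(p), ])^2))
  expect_lt(max(abs(chord - 0.5)), 1e-6)
  expect_lt(max(abs(sqrt(p[, 1]^2 + p[, 2]^2) - R)), 1e-3)
  # analytic count: chords of 0.5 on a radius-20 circle subtend
  # 2*asin(0.25/20), so the arc holds floor(arclength_angle/step) chords
  expect_equal(nrow(p),
               floor((pi / 3) / (2 * asin(0.25 / R))) + 1)

  expect_error(resampleCenterline(cbind(0, 0, c(0, 0.4))), "< 1 mm")
})

test_that("trilinear sampling agrees with the 8-neighbour oracle at 1000 points", {
  set.seed(8)
  vol <- ImageVolume(array(rnorm(30 * 25 * 20), c(30, 25, 20)),
                     c(0.4, 0.5, 0.6), origin = c(1, 2, 3))
  pts <- cbind(runif(1000, 1.1, 1 + 28 * 0.4),
               runif(1000, 2.1, 2 + 23 * 0.5),
               runif(1000, 3.1, 3 + 18 * 0.6))
  got <- trilinearSample(vol, pts)$values
  ref <- vapply(seq_len(1000), function(i) trilinearOracle(vol, pts[i, ]),
                numeric(1))
  expect_lt(max(abs(got - ref)), 1e-9)
})

test_that("a straight axial tube reconstructs with its centre at pixel (64, 64)", {
  vox <- 0.3
  nx <- 60; nz <- 50
  cx <- (nx - 1) * vox / 2
  xs <- (0:(nx - 1)) * vox
  d2 <- outer((xs - cx)^2, (xs - cx)^2, "+")
  vol <- array(50, c(nx, nx, nz))
  for (k in 1:nz) vol[, , k][d2 <= 1.2^2] <- 400
  iv <- ImageVolume(vol, rep(vox, 3))
  cl <- resampleCenterline(cbind(cx, cx, c(3, 11)))
  mpr <- reconstructMPR(iv, cl, maxFillFraction = 1)
  expect_equal(nSlices(mpr), 17L)
  mid <- mprData(mpr)[, , 9]
  expect_equal(mid[64, 64], 400)          # centreline pixel inside the lumen
  expect_equal(mid[5, 5], 50)             # far corner is background
  # radial symmetry: the lumen disc is centred on (64, 64)
  expect_equal(mid[64 + 10, 64], mid[64 - 10, 64], tolerance = 1e-9)

  # constant volume reconstructs to a constant MPR
  cvol <- ImageVolume(array(7, c(32, 32, 32)), rep(0.6, 3))
  ccl <- resampleCenterline(cbind(9.3, 9.3, c(5, 13)))
  cmpr <- reconstructMPR(cvol, ccl, maxFillFraction = 1)
  expect_lt(max(abs(mprData(cmpr) - 7)), 1e-9)
})

test_that("frames are orthonormal and rotate by less than 10 degrees per slice", {
  set.seed(13)
  ph <- generatePhantom(phantomConfig(arteryLengthMM = 30, seed = 13))
  mpr <- reconstructMPR(ph$volume, ph$centerline, maxFillFraction = 0.2)
  n <- mpr@normals
  ang <- acos(pmin(1, rowSums(n[-1, ] * n[-nrow(n), ])))
  expect_lt(max(ang) * 180 / pi, 10)
  # orthonormality is a class invariant; spot-check anyway
  expect_lt(max(abs(rowSums(mpr@tangents * mpr@normals))), 1e-9)
})

test_that("rigid translation of volume and centerline leaves the MPR unchanged", {
  set.seed(14)
  vol <- array(rnorm(40 * 40 * 40, 100, 50), c(40, 40, 40))
  iv1 <- ImageVolume(vol, rep(0.4, 3), origin = c(0, 0, 0))
  iv2 <- ImageVolume(vol, rep(0.4, 3), origin = c(3.2, -1.7, 5.9))
  raw <- cbind(7 + 0.3 * sin(seq(0, 2, length.out = 40)), 7.5,
               seq(4, 11, length.out = 40))
  cl1 <- resampleCenterline(raw)
  cl2 <- resampleCenterline(sweep(raw, 2, c(3.2, -1.7, 5.9), "+"))
  m1 <- reconstructMPR(iv1, cl1, maxFillFraction = 1)
  m2 <- reconstructMPR(iv2, cl2, maxFillFraction = 1)
  expect_lt(max(abs(mprData(m1) - mprData(m2))), 1e-6)
})

test_that("out-of-volume samples are filled and heavy truncation is rejected", {
  vol <- ImageVolume(array(100, c(20, 20, 30)), rep(0.4, 3))
  # centerline hugging the volume edge: much of the 12.7 mm plane is outside
  cl <- resampleCenterline(cbind(1, 1, c(2, 9)))
  expect_error(reconstructMPR(vol, cl), "rejected")
  mpr <- reconstructMPR(vol, cl, maxFillFraction = 1)
  expect_gt(mpr@fillFraction, 0.05)
  expect_true(any(mprData(mpr) == -1024))
})

test_that("degenerate tangents from repeated points are rejected", {
  pts <- matrix(c(5, 5, 2, 5, 5, 2, 5, 5, 3), 3, 3, byrow = TRUE)
  expect_error(coroflow:::.rmFrames(pts), "degenerate tangent")
  # the class invariant already forbids such centerlines
  expect_error(new("ArteryCenterline", points = pts,
                   labels = rep("LAD", 3), nsucc = rep(1L, 3),
                   spacing = 0.5), "spacing")
})

test_that("intensity statistics pool over the corpus and are not re-fitted", {
  set.seed(15)
  mk <- function(mu) new("MPRVolume",
    data = array(rnorm(127 * 127 * 2, mu, 30), c(127, 127, 2)),
    inplaneSpacing = 0.1, sliceSpacing = 0.5, centers = matrix(0, 2, 3),
    tangents = matrix(rep(c(0, 0, 1), each = 2), 2, 3),
    normals = matrix(rep(c(1, 0, 0), each = 2), 2, 3),
    binormals = matrix(rep(c(0, 1, 0), each = 2), 2, 3), fillFraction = 0)
  corpusA <- list(mk(100), mk(300))
  st <- fitIntensityStats(corpusA)
  normed <- lapply(corpusA, applyIntensityNorm, stats = st)
  all <- unlist(lapply(normed, mprData))
  expect_lt(abs(mean(all)), 1e-6)
  expect_lt(abs(sqrt(mean((all - mean(all))^2)) - 1), 1e-6)

  # stats applied to a different corpus do not re-centre it
  corpusB <- list(mk(700))
  b <- mprData(applyIntensityNorm(corpusB[[1]], st))
  expect_gt(abs(mean(b)), 1)

  const <- mk(0); const@data[] <- 5
  expect_error(fitIntensityStats(list(const)), "zero intensity variance")
})
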