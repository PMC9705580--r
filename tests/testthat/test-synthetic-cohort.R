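# Phantom generation, reference characteristics and the toy FFR model.

test_that("an unobstructed tube has constant analytic lumen area", {
  ph <- generatePhantom(phantomConfig(arteryLengthMM = 15, seed = 2))
  gt <- ph$groundTruth
  expect_lt(max(abs(lumenArea(gt) - pi * 1.4^2)), 1e-9)
  expect_true(is.na(lesionLocation(gt)))
  expect_gte(trueFFR(gt), 0.97)
  expect_equal(attenuation(gt), rep(400, length(lumenArea(gt))))
})

test_that("a 60% area stenosis reaches 0.4 of the baseline area at its centre", {
  cfg <- phantomConfig(arteryLengthMM = 30, baselineRadiusMM = 1.4,
                       stenosisSpec = list(c(15, 10, 0.6)), seed = 3)
  gt <- generatePhantom(cfg)$groundTruth
  expect_equal(min(lumenArea(gt)), 0.4 * pi * 1.4^2, tolerance = 1e-9)
  expect_equal(lesionLocation(gt), which.min(lumenArea(gt)))
  # the centre lies at 15 mm = slice 31 (1-based, 0.5 mm spacing)
  expect_equal(lesionLocation(gt), 31L)
})

test_that("phantom generation is bit-identical under a fixed seed", {
  cfg <- phantomConfig(arteryLengthMM = 15,
                       stenosisSpec = list(c(7.5, 6, 0.5)),
                       calciumSpec = list(c(7.5, 4, 0.3)), seed = 11)
  a <- generatePhantom(cfg)
  b <- generatePhantom(cfg)
  expect_identical(volumeData(a$volume), volumeData(b$volume))
  expect_identical(volumeData(a$lumenMask), volumeData(b$lumenMask))
  expect_identical(treeNodes(a$tree), treeNodes(b$tree))
})

test_that("a stenosis overlapping the artery end is rejected", {
  cfg <- phantomConfig(arteryLengthMM = 20,
                       stenosisSpec = list(c(19, 6, 0.5)))
  expect_error(generatePhantom(cfg), "overlaps the artery end")
})

test_that("branched phantoms carry a side branch and a bifurcation node", {
  ph <- generatePhantom(phantomConfig(arteryLengthMM = 25, nArteries = 2L,
                                      seed = 5))
  nd <- treeNodes(ph$tree)
  expect_true(any(nd$label == "side-branch"))
  nchild <- table(nd$parent)
  expect_true(any(nchild >= 2))
})

test_that("reference characteristics follow the pixel-summation definition", {
  # hand-built MPR stacks: 314 lumen pixels in slice 1, none elsewhere
  S <- 3
  lum <- array(0, c(127, 127, S))
  lum[1:314 + 127 * 20] <- 1   # 314 pixels, all inside slice 1
  img <- array(400, c(127, 127, S))
  zero <- array(0, c(127, 127, S))
  asMPR <- function(x) new("MPRVolume", data = x, inplaneSpacing = 0.1,
    sliceSpacing = 0.5, centers = matrix(0, S, 3),
    tangents = matrix(rep(c(0, 0, 1), each = S), S, 3),
    normals = matrix(rep(c(1, 0, 0), each = S), S, 3),
    binormals = matrix(rep(c(0, 1, 0), each = S), S, 3),
    fillFraction = 0)
  prof <- referenceCharacteristics(asMPR(lum), asMPR(zero), asMPR(img))
  expect_equal(lumenArea(prof)[1], 3.14)
  expect_equal(calciumArea(prof), rep(0, S))
  expect_equal(attenuation(prof)[1], 400)       # uniform HU inside the mask
  expect_true(all(is.na(attenuation(prof)[2:3])))  # no lumen pixels

  bad <- new("MPRVolume", data = lum[, , 1:2], inplaneSpacing = 0.1,
    sliceSpacing = 0.5, centers = matrix(0, 2, 3),
    tangents = matrix(rep(c(0, 0, 1), each = 2), 2, 3),
    normals = matrix(rep(c(1, 0, 0), each = 2), 2, 3),
    binormals = matrix(rep(c(0, 1, 0), each = 2), 2, 3), fillFraction = 0)
  expect_error(referenceCharacteristics(bad, asMPR(zero), asMPR(img)),
               "geometry")
})

test_that("MPR-resampled mask area of a straight tube matches pi r^2 within 3%", {
  for (r in c(0.5, 0.8, 1.4)) {
    vox <- 0.3
    nx <- ceiling((2 * r + 8) / vox)
    nz <- ceiling(16 / vox)
    cx <- (nx - 1) * vox / 2 + 0.13 * vox   # off-grid centre
    samples <- cbind(cx, cx, seq(1, 15, by = 0.1), r)
    mask <- coroflow:::.rasterTube(samples, c(nx, nx, nz), rep(vox, 3))
    vol <- ImageVolume(mask, rep(vox, 3))
    cl <- resampleCenterline(cbind(cx, cx, c(2, 14)))
    mpr <- reconstructMPR(vol, cl, maxFillFraction = 1)
    prof <- referenceCharacteristics(mpr, mpr, mpr)
    interior <- 3:(nSlices(mpr) - 3)
    relerr <- abs(lumenArea(prof)[interior] - pi * r^2) / (pi * r^2)
    expect_lt(max(relerr), 0.03)
  }
})

test_that("the toy FFR model honours its calibration anchors", {
  # unobstructed 3 mm^2 artery of 100 mm
  expect_gte(simulateFFR(rep(3, 201)), 0.97)
  # 70%-area stenosis, 10 mm, centred: FFR 0.70 +- 0.02
  s <- seq(0, 100, by = 0.5)
  A <- 3 * (1 - stenosisReduction(s, list(c(50, 10, 0.7))))
  expect_equal(simulateFFR(A), 0.70, tolerance = 0.02)
  # the frozen constants re-derive from the anchors
  cal <- calibrateFFRModel()
  frozen <- ffrModelParams()
  expect_equal(cal$c, frozen$c, tolerance = 1e-6)
  expect_equal(cal$k, frozen$k, tolerance = 1e-4)
  expect_error(simulateFFR(c(3, 0, 3)), "> 0")
})

test_that("the toy FFR model is monotone under pointwise area reduction", {
  set.seed(42)
  for (i in 1:100) {
    S <- sample(40:160, 1)
    A <- runif(S, 0.8, 8)
    B <- A * runif(S, 0.55, 1)   # pointwise reduced
    expect_lte(simulateFFR(B), simulateFFR(A))
  }
})

test_that("cohorts reach the requested prevalence and are reproducible", {
  coh <- generateCohort(100, classBalance = 0.42, seed = 7)
  frac <- mean(coh$index$label)
  expect_gte(frac, 0.37)
  expect_lte(frac, 0.47)
  expect_true(all(coh$index$ffr > 0 & coh$index$ffr <= 1))
  # every artery carries a defined measurement location
  for (r in coh$arteries) {
    expect_false(is.na(measurementIndex(r$reference)))
    expect_lte(measurementIndex(r$reference), nSlices(r$profile))
  }
  coh2 <- generateCohort(100, classBalance = 0.42, seed = 7)
  expect_identical(coh$index, coh2$index)
  expect_equal(lumenArea(coh$arteries[[5]]$profile),
               lumenArea(coh2$arteries[[5]]$profile))

  one <- generateCohort(1, seed = 1)
  expect_equal(max(one$index$patient), 1L)
})
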