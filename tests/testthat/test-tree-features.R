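# Bifurcation / main-branch extraction from the centerline tree and
# characteristic normalization.

makeChain <- function(n, label = "LAD", z0 = 0, id0 = 0L, parent0 = NA) {
  data.frame(id = id0 + seq_len(n), x = 0, y = 0,
             z = z0 + (seq_len(n) - 1) * 0.5,
             parent = c(parent0, id0 + seq_len(n - 1)), label = label)
}

test_that("an unbranched main artery maps to all-zero bifurcation, all-one main flags", {
  tree <- CenterlineTree(makeChain(21))
  art <- resampleCenterline(cbind(0, 0, c(0, 10)))
  tc <- extractTreeCharacteristics(tree, art)
  expect_equal(tc$bifurcation, rep(0, 21))
  expect_equal(tc$mainBranch, rep(1, 21))
})

test_that("only slices mapped to the branching node are flagged", {
  nd <- makeChain(21)
  # side branch leaving node 11 laterally
  nb <- data.frame(id = 21L + 1:8, x = (1:8) * 0.4, y = (1:8) * 0.3,
                   z = 5 + (1:8) * 0.2, parent = c(11L, 21L + 1:7),
                   label = "side-branch")
  tree <- CenterlineTree(rbind(nd, nb))
  art <- resampleCenterline(cbind(0, 0, c(0, 10)))
  tc <- extractTreeCharacteristics(tree, art)
  expect_equal(which(tc$bifurcation == 1), 11L)
  expect_equal(tc$mainBranch, rep(1, 21))
})

test_that("main-branch flags flip exactly at the label boundary", {
  # LAD for 5 mm, then a diagonal (side-branch) continuation
  nd <- rbind(makeChain(11, "LAD"),
              makeChain(10, "side-branch", z0 = 5.5, id0 = 11L,
                        parent0 = 11L))
  tree <- CenterlineTree(nd)
  art <- resampleCenterline(cbind(0, 0, c(0, 10)))
  tc <- extractTreeCharacteristics(tree, art)
  # node-walk oracle: nearest node label per artery point
  oracle <- vapply(seq_len(21), function(i) {
    p <- clPoints(art)[i, ]
    d2 <- (nd$x - p[1])^2 + (nd$y - p[2])^2 + (nd$z - p[3])^2
    nd$label[which.min(d2)] %in% c("LM", "LAD", "LCX", "RCA")
  }, logical(1))
  expect_equal(tc$mainBranch, as.numeric(oracle))
  expect_equal(tc$mainBranch, c(rep(1, 11), rep(0, 10)))
})

test_that("unmapped artery points are reported with their indices", {
  tree <- CenterlineTree(makeChain(5))
  art <- resampleCenterline(cbind(10, 10, c(0, 5)))  # 14 mm away laterally
  expect_error(extractTreeCharacteristics(tree, art), "indices")
})

test_that("flags are stable to resampling density within the mapping tolerance", {
  nd <- makeChain(41)  # 0.5 mm nodes over 20 mm
  nb <- data.frame(id = 41L + 1:6, x = (1:6) * 0.5, y = 0,
                   z = 10 + (1:6) * 0.3, parent = c(21L, 41L + 1:5),
                   label = "side-branch")
  tree <- CenterlineTree(rbind(nd, nb))
  dense <- resampleCenterline(cbind(0, 0, c(0, 20)), spacing = 0.5)
  # raw path described with very different vertex density
  sparse <- resampleCenterline(cbind(0, 0, c(0, 7, 20)), spacing = 0.5)
  a <- extractTreeCharacteristics(tree, dense)
  b <- extractTreeCharacteristics(tree, sparse)
  expect_equal(a$bifurcation, b$bifurcation)
  expect_equal(a$mainBranch, b$mainBranch)
})

test_that("characteristic normalization pools, degenerates gracefully and round-trips", {
  set.seed(21)
  profs <- lapply(1:3, function(i) makeProfile(30, seed = i))
  # the toy corpus has constant main-branch flags: degenerate but valid
  st <- suppressWarnings(fitCharacteristicStats(profs))
  pooled <- do.call(rbind, lapply(profs, coroflow:::.profileMatrix))
  normed <- do.call(rbind, lapply(profs, applyCharacteristicNorm, stats = st))
  expect_lt(max(abs(colMeans(normed))), 1e-6)

  expect_error(fitCharacteristicStats(profs[1]), "at least 2")

  # all-zero calcium corpus: sd replaced by 1 with a warning, series kept
  zprofs <- lapply(profs, function(p) {
    CharacteristicProfile(lumenArea(p), attenuation(p),
                          rep(0, nSlices(p)), bifurcationFlags(p),
                          mainBranchFlags(p))
  })
  expect_warning(st0 <- fitCharacteristicStats(zprofs), "calciumArea")
  n0 <- applyCharacteristicNorm(zprofs[[1]], st0)
  expect_equal(n0[, "calciumArea"], rep(0, 30))

  # persistence round-trip
  f <- tempfile(fileext = ".json")
  writeNormalizationStats(st, f)
  st2 <- readNormalizationStats(f)
  expect_lt(max(abs(statsMean(st2) - statsMean(st))), 1e-12)
  expect_lt(max(abs(applyCharacteristicNorm(profs[[1]], st2) -
                    applyCharacteristicNorm(profs[[1]], st))), 1e-12)

  # undefined attenuation becomes 0 after normalization
  pNA <- CharacteristicProfile(rep(3, 4), c(400, NA, 410, NA), rep(0.1, 4))
  nNA <- applyCharacteristicNorm(pNA, st)
  expect_equal(nNA[c(2, 4), "attenuation"], c(0, 0))
})
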