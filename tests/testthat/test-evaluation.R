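# Metrics, patient-level aggregation, referral simulation, permutation
# testing and the ablation harness plumbing.

test_that("dichotomization follows the FFR and probability conventions", {
  expect_true(dichotomize(0.80, "ffr"))     # FFR 0.8 is positive
  expect_false(dichotomize(0.81, "ffr"))
  expect_true(dichotomize(0.5, "probability"))  # ties are positive
  expect_false(dichotomize(0.49, "probability"))
})

test_that("metrics match the exhaustive pairwise AUC oracle", {
  expect_equal(computeMetrics(c(0.9, 0.8, 0.2, 0.1),
                              c(TRUE, TRUE, FALSE, FALSE))@auc, 1)
  expect_equal(computeMetrics(rep(0.5, 8),
                              c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE,
                                TRUE, FALSE))@auc, 0.5)
  set.seed(50)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    scores <- round(runif(n), 2)     # rounding induces ties
    labels <- runif(n) < 0.4
    if (!any(labels) || all(labels)) labels[1:2] <- c(TRUE, FALSE)
    expect_equal(computeMetrics(scores, labels)@auc,
                 aucPairOracle(scores, labels), tolerance = 1e-12)
  }
  # single-class reference: AUC undefined, other metrics computed
  m <- computeMetrics(c(0.9, 0.2), c(FALSE, FALSE))
  expect_true(is.na(m@auc))
  expect_equal(m@accuracy, 0.5)
  expect_equal(m@specificity, 0.5)
  # FFR mode ranks low values as positive
  m2 <- computeMetrics(c(0.6, 0.95), c(TRUE, FALSE), mode = "ffr")
  expect_equal(m2@auc, 1)
  expect_equal(m2@sensitivity, 1)
})

test_that("patient-level scores take the maximum artery and the any-positive label", {
  d <- patientLevel(c("a", "a", "b", "c"), c(0.2, 0.9, 0.4, 0.7),
                    c(0.85, 0.7, 0.9, 0.95))
  expect_equal(d$score[d$patient == "a"], 0.9)
  expect_true(d$label[d$patient == "a"])
  expect_false(d$label[d$patient == "b"])   # all arteries FFR > 0.8
  expect_equal(d$score[d$patient == "c"], 0.7)  # single artery passes through
  expect_warning(
    patientLevel(factor(c("a", "a"), levels = c("a", "ghost")),
                 c(0.1, 0.2), c(0.9, 0.9)),
    "zero arteries")
})

test_that("referral simulation removes or corrects the most uncertain cases", {
  set.seed(51)
  n <- 40
  scores <- runif(n)
  labels <- runif(n) < 0.4
  unc <- runif(n)
  base <- computeMetrics(scores, labels)
  r0 <- referralSimulation(scores, labels, unc, fraction = 0)
  expect_equal(r0@auc, base@auc)
  expect_equal(r0@accuracy, base@accuracy)

  rx <- referralSimulation(scores, labels, unc, 0.2, mode = "exclude")
  expect_equal(rx@nArteries, n - ceiling(0.2 * n))

  rc <- referralSimulation(scores, labels, unc, 1, mode = "correct")
  expect_equal(rc@accuracy, 1)
  expect_equal(rc@sensitivity, 1)
  expect_equal(rc@specificity, 1)

  expect_error(referralSimulation(scores, labels, unc, 1, mode = "exclude"),
               "fraction")
  # deterministic tie-breaking by case id
  tie <- rep(0.5, n)
  a <- referralSimulation(scores, labels, tie, 0.1, mode = "correct")
  b <- referralSimulation(scores, labels, tie, 0.1, mode = "correct")
  expect_equal(a@accuracy, b@accuracy)
})

test_that("the paired permutation test matches exhaustive enumeration", {
  set.seed(52)
  labels <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, FALSE)
  a <- runif(8); b <- runif(8)
  exact <- permExactOracle(a, b, labels)
  pt <- aucPermutationTest(a, b, labels, nIter = 1000, seed = 3)
  # Monte-Carlo error of a binomial proportion at n = 1000
  mcErr <- 3.5 * sqrt(exact * (1 - exact) / 1000) + 2 / 1000
  expect_lt(abs(pt$pValue - exact), mcErr + 1e-9)
  expect_gt(pt$pValue, 0)
  expect_lte(pt$pValue, 1)

  # identical score vectors give p = 1 under the add-one rule
  same <- aucPermutationTest(a, a, labels, nIter = 100, seed = 1)
  expect_equal(same$pValue, 1)
  expect_error(aucPermutationTest(a, b[1:5], labels), "paired")
})

test_that("permutation p-values are super-uniform under exchangeability", {
  set.seed(53)
  alpha <- c(0.1, 0.25, 0.5)
  ps <- replicate(150, {
    labels <- runif(10) < 0.5
    if (!any(labels) || all(labels)) labels[1:2] <- c(TRUE, FALSE)
    a <- runif(10); b <- runif(10)   # exchangeable: same distribution
    aucPermutationTest(a, b, labels, nIter = 49,
                       seed = sample.int(1e6, 1))$pValue
  })
  for (al in alpha)
    expect_lte(mean(ps <= al), al + 3 * sqrt(al * (1 - al) / 150))
})

test_that("the ablation harness zeroes channels without changing the architecture", {
  recs <- lapply(1:8, function(i)
    makeRecord(20, c(0.5, 0.9)[1 + i %% 2], i, seed = i, lesion = 5))
  ab <- suppressWarnings(ablationHarness(
    recs[1:6], recs[7:8],
    subsets = list(all = c("lumenArea", "attenuation", "calciumArea",
                           "bifurcation", "mainBranch"),
                   noLumen = c("attenuation", "calciumArea", "bifurcation",
                               "mainBranch")),
    config = stenosisNetConfig(seed = 2), epochs = 1))
  # identical parameter shapes in both models
  shapes <- function(m) lapply(unlist(m@params, recursive = TRUE), length)
  expect_identical(shapes(ab$all$model), shapes(ab$noLumen$model))
  expect_error(suppressWarnings(
    ablationHarness(recs[1:6], recs[7:8], subsets = list(none = character()),
                    config = stenosisNetConfig())), "empty")
  # zeroed lumen: predictions are invariant to the lumen series
  mod <- ab$noLumen$model
  r <- recs[[7]]
  p1 <- predictStenosis(mod, r$profile, 5)
  prof2 <- r$profile
  prof2@lumenArea <- prof2@lumenArea * 3 + 1
  p2 <- predictStenosis(mod, prof2, 5)
  expect_equal(probClass(p1), probClass(p2), tolerance = 1e-12)
  expect_equal(ffrRegressed(p1), ffrRegressed(p2), tolerance = 1e-12)
})
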