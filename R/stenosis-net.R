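# 1D convolution + transformer network over the five artery-characteristic
# series. The regression head predicts non-negative per-position pressure
# drops that are masked, summed along the artery and subtracted from 1 to
# yield the FFR (so ffr <= 1 holds architecturally); the classification
# head predicts the probability of functional significance (FFR <= 0.8).
#
# Dataflow: percentage differences of lumen area and attenuation pass
# through separate two-layer pre-encoders (16 filters, LeakyReLU between
# the layers); their encodings are concatenated with the normalized
# calcium, bifurcation and main-branch series; average pooling (kernel 4)
# then two convolutions with dilation 1 and 2 (each LeakyReLU + instance
# norm + dropout); the pooled-resolution normalized lumen/attenuation
# series are concatenated back in and fed through a linear projection to a
# single transformer encoder layer (2 heads, width 16, no positional
# encoding). All convolutions use kernel 3 with zero padding.

#' Per-location percentage difference of a series
#'
#' `d[1] = 0`, `d[i] = (x[i] - x[i-1]) / (|x[i-1]| + 1e-6)`: the fractional
#' change at each location with respect to the previous one, emphasizing
#' changes over absolute values. Applied to the raw lumen-area and
#' attenuation series before their pre-encoders.
#'
#' @param x numeric series (length >= 1).
#' @return Numeric series of the same length.
#' @examples
#' pctDifference(c(2, 1))   # 0, -0.5
#' @export
pctDifference <- function(x) {
  n <- length(x)
  if (n == 1L) return(0)
  c(0, (x[-1] - x[-n]) / (abs(x[-n]) + 1e-6))
}

#' Measurement mask over artery slices
#'
#' The invasive FFR measurement location is assumed 10 mm (20 slices at
#' 0.5 mm) distal to the annotated lesion; pressure-drop contributions
#' distal to it are masked out. Without a lesion annotation the most
#' distal clinically relevant location (lumen area > `minArea` mm^2) is
#' used. If no slice qualifies the full artery is kept, with a warning.
#'
#' @param S slice count.
#' @param lesionLocation 1-based slice index of the lesion, or `NA`.
#' @param lumenArea raw lumen-area series (needed when no lesion is given).
#' @param sliceSpacing slice distance in mm.
#' @param minArea clinical-relevance threshold in mm^2.
#' @return Binary vector of length `S`; 1 keeps the slice's drop.
#' @export
measurementMask <- function(S, lesionLocation = NA, lumenArea = NULL,
                            sliceSpacing = 0.5, minArea = 2) {
  if (S < 1) stop("S must be >= 1")
  mask <- numeric(S)
  if (!is.na(lesionLocation)) {
    end <- min(lesionLocation + round(10 / sliceSpacing), S)
  } else {
    if (is.null(lumenArea)) stop("need lumenArea when no lesion is annotated")
    ok <- which(lumenArea > minArea)
    if (!length(ok)) {
      warning("no slice with lumen area above threshold; masking full artery")
      end <- S
    } else end <- max(ok)
  }
  mask[seq_len(end)] <- 1
  mask
}

# pooled-resolution mask: a pooled position is unmasked iff any of its 4
# source slices is unmasked (conservative inclusion of the measurement
# location).
.poolMask <- function(mask) {
  P <- length(mask) %/% 4L
  grp <- rep(seq_len(P), each = 4)
  as.numeric(rowsum(mask[seq_len(4 * P)], grp) > 0)
}

#' Configuration for the stenosis-assessment network
#'
#' Defaults follow the reference settings: 16 filters, kernel 3, dropout
#' 0.5 everywhere, encoder pooling kernel 4, dilations 1 and 2, one
#' transformer layer, 5 classification pooling bins, 150 epochs with a
#' triangular cyclic learning rate between 5e-4 and 1e-5 over a 40-epoch
#' period, gradient accumulation over 8 arteries, and equal loss weights.
#'
#' @param filters,kernel,dropout,poolKernel,dilations,transformerLayers,bins
#'   architecture settings (see description).
#' @param heads attention heads of the transformer layer.
#' @param epochs,lrMax,lrMin,lrPeriod,accumSteps,lossWeights,weightDecay
#'   training settings.
#' @param channelMask named logical vector over the five characteristics;
#'   `FALSE` zeroes that input channel at train and test time (used by the
#'   ablation harness).
#' @param seed RNG seed.
#' @return Named list of settings.
#' @export
stenosisNetConfig <- function(filters = 16L, kernel = 3L, dropout = 0.5,
                              poolKernel = 4L, dilations = c(1L, 2L),
                              transformerLayers = 1L, bins = 5L, heads = 2L,
                              epochs = 150L, lrMax = 5e-4, lrMin = 1e-5,
                              lrPeriod = 40, accumSteps = 8L,
                              lossWeights = c(1, 1), weightDecay = 1e-3,
                              channelMask = NULL, seed = 1L) {
  stopifnot(filters >= 1L, dropout >= 0, dropout < 1, bins >= 1L)
  if (is.null(channelMask))
    channelMask <- stats::setNames(rep(TRUE, 5), .CHAR_NAMES)
  if (!all(.CHAR_NAMES %in% names(channelMask)))
    stop("channelMask must be named over the five characteristics")
  if (!any(channelMask)) stop("at least one characteristic must be enabled")
  list(filters = as.integer(filters), kernel = as.integer(kernel),
       dropout = dropout, poolKernel = as.integer(poolKernel),
       dilations = as.integer(dilations),
       transformerLayers = as.integer(transformerLayers),
       bins = as.integer(bins), heads = as.integer(heads),
       epochs = as.integer(epochs), lrMax = lrMax, lrMin = lrMin,
       lrPeriod = lrPeriod, accumSteps = as.integer(accumSteps),
       lossWeights = lossWeights, weightDecay = weightDecay,
       channelMask = channelMask[.CHAR_NAMES], seed = as.integer(seed))
}

#' Stenosis-assessment network model
#'
#' @slot config settings from [stenosisNetConfig()].
#' @slot params named list of weight arrays.
#' @slot charStats [NormalizationStats-class] of the five characteristics
#'   used to normalize inputs, or `NULL` until training.
#' @export
setClass("StenosisNetModel",
  representation(config = "list", params = "list", charStats = "ANY"))

setMethod("show", "StenosisNetModel", function(object) {
  np <- sum(vapply(unlist(object@params, recursive = TRUE),
                   length, numeric(1)))
  off <- names(which(!object@config$channelMask))
  cat(sprintf("StenosisNetModel: %d filters, %d-head transformer, %d parameters%s\n",
              object@config$filters, object@config$heads, np,
              if (length(off)) paste0(" (channels off: ",
                                      paste(off, collapse = ", "), ")")
              else ""))
})

#' Build an untrained stenosis-assessment network
#'
#' @param config from [stenosisNetConfig()].
#' @param charStats optional [NormalizationStats-class] for the inputs.
#' @return A [StenosisNetModel-class].
#' @export
buildStenosisNet <- function(config = stenosisNetConfig(),
                             charStats = NULL) {
  set.seed(config$seed)
  f <- config$filters
  cat3 <- 2L * f + 3L   # pre-encoded lumen + attenuation + 3 raw channels
  catT <- f + 2L        # encoder output + pooled lumen/attenuation bypass
  convUnit <- function(cin, cout) list(w = .heConv1d(cin, cout),
                                       b = numeric(cout))
  normUnit <- function(cin, cout) list(w = .heConv1d(cin, cout),
                                       b = numeric(cout),
                                       g = rep(1, cout), be = numeric(cout))
  params <- list(
    preL1 = convUnit(1L, f), preL2 = convUnit(f, f),
    preA1 = convUnit(1L, f), preA2 = convUnit(f, f),
    enc1 = normUnit(cat3, f), enc2 = normUnit(f, f),
    proj = list(w = .heDense(catT, f), b = numeric(f)),
    attn = list(Wq = .heDense(f, f) / sqrt(2), bq = numeric(f),
                Wk = .heDense(f, f) / sqrt(2), bk = numeric(f),
                Wv = .heDense(f, f) / sqrt(2), bv = numeric(f),
                Wo = .heDense(f, f) / sqrt(2), bo = numeric(f)),
    ln1 = list(g = rep(1, f), b = numeric(f)),
    ffn1 = list(w = .heDense(f, 2L * f), b = numeric(2L * f)),
    ffn2 = list(w = .heDense(2L * f, f), b = numeric(f)),
    ln2 = list(g = rep(1, f), b = numeric(f)),
    # the final drop convolution starts near zero so the initial drop sum
    # (and hence the regressed FFR) starts close to 1 regardless of artery
    # length; a small positive scale keeps the ReLU from starting dead
    reg1 = normUnit(f, f), reg2 = normUnit(f, f),
    reg3 = list(w = 0.05 * .heConv1d(f, 1L), b = numeric(1)),
    cls1 = list(w = .heDense(config$bins * f, f), b = numeric(f)),
    cls2 = list(w = .heDense(f, f), b = numeric(f)),
    cls3 = list(w = .heDense(f, 1L), b = numeric(1)))
  new("StenosisNetModel", config = config, params = params,
      charStats = charStats)
}

# Full forward pass for one artery.
# norm: S x 5 normalized characteristic matrix; rawLumen/rawAtten: raw
# series for the percentage-difference path; mask: slice-level binary mask.
# ablateAttention / ablateNorm are inference-only diagnostics: they bypass
# the two pathways (self-attention; instance-norm statistics) that couple
# positions beyond the convolutional receptive field.
.stenosisForward <- function(params, cfg, norm, rawLumen, rawAtten, mask,
                             train = FALSE, ablateAttention = FALSE,
                             ablateNorm = FALSE) {
  if (train && ablateNorm)
    stop("norm ablation is an inference-only diagnostic")
  instN <- if (ablateNorm) {
    function(x, g, b) list(y = x, xhat = x, inv = rep(1, ncol(x)))
  } else .instNormF
  S <- nrow(norm)
  if (S < 4L) stop("artery shorter than 4 slices: no pooled position")
  cm <- cfg$channelMask
  norm <- norm %*% diag(as.numeric(cm))
  dl <- if (cm[["lumenArea"]]) pctDifference(rawLumen) else numeric(S)
  da <- if (cm[["attenuation"]]) pctDifference(rawAtten) else numeric(S)
  drp <- function(dims) .dropoutMask(dims, cfg$dropout, train)

  z1L <- .conv1dF(matrix(dl, ncol = 1), params$preL1$w, params$preL1$b)
  a1L <- .leakyReluF(z1L)
  hL <- .conv1dF(a1L, params$preL2$w, params$preL2$b)
  z1A <- .conv1dF(matrix(da, ncol = 1), params$preA1$w, params$preA1$b)
  a1A <- .leakyReluF(z1A)
  hA <- .conv1dF(a1A, params$preA2$w, params$preA2$b)

  X35 <- cbind(hL, hA, norm[, 3:5, drop = FALSE])
  Xp <- .avgPool4F(X35)
  P <- nrow(Xp)

  e1z <- .conv1dF(Xp, params$enc1$w, params$enc1$b, dil = cfg$dilations[1])
  e1a <- .leakyReluF(e1z)
  e1n <- instN(e1a, params$enc1$g, params$enc1$be)
  m1 <- drp(dim(e1n$y)); e1d <- .applyMask(e1n$y, m1)
  e2z <- .conv1dF(e1d, params$enc2$w, params$enc2$b, dil = cfg$dilations[2])
  e2a <- .leakyReluF(e2z)
  e2n <- instN(e2a, params$enc2$g, params$enc2$be)
  m2 <- drp(dim(e2n$y)); e2d <- .applyMask(e2n$y, m2)

  byp <- cbind(.avgPool4F(norm[, 1, drop = FALSE]),
               .avgPool4F(norm[, 2, drop = FALSE]))
  C18 <- cbind(e2d, byp)
  prj <- .addCols(C18 %*% params$proj$w, params$proj$b)

  at <- if (ablateAttention) NULL else .mhaF(prj, params$attn, cfg$heads)
  s1 <- if (ablateAttention) prj else prj + at$y
  l1 <- .layerNormF(s1, params$ln1$g, params$ln1$b)
  fz <- .addCols(l1$y %*% params$ffn1$w, params$ffn1$b)
  fa <- pmax(fz, 0)
  f2 <- .addCols(fa %*% params$ffn2$w, params$ffn2$b)
  l2 <- .layerNormF(l1$y + f2, params$ln2$g, params$ln2$b)
  Tr <- l2$y

  rz1 <- .conv1dF(Tr, params$reg1$w, params$reg1$b)
  ra1 <- .leakyReluF(rz1)
  rn1 <- instN(ra1, params$reg1$g, params$reg1$be)
  m3 <- drp(dim(rn1$y)); rd1 <- .applyMask(rn1$y, m3)
  rz2 <- .conv1dF(rd1, params$reg2$w, params$reg2$b)
  ra2 <- .leakyReluF(rz2)
  rn2 <- instN(ra2, params$reg2$g, params$reg2$be)
  m4 <- drp(dim(rn2$y)); rd2 <- .applyMask(rn2$y, m4)
  rz3 <- .conv1dF(rd2, params$reg3$w, params$reg3$b)
  drops <- pmax(rz3, 0)
  maskP <- .poolMask(mask)
  ffr <- 1 - sum(drops[, 1] * maskP)

  bins <- .sumPoolBinsF(Tr, cfg$bins)
  v <- as.vector(bins)
  c1z <- drop(v %*% params$cls1$w) + params$cls1$b
  c1a <- .leakyReluF(c1z)
  m5 <- drp(length(c1a)); c1d <- if (is.null(m5)) c1a else c1a * m5
  c2z <- drop(c1d %*% params$cls2$w) + params$cls2$b
  c2a <- .leakyReluF(c2z)
  m6 <- drp(length(c2a)); c2d <- if (is.null(m6)) c2a else c2a * m6
  zc <- drop(c2d %*% params$cls3$w) + params$cls3$b
  prob <- .sigmoid(zc)

  list(ffr = ffr, prob = prob, drops = drops[, 1], maskP = maskP,
       cache = list(S = S, P = P, maskP = maskP, dl = dl, da = da,
                    z1L = z1L, a1L = a1L,
                    z1A = z1A, a1A = a1A, Xp = Xp,
                    e1z = e1z, e1n = e1n, m1 = m1, e1d = e1d,
                    e2z = e2z, e2n = e2n, m2 = m2, C18 = C18, prj = prj,
                    at = at, l1 = l1, fz = fz, fa = fa, l2 = l2, Tr = Tr,
                    rz1 = rz1, rn1 = rn1, m3 = m3, rd1 = rd1,
                    rz2 = rz2, rn2 = rn2, m4 = m4, rd2 = rd2, rz3 = rz3,
                    bins = bins, v = v, c1z = c1z, c1d = c1d,
                    c2z = c2z, c2d = c2d, zc = zc,
                    ablate = ablateAttention))
}

# Backward pass from dffr (scalar) and dzc (scalar, gradient at the
# pre-sigmoid classification output). Returns grads shaped like params.
.stenosisBackward <- function(params, cfg, cache, dffr, dzc) {
  g <- list()
  P <- cache$P
  f <- cfg$filters

  # classification head
  dc2d <- dzc * params$cls3$w[, 1]
  g$cls3 <- list(w = matrix(cache$c2d * dzc, ncol = 1), b = dzc)
  dc2a <- if (is.null(cache$m6)) dc2d else dc2d * cache$m6
  dc2z <- .leakyReluB(cache$c2z, dc2a)
  g$cls2 <- list(w = outer(cache$c1d, dc2z), b = dc2z)
  dc1d <- drop(params$cls2$w %*% dc2z)
  dc1a <- if (is.null(cache$m5)) dc1d else dc1d * cache$m5
  dc1z <- .leakyReluB(cache$c1z, dc1a)
  g$cls1 <- list(w = outer(cache$v, dc1z), b = dc1z)
  dv <- drop(params$cls1$w %*% dc1z)
  dT <- .sumPoolBinsB(matrix(dv, cfg$bins, f), P, cfg$bins)

  # regression head
  ddrops <- matrix(-dffr * cache$maskP, ncol = 1)
  drz3 <- ddrops * (cache$rz3 > 0)
  b3 <- .conv1dB(cache$rd2, params$reg3$w, 1L, drz3)
  g$reg3 <- list(w = b3$dw, b = b3$db)
  drd2 <- b3$dx
  drn2 <- .applyMask(drd2, cache$m4)
  in2 <- .instNormB(cache$rn2, params$reg2$g, drn2)
  dra2 <- .leakyReluB(cache$rz2, in2$dx)
  b2 <- .conv1dB(cache$rd1, params$reg2$w, 1L, dra2)
  g$reg2 <- list(w = b2$dw, b = b2$db, g = in2$dg, be = in2$db)
  drd1 <- b2$dx
  drn1 <- .applyMask(drd1, cache$m3)
  in1 <- .instNormB(cache$rn1, params$reg1$g, drn1)
  dra1 <- .leakyReluB(cache$rz1, in1$dx)
  b1 <- .conv1dB(cache$Tr, params$reg1$w, 1L, dra1)
  g$reg1 <- list(w = b1$dw, b = b1$db, g = in1$dg, be = in1$db)
  dT <- dT + b1$dx

  # transformer
  ln2b <- .layerNormB(cache$l2, params$ln2$g, dT)
  g$ln2 <- list(g = ln2b$dg, b = ln2b$db)
  ds2 <- ln2b$dx
  dfa <- ds2 %*% t(params$ffn2$w)
  g$ffn2 <- list(w = crossprod(cache$fa, ds2), b = colSums(ds2))
  dfz <- dfa * (cache$fz > 0)
  g$ffn1 <- list(w = crossprod(cache$l1$y, dfz), b = colSums(dfz))
  dl1y <- ds2 + dfz %*% t(params$ffn1$w)
  ln1b <- .layerNormB(cache$l1, params$ln1$g, dl1y)
  g$ln1 <- list(g = ln1b$dg, b = ln1b$db)
  ds1 <- ln1b$dx
  if (cache$ablate) {
    dprj <- ds1
    zeroLike <- function(x) if (is.matrix(x)) matrix(0, nrow(x), ncol(x))
                            else numeric(length(x))
    g$attn <- lapply(params$attn, zeroLike)
  } else {
    mb <- .mhaB(cache$prj, params$attn, cache$at, ds1, cfg$heads)
    g$attn <- mb$grads
    dprj <- ds1 + mb$dx
  }
  g$proj <- list(w = crossprod(cache$C18, dprj), b = colSums(dprj))
  dC18 <- dprj %*% t(params$proj$w)
  de2d <- dC18[, seq_len(f), drop = FALSE]

  # encoder
  de2n <- .applyMask(de2d, cache$m2)
  ie2 <- .instNormB(cache$e2n, params$enc2$g, de2n)
  de2a <- .leakyReluB(cache$e2z, ie2$dx)
  be2 <- .conv1dB(cache$e1d, params$enc2$w, cfg$dilations[2], de2a)
  g$enc2 <- list(w = be2$dw, b = be2$db, g = ie2$dg, be = ie2$db)
  de1d <- be2$dx
  de1n <- .applyMask(de1d, cache$m1)
  ie1 <- .instNormB(cache$e1n, params$enc1$g, de1n)
  de1a <- .leakyReluB(cache$e1z, ie1$dx)
  be1 <- .conv1dB(cache$Xp, params$enc1$w, cfg$dilations[1], de1a)
  g$enc1 <- list(w = be1$dw, b = be1$db, g = ie1$dg, be = ie1$db)
  dXp <- be1$dx
  dX35 <- .avgPool4B(dXp, cache$S)

  # pre-encoders
  dhL <- dX35[, seq_len(f), drop = FALSE]
  dhA <- dX35[, f + seq_len(f), drop = FALSE]
  bL2 <- .conv1dB(cache$a1L, params$preL2$w, 1L, dhL)
  g$preL2 <- list(w = bL2$dw, b = bL2$db)
  dz1L <- .leakyReluB(cache$z1L, bL2$dx)
  bL1 <- .conv1dB(matrix(cache$dl, ncol = 1), params$preL1$w, 1L, dz1L)
  g$preL1 <- list(w = bL1$dw, b = bL1$db)
  bA2 <- .conv1dB(cache$a1A, params$preA2$w, 1L, dhA)
  g$preA2 <- list(w = bA2$dw, b = bA2$db)
  dz1A <- .leakyReluB(cache$z1A, bA2$dx)
  bA1 <- .conv1dB(matrix(cache$da, ncol = 1), params$preA1$w, 1L, dz1A)
  g$preA1 <- list(w = bA1$dw, b = bA1$db)
  g[names(params)]
}

# slice-level measurement mask for a cohort record
.recordMask <- function(profile, reference) {
  S <- nSlices(profile)
  measurementMask(S, lesionLocation = lesionLocation(reference),
                  lumenArea = lumenArea(profile))
}

#' Predict FFR and significance probability for one artery
#'
#' Runs a single stenosis-assessment model (dropout disabled: outputs are
#' deterministic for fixed weights and input). The measurement mask is
#' derived from the lesion annotation when available, otherwise from the
#' most distal slice with lumen area above 2 mm^2.
#'
#' @param model a [StenosisNetModel-class] with fitted `charStats`.
#' @param profile a [CharacteristicProfile-class] (raw, unnormalized).
#' @param lesionLocation slice index of the annotated lesion or `NA`.
#' @param ablateAttention zero the attention mixing (diagnostic).
#' @return A [Prediction-class] (pseudo and merged probabilities filled in
#'   via [pseudoProbability()] and [mergeOutputs()]).
#' @export
predictStenosis <- function(model, profile, lesionLocation = NA,
                            ablateAttention = FALSE) {
  if (is.null(model@charStats))
    stop("model has no characteristic normalization statistics")
  norm <- applyCharacteristicNorm(profile, model@charStats)
  mask <- measurementMask(nSlices(profile), lesionLocation,
                          lumenArea = lumenArea(profile))
  fw <- .stenosisForward(model@params, model@config, norm,
                         lumenArea(profile), attenuation(profile), mask,
                         train = FALSE, ablateAttention = ablateAttention)
  pp <- pseudoProbability(fw$ffr)
  Prediction(ffrRegressed = fw$ffr, probClass = fw$prob, probPseudo = pp,
             probMerged = mergeOutputs(fw$prob, pp))
}

#' Train the stenosis-assessment network
#'
#' Loss is `MSE(ffr, reference) + BCE(probability, label)` with the
#' configured weights, accumulated over `accumSteps` arteries (one artery
#' per forward pass; lengths vary) before each AdamW update, under a
#' triangular cyclic learning rate. Profiles are normalized with
#' statistics fitted on the training arteries (persisted in the model).
#'
#' @param model a [StenosisNetModel-class] from [buildStenosisNet()].
#' @param records list of artery records, each with elements `profile`
#'   (a [CharacteristicProfile-class]) and `reference`
#'   (an [FFRReference-class]).
#' @param epochs override of the config epoch count.
#' @param charStats optional pre-fitted [NormalizationStats-class]; by
#'   default fitted on `records` (suppressing the zero-variance warning
#'   for degenerate toy corpora).
#' @param verbose print per-epoch losses.
#' @return The trained model, with a per-epoch `history` data.frame
#'   attached as attribute `history`.
#' @export
trainStenosisNet <- function(model, records, epochs = NULL,
                             charStats = NULL, verbose = FALSE) {
  cfg <- model@config
  epochs <- epochs %||% cfg$epochs
  if (is.null(charStats))
    charStats <- suppressWarnings(
      fitCharacteristicStats(lapply(records, `[[`, "profile")))
  model@charStats <- charStats
  prep <- lapply(records, function(r) {
    list(norm = applyCharacteristicNorm(r$profile, charStats),
         rawLumen = lumenArea(r$profile),
         rawAtten = attenuation(r$profile),
         mask = .recordMask(r$profile, r$reference),
         ffr = ffrValue(r$reference),
         y = as.numeric(ffrValue(r$reference) <= 0.8))
  })
  params <- model@params
  opt <- .adamwInit(params)
  set.seed(cfg$seed + 13L)
  w <- cfg$lossWeights
  history <- data.frame(epoch = integer(), mse = numeric(), bce = numeric())
  scaleG <- function(gr, s) lapply(gr, function(x)
    if (is.list(x)) lapply(x, `*`, s) else x * s)
  addG <- function(a, b) {
    if (is.null(a)) return(b)
    Map(function(x, y) if (is.list(x)) Map(`+`, x, y) else x + y, a, b)
  }
  for (ep in seq_len(epochs)) {
    ord <- sample(length(prep))
    acc <- NULL; nacc <- 0L
    mseSum <- 0; bceSum <- 0
    lr <- cyclicLearningRate(ep - 1, cfg$lrMax, cfg$lrMin, cfg$lrPeriod)
    for (i in ord) {
      r <- prep[[i]]
      fw <- .stenosisForward(params, cfg, r$norm, r$rawLumen, r$rawAtten,
                             r$mask, train = TRUE)
      p <- min(max(fw$prob, 1e-7), 1 - 1e-7)
      mse <- (fw$ffr - r$ffr)^2
      bce <- -(r$y * log(p) + (1 - r$y) * log(1 - p))
      if (!is.finite(mse + bce))
        stop(sprintf(
          "non-finite loss at epoch %d (artery %d): ffr=%g prob=%g",
          ep, i, fw$ffr, fw$prob))
      mseSum <- mseSum + mse; bceSum <- bceSum + bce
      gr <- .stenosisBackward(params, cfg, fw$cache,
                              dffr = 2 * w[1] * (fw$ffr - r$ffr),
                              dzc = w[2] * (p - r$y))
      acc <- addG(acc, gr); nacc <- nacc + 1L
      if (nacc == cfg$accumSteps || i == ord[length(ord)]) {
        upd <- .adamwStep(params, scaleG(acc, 1 / nacc), opt, lr,
                          weightDecay = cfg$weightDecay)
        params <- upd$params; opt <- upd$state
        acc <- NULL; nacc <- 0L
      }
    }
    history <- rbind(history,
                     data.frame(epoch = ep, mse = mseSum / length(prep),
                                bce = bceSum / length(prep)))
    if (verbose)
      message(sprintf("epoch %d: lr %.2g mse %.4f bce %.4f", ep, lr,
                      mseSum / length(prep), bceSum / length(prep)))
  }
  model@params <- params
  attr(model, "history") <- history
  model
}
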