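# 2D CNN regressing per-cross-section artery characteristics (lumen area,
# mean lumen attenuation, calcium area) from stacks of three MPR slices.
# Architecture: four blocks of [conv 3x3/16 + batch norm + ReLU] x2, each
# followed by 2x2 max pooling (127 -> 63 -> 31 -> 15 -> 7), then three
# separate heads: global average pooling and a single linear unit each.
# Targets are trained in normalized space (zero mean, unit variance over
# training slices) and de-normalized at output.

#' Configuration for the characterization network
#'
#' Defaults follow the reference training settings (MAE loss with the
#' attenuation term weighted 0.1, AdamW, learning rate 1e-5, batch size
#' 512, 800 epochs). Smaller-scale runs should lower `epochs`/`batchSize`
#' and raise `lr` accordingly.
#'
#' @param inSlices slices per input stack (odd; 3).
#' @param filters convolution filters per layer (16).
#' @param kernel convolution kernel size (3).
#' @param lr learning rate.
#' @param batchSize training batch size.
#' @param epochs training epochs.
#' @param attenuationWeight weight of the attenuation MAE term (0.1).
#' @param weightDecay AdamW decoupled weight decay.
#' @param seed RNG seed for initialization and batching.
#' @return Named list of settings.
#' @export
characterizerConfig <- function(inSlices = 3L, filters = 16L, kernel = 3L,
                                lr = 1e-5, batchSize = 512L, epochs = 800L,
                                attenuationWeight = 0.1, weightDecay = 1e-4,
                                seed = 1L) {
  stopifnot(inSlices %% 2L == 1L, filters >= 1L)
  list(inSlices = as.integer(inSlices), filters = as.integer(filters),
       kernel = as.integer(kernel), lr = lr,
       batchSize = as.integer(batchSize), epochs = as.integer(epochs),
       attenuationWeight = attenuationWeight, weightDecay = weightDecay,
       seed = as.integer(seed))
}

#' Characterization network model
#'
#' @slot config settings from [characterizerConfig()].
#' @slot params named list of weight arrays.
#' @slot running batch-norm running statistics (used at inference).
#' @slot targetStats [NormalizationStats-class] of the three regression
#'   targets, or `NULL` before training.
#' @slot intensityStats pooled MPR intensity [NormalizationStats-class]
#'   carried with the model, or `NULL`.
#' @export
setClass("CharacterizerModel",
  representation(config = "list", params = "list", running = "list",
                 targetStats = "ANY", intensityStats = "ANY"))

setMethod("show", "CharacterizerModel", function(object) {
  np <- sum(vapply(unlist(object@params, recursive = TRUE),
                   length, numeric(1)))
  cat(sprintf("CharacterizerModel: 4 conv blocks x %d filters, 3 heads, %d parameters%s\n",
              object@config$filters, np,
              if (is.null(object@targetStats)) " (untrained)" else ""))
})

.charLayerDims <- function(cfg) {
  list(cin = c(cfg$inSlices, rep(cfg$filters, 7)),
       cout = rep(cfg$filters, 8))
}

#' Build an untrained characterization network
#'
#' Initialization is seeded from `config$seed`; two builds with the same
#' seed have identical parameters, and the parameter count is independent
#' of the seed.
#'
#' @param config from [characterizerConfig()].
#' @return A [CharacterizerModel-class].
#' @export
buildCharacterizer <- function(config = characterizerConfig()) {
  set.seed(config$seed)
  dims <- .charLayerDims(config)
  k <- config$kernel
  params <- list()
  running <- list()
  for (l in 1:8) {
    cin <- dims$cin[l]; cout <- dims$cout[l]
    params[[paste0("conv", l)]] <- list(
      w = array(stats::rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
                c(k, k, cin, cout)),
      b = numeric(cout),
      gamma = rep(1, cout), beta = numeric(cout))
    running[[paste0("conv", l)]] <- list(mean = numeric(cout),
                                         var = rep(1, cout))
  }
  params$heads <- list(w = matrix(stats::rnorm(config$filters * 3, 0, 0.1),
                                  config$filters, 3),
                       b = numeric(3))
  new("CharacterizerModel", config = config, params = params,
      running = running, targetStats = NULL, intensityStats = NULL)
}

# forward pass over a batch x: (127, 127, inSlices, B).
# train = TRUE uses batch statistics and returns caches + running update.
.charForward <- function(params, running, x, train) {
  act <- x
  cache <- if (train) list(input = x) else NULL
  newRunning <- running
  eps <- 1e-5
  for (l in 1:8) {
    p <- params[[paste0("conv", l)]]
    convOut <- .cfConv2dForward(act, p$w, p$b)
    if (train) {
      bn <- .cfBNReluForward(convOut, p$gamma, p$beta, eps)
      r <- running[[paste0("conv", l)]]
      newRunning[[paste0("conv", l)]] <-
        list(mean = 0.9 * r$mean + 0.1 * bn$mean,
             var = 0.9 * r$var + 0.1 * bn$var)
      a <- bn$y
      cache[[paste0("l", l)]] <- list(xin = act, convOut = convOut,
                                      mu = bn$mean, var = bn$var)
    } else {
      r <- running[[paste0("conv", l)]]
      a <- .cfBNReluEval(convOut, p$gamma, p$beta, r$mean, r$var, eps)
    }
    if (l %% 2 == 0) {
      mp <- .cfMaxPool2Forward(a)
      if (train) cache[[paste0("pool", l / 2)]] <-
          list(idx = mp$idx, H = dim(a)[1], W = dim(a)[2])
      act <- mp$y
    } else {
      act <- a
    }
  }
  # act: (7, 7, filters, B); global average pool then three linear units
  d <- dim(act)
  feats <- matrix(colMeans(matrix(act, d[1] * d[2])), d[3], d[4])
  preds <- t(sweep(crossprod(feats, params$heads$w), 2, params$heads$b, "+"))
  if (train) { cache$feats <- feats; cache$gapDim <- d }
  list(preds = preds, cache = cache, running = newRunning)
}

# backward from dpreds (3 x B); returns gradients with the params structure.
.charBackward <- function(params, cache, dpreds) {
  grads <- list()
  feats <- cache$feats
  grads$heads <- list(w = feats %*% t(dpreds),
                      b = rowSums(dpreds))
  dfeats <- params$heads$w %*% dpreds      # filters x B
  d <- cache$gapDim
  dact <- array(rep(as.vector(dfeats), each = d[1] * d[2]) /
                  (d[1] * d[2]), d)
  eps <- 1e-5
  for (l in 8:1) {
    if (l %% 2 == 0) {
      pl <- cache[[paste0("pool", l / 2)]]
      dact <- .cfMaxPool2Backward(pl$idx, dact, pl$H, pl$W)
    }
    cl <- cache[[paste0("l", l)]]
    p <- params[[paste0("conv", l)]]
    bnB <- .cfBNReluBackward(cl$convOut, dact, cl$mu, cl$var,
                             p$gamma, p$beta, eps)
    cB <- .cfConv2dBackward(cl$xin, p$w, bnB$dx)
    grads[[paste0("conv", l)]] <- list(w = cB$dw, b = cB$db,
                                       gamma = bnB$dgamma, beta = bnB$dbeta)
    dact <- cB$dx
  }
  grads[names(params)]
}

# assemble the (127, 127, 3, B) batch for slice indices `pick` of an
# artery MPR array, with edge replication at the artery ends.
.tripletBatch <- function(mprArray, pick) {
  S <- dim(mprArray)[3]
  B <- length(pick)
  x <- array(0, c(dim(mprArray)[1], dim(mprArray)[2], 3L, B))
  for (b in seq_len(B)) {
    i <- pick[b]
    x[, , 1, b] <- mprArray[, , max(i - 1L, 1L)]
    x[, , 2, b] <- mprArray[, , i]
    x[, , 3, b] <- mprArray[, , min(i + 1L, S)]
  }
  x
}

#' Train the characterization network
#'
#' Minimizes `MAE(lumen) + 0.1 * MAE(attenuation) + MAE(calcium)` (weights
#' from the config) in normalized target space with AdamW. The dataset is a
#' list of arteries, each a list with `mpr` (a normalized
#' [MPRVolume-class] or a 127 x 127 x S array) and `targets` (S x 3 matrix
#' of lumen area, attenuation, calcium area per slice). Splitting into
#' train/validation arteries is the caller's responsibility and must be
#' artery-wise.
#'
#' @param model a [CharacterizerModel-class] from [buildCharacterizer()].
#' @param trainArteries list of arteries as described above.
#' @param valArteries optional held-out arteries for a per-epoch
#'   validation loss.
#' @param epochs,lr,batchSize overrides of the config values.
#' @param verbose print per-epoch losses.
#' @return The trained model with a `history` data.frame attached as
#'   attribute `history`.
#' @export
trainCharacterizer <- function(model, trainArteries, valArteries = NULL,
                               epochs = NULL, lr = NULL, batchSize = NULL,
                               verbose = FALSE) {
  cfg <- model@config
  epochs <- epochs %||% cfg$epochs
  lr <- lr %||% cfg$lr
  batchSize <- batchSize %||% cfg$batchSize
  asArray <- function(m) if (is(m, "MPRVolume")) mprData(m) else m
  tgts <- do.call(rbind, lapply(trainArteries, `[[`, "targets"))
  mu <- colMeans(tgts)
  sd <- sqrt(colMeans(sweep(tgts, 2, mu)^2))
  sd[sd <= 1e-12] <- 1
  names(mu) <- names(sd) <- c("lumenArea", "attenuation", "calciumArea")
  model@targetStats <- NormalizationStats(mu, sd)
  w3 <- c(1, cfg$attenuationWeight, 1)

  pool <- do.call(rbind, lapply(seq_along(trainArteries), function(a) {
    cbind(a, seq_len(dim(asArray(trainArteries[[a]]$mpr))[3]))
  }))
  params <- model@params
  running <- model@running
  opt <- .adamwInit(params)
  set.seed(cfg$seed + 7L)
  history <- data.frame(epoch = integer(), train = numeric(),
                        val = numeric())
  for (ep in seq_len(epochs)) {
    ord <- sample(nrow(pool))
    epLoss <- 0; nb <- 0
    for (start in seq(1, nrow(pool), by = batchSize)) {
      rows <- pool[ord[start:min(start + batchSize - 1, nrow(pool))], ,
                   drop = FALSE]
      xs <- vector("list", nrow(rows))
      ys <- matrix(0, 3, nrow(rows))
      for (r in seq_len(nrow(rows))) {
        art <- trainArteries[[rows[r, 1]]]
        xs[[r]] <- .tripletBatch(asArray(art$mpr), rows[r, 2])
        ys[, r] <- (art$targets[rows[r, 2], ] - mu) / sd
      }
      x <- array(unlist(xs), c(127, 127, 3, nrow(rows)))
      fw <- .charForward(params, running, x, train = TRUE)
      running <- fw$running
      resid <- fw$preds - ys
      loss <- sum(w3 * rowMeans(abs(resid)))
      if (!is.finite(loss))
        stop(sprintf("NaN/Inf training loss at epoch %d; last batch had %d samples, lr %g",
                     ep, nrow(rows), lr))
      dpreds <- (w3 * sign(resid)) / ncol(resid)
      grads <- .charBackward(params, fw$cache, dpreds)
      upd <- .adamwStep(params, grads, opt, lr,
                        weightDecay = cfg$weightDecay)
      params <- upd$params
      opt <- upd$state
      epLoss <- epLoss + loss; nb <- nb + 1
    }
    valLoss <- NA_real_
    if (!is.null(valArteries)) {
      model@params <- params; model@running <- running
      valLoss <- .charValLoss(model, valArteries, mu, sd, w3)
    }
    history <- rbind(history, data.frame(epoch = ep, train = epLoss / nb,
                                         val = valLoss))
    if (verbose)
      message(sprintf("epoch %d: train loss %.4f val %.4f",
                      ep, epLoss / nb, valLoss))
  }
  model@params <- params
  model@running <- running
  attr(model, "history") <- history
  model
}

.charValLoss <- function(model, arteries, mu, sd, w3) {
  tot <- 0; n <- 0
  for (art in arteries) {
    prof <- characterizeArtery(model, art$mpr)
    pred <- cbind(lumenArea(prof), attenuation(prof), calciumArea(prof))
    resid <- sweep(pred - art$targets, 2, sd, "/")
    tot <- tot + sum(w3 * colMeans(abs(resid))) * nrow(pred)
    n <- n + nrow(pred)
  }
  tot / n
}

#' Regress per-slice characteristics for a whole artery
#'
#' Applies the network to every cross-section of the MPR: the input for
#' slice `i` is the stack `(i-1, i, i+1)` with edge replication at the
#' artery ends. Outputs are de-normalized with the training target
#' statistics; no clipping is applied (downstream normalization handles
#' scale).
#'
#' @param model a trained [CharacterizerModel-class].
#' @param mpr a [MPRVolume-class] normalized with the training intensity
#'   statistics, or a raw 127 x 127 x S array.
#' @param batchSize slices per forward pass.
#' @return A [CharacteristicProfile-class] (tree flags at defaults).
#' @export
characterizeArtery <- function(model, mpr, batchSize = 32L) {
  x <- if (is(mpr, "MPRVolume")) mprData(mpr) else mpr
  S <- dim(x)[3]
  if (is.na(S) || S < 1) stop("MPR must contain at least one slice")
  preds <- matrix(0, 3, S)
  for (start in seq(1, S, by = batchSize)) {
    pick <- start:min(start + batchSize - 1, S)
    xb <- .tripletBatch(x, pick)
    fw <- .charForward(model@params, model@running, xb, train = FALSE)
    preds[, pick] <- fw$preds
  }
  if (!is.null(model@targetStats)) {
    mu <- statsMean(model@targetStats); sd <- statsSd(model@targetStats)
    preds <- preds * sd + mu
  }
  CharacteristicProfile(preds[1, ], preds[2, ], preds[3, ])
}
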