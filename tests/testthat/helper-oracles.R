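# Independent oracles and small fixture builders used across the suite.
# The oracles deliberately use naive formulations (scalar loops, exhaustive
# enumeration) so they stay independent of the package's vectorized paths.

# scalar 8-neighbour trilinear interpolation at one physical point
trilinearOracle <- function(volume, p) {
  x <- volumeData(volume)
  sp <- voxelSpacing(volume)
  or <- volumeOrigin(volume)
  v <- (p - or) / sp
  i0 <- floor(v)
  f <- v - i0
  acc <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wgt <- (if (dx) f[1] else 1 - f[1]) *
           (if (dy) f[2] else 1 - f[2]) *
           (if (dz) f[3] else 1 - f[3])
    acc <- acc + wgt * x[i0[1] + dx + 1, i0[2] + dy + 1, i0[3] + dz + 1]
  }
  acc
}

# AUC by exhaustive positive/negative pair counting, ties worth 1/2
aucPairOracle <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# exact permutation p-value over all 2^n swap patterns (paired sign flip)
permExactOracle <- function(a, b, labels) {
  n <- length(labels)
  obs <- abs(aucPairOracle(a, labels) - aucPairOracle(b, labels))
  count <- 0
  for (mask in 0:(2^n - 1)) {
    swap <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    aa <- ifelse(swap, b, a)
    bb <- ifelse(swap, a, b)
    d <- abs(aucPairOracle(aa, labels) - aucPairOracle(bb, labels))
    if (d >= obs - 1e-12) count <- count + 1
  }
  count / 2^n
}

# small artery profile with controllable geometry
makeProfile <- function(S, areas = NULL, seed = 1) {
  set.seed(seed)
  if (is.null(areas)) areas <- runif(S, 2.5, 7)
  CharacteristicProfile(areas, rnorm(S, 400, 10),
                        pmax(rnorm(S, 0.1, 0.3), 0),
                        as.numeric(seq_len(S) == max(2, S %/% 2)),
                        rep(1, S))
}

# minimal cohort record
makeRecord <- function(S, ffr, patient, seed = 1, lesion = NA) {
  prof <- makeProfile(S, seed = seed)
  meas <- if (!is.na(lesion)) min(lesion + 20L, S) else S
  list(profile = prof, reference = FFRReference(ffr, lesion, meas),
       patient = patient)
}

# numeric gradient of f at x by central differences (dense)
numGrad <- function(f, x, eps = 1e-6) {
  g <- array(0, dim(x) %||% length(x))
  for (i in seq_along(x)) {
    x1 <- x; x2 <- x
    x1[i] <- x1[i] + eps
    x2[i] <- x2[i] - eps
    g[i] <- (f(x1) - f(x2)) / (2 * eps)
  }
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a
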