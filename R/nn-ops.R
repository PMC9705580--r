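# 1D network primitives with explicit forward/backward passes, plus the
# AdamW optimizer. Sequences are matrices (positions x channels). These are
# internal building blocks for the stenosis-assessment network; gradients
# are verified against central differences in the test suite.

.shift1d <- function(x, off) {
  # row i of the result is x[i + off, ], zero outside the sequence
  S <- nrow(x)
  y <- matrix(0, S, ncol(x))
  if (off == 0) return(x)
  if (abs(off) >= S) return(y)
  if (off > 0) y[1:(S - off), ] <- x[(1 + off):S, , drop = FALSE]
  else y[(1 - off):S, ] <- x[1:(S + off), , drop = FALSE]
  y
}

# kernel-3 1D convolution, zero padding, optional dilation.
# w: array (3, Cin, Cout); y[i,] = sum_j x[i + (j-2)*dil, ] %*% w[j,,]
.wSlice <- function(w, j) matrix(w[j, , ], dim(w)[2], dim(w)[3])

# column-wise helpers avoiding sweep()'s aperm overhead
.addCols <- function(x, b) x + rep(b, each = nrow(x))
.mulCols <- function(x, s) x * rep(s, each = nrow(x))

.conv1dF <- function(x, w, b, dil = 1L) {
  .cfConv1dForward(x, w, as.numeric(b), as.integer(dil))
}

.conv1dB <- function(x, w, dil, dy) {
  .cfConv1dBackward(x, w, dy, as.integer(dil))
}

.leakyReluF <- function(x, a = 0.01) pmax(x, 0) + a * pmin(x, 0)
.leakyReluB <- function(x, dy, a = 0.01) dy * ((x > 0) + a * (x <= 0))

.instNormF <- function(x, g, b, eps = 1e-5) {
  # per channel over the sequence dimension (population variance)
  mu <- colMeans(x)
  xc <- .addCols(x, -mu)
  v <- colMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- .mulCols(xc, inv)
  list(y = .addCols(.mulCols(xhat, g), b), xhat = xhat, inv = inv)
}

.instNormB <- function(cache, g, dy) {
  n <- nrow(dy)
  xhat <- cache$xhat
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  dxhat <- .mulCols(dy, g)
  dx <- .addCols(dxhat, -colMeans(dxhat)) -
    .mulCols(xhat, colMeans(dxhat * xhat))
  list(dx = .mulCols(dx, cache$inv), dg = dg, db = db)
}

.dropoutMask <- function(dims, p, train) {
  if (!train || p <= 0) return(NULL)
  array(as.numeric(stats::runif(prod(dims)) >= p) / (1 - p), dims)
}
.applyMask <- function(x, m) if (is.null(m)) x else x * m

.avgPool4F <- function(x) {
  P <- nrow(x) %/% 4L
  i1 <- seq.int(1L, 4L * P, by = 4L)
  (x[i1, , drop = FALSE] + x[i1 + 1L, , drop = FALSE] +
   x[i1 + 2L, , drop = FALSE] + x[i1 + 3L, , drop = FALSE]) / 4
}
.avgPool4B <- function(dy, S) {
  dx <- matrix(0, S, ncol(dy))
  P <- nrow(dy)
  dx[seq_len(4 * P), ] <- dy[rep(seq_len(P), each = 4), , drop = FALSE] / 4
  dx
}

# adaptive sum pooling into `bins` contiguous near-equal groups; the
# remainder is spread over the proximal bins. Bins beyond the sequence
# length stay empty (zero sums).
.binSizes <- function(P, bins = 5L) {
  base <- P %/% bins
  sizes <- rep(base, bins)
  rem <- P - base * bins
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  sizes
}
.sumPoolBinsF <- function(x, bins = 5L) {
  sizes <- .binSizes(nrow(x), bins)
  ends <- cumsum(sizes)
  y <- matrix(0, bins, ncol(x))
  for (k in seq_len(bins)) {
    if (sizes[k] > 0)
      y[k, ] <- colSums(x[(ends[k] - sizes[k] + 1L):ends[k], ,
                          drop = FALSE])
  }
  y
}
.sumPoolBinsB <- function(dy, P, bins = 5L) {
  sizes <- .binSizes(P, bins)
  grp <- rep(seq_len(bins), times = sizes)
  dy[grp, , drop = FALSE]
}

.layerNormF <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  list(y = .addCols(.mulCols(xhat, g), b), xhat = xhat, inv = inv)
}
.layerNormB <- function(cache, g, dy) {
  C <- ncol(dy)
  xhat <- cache$xhat
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  dxhat <- .mulCols(dy, g)
  dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * cache$inv
  list(dx = dx, dg = dg, db = db)
}

.softmaxRows <- function(z) {
  m <- z[cbind(seq_len(nrow(z)), max.col(z, ties.method = "first"))]
  e <- exp(z - m)
  e / rowSums(e)
}

# multi-head self-attention, width 16, `heads` heads, no positional encoding
.mhaF <- function(x, p, heads = 2L) {
  C <- ncol(x)
  dh <- C %/% heads
  Q <- .addCols(x %*% p$Wq, p$bq)
  K <- .addCols(x %*% p$Wk, p$bk)
  V <- .addCols(x %*% p$Wv, p$bv)
  O <- matrix(0, nrow(x), C)
  A <- vector("list", heads)
  for (h in seq_len(heads)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    Ah <- .softmaxRows(Q[, cols, drop = FALSE] %*%
                       t(K[, cols, drop = FALSE]) / sqrt(dh))
    O[, cols] <- Ah %*% V[, cols, drop = FALSE]
    A[[h]] <- Ah
  }
  y <- .addCols(O %*% p$Wo, p$bo)
  list(y = y, Q = Q, K = K, V = V, O = O, A = A)
}

.mhaB <- function(x, p, cache, dy, heads = 2L) {
  C <- ncol(x)
  dh <- C %/% heads
  dWo <- crossprod(cache$O, dy)
  dbo <- colSums(dy)
  dO <- dy %*% t(p$Wo)
  dQ <- matrix(0, nrow(x), C); dK <- dQ; dV <- dQ
  for (h in seq_len(heads)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    Ah <- cache$A[[h]]
    Vh <- cache$V[, cols, drop = FALSE]
    dOh <- dO[, cols, drop = FALSE]
    dV[, cols] <- crossprod(Ah, dOh)
    dA <- dOh %*% t(Vh)
    # softmax backward per row
    dZ <- Ah * (dA - rowSums(dA * Ah))
    dQ[, cols] <- dZ %*% cache$K[, cols, drop = FALSE] / sqrt(dh)
    dK[, cols] <- crossprod(dZ, cache$Q[, cols, drop = FALSE]) / sqrt(dh)
  }
  list(dx = dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv),
       grads = list(Wq = crossprod(x, dQ), bq = colSums(dQ),
                    Wk = crossprod(x, dK), bk = colSums(dK),
                    Wv = crossprod(x, dV), bv = colSums(dV),
                    Wo = dWo, bo = dbo))
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

# -- initialization and optimizer -------------------------------------------

.heConv1d <- function(cin, cout) {
  array(stats::rnorm(3 * cin * cout, 0, sqrt(2 / (3 * cin))), c(3, cin, cout))
}
.heDense <- function(cin, cout) {
  matrix(stats::rnorm(cin * cout, 0, sqrt(2 / cin)), cin, cout)
}

# AdamW with decoupled weight decay over a named (possibly nested) list of
# numeric arrays.
.adamwInit <- function(params) {
  zero <- function(x) {
    if (is.list(x)) lapply(x, zero) else array(0, dim(x) %||% length(x))
  }
  list(m = zero(params), v = zero(params), t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.adamwStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, weightDecay = 0.01) {
  state$t <- state$t + 1L
  t <- state$t
  step <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(step, p, g, m, v)
      return(list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    p <- p - lr * (mh / (sqrt(vh) + eps) + weightDecay * p)
    list(p = p, m = m, v = v)
  }
  out <- Map(step, params, grads, state$m, state$v)
  list(params = lapply(out, `[[`, "p"),
       state = list(m = lapply(out, `[[`, "m"),
                    v = lapply(out, `[[`, "v"), t = t))
}

#' Triangular cyclic learning rate
#'
#' Linear ramp from `lrMax` down to `lrMin` and back over `period` epochs,
#' evaluated at a (possibly fractional) epoch position. The schedule starts
#' at `lrMax`, reaches `lrMin` after half a period.
#'
#' @param epoch 0-based epoch position.
#' @param lrMax,lrMin bounds of the cycle.
#' @param period cycle length in epochs.
#' @return Learning rate.
#' @export
cyclicLearningRate <- function(epoch, lrMax = 5e-4, lrMin = 1e-5,
                               period = 40) {
  phase <- (epoch %% period) / period        # 0..1
  frac <- 2 * abs(phase - 0.5)               # 1 at 0, 0 at half period
  lrMin + (lrMax - lrMin) * frac
}
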