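# Straightened multiplanar reformation along artery centerlines.
#
# Conventions: coordinates are physical mm; volume indexing is 0-based in
# the interpolation arithmetic; MPR pixel (64, 64) (1-based) is the
# centerline point. In-plane orientation is propagated by
# rotation-minimizing (parallel-transport) frames via the double-reflection
# method, initialized from a fixed arbitrary normal at the ostium; tangents
# are central differences of the resampled points (one-sided at the ends).

#' Resample a centerline polyline at a fixed step
#'
#' Walks the piecewise-linear arc-length parameterization of the raw
#' polyline emitting points at exactly `spacing` mm (default 0.5 mm, the
#' MPR slice distance): each resampled point lies on the polyline at
#' Euclidean distance `spacing` from the previous one, so consecutive
#' distances are exact to machine precision even on curved paths. Labels
#' and successor counts are carried over from the nearest raw point.
#'
#' @param rawPoints numeric matrix (n x 3, n >= 2) of positions in mm.
#' @param label anatomical labels: one per raw point, or a single label.
#' @param nsucc successor counts per raw point (default 1).
#' @param spacing step in mm.
#' @return An [ArteryCenterline-class].
#' @export
resampleCenterline <- function(rawPoints, label = "LAD", nsucc = NULL,
                               spacing = 0.5) {
  rawPoints <- as.matrix(rawPoints)
  n <- nrow(rawPoints)
  if (n < 2L) stop("need at least 2 raw points")
  seg <- rawPoints[-1, , drop = FALSE] - rawPoints[-n, , drop = FALSE]
  segLen <- sqrt(rowSums(seg^2))
  total <- sum(segLen)
  if (total < 1.0)
    stop(sprintf("centerline is only %.2f mm long (< 1 mm)", total))
  if (length(label) == 1L) label <- rep(label, n)
  if (is.null(nsucc)) nsucc <- rep(1L, n)

  pts <- matrix(0, ceiling(total / spacing) + 2L, 3)
  near <- integer(nrow(pts))
  pts[1, ] <- rawPoints[1, ]
  near[1] <- 1L
  np <- 1L
  j <- 1L        # current segment index
  t0 <- 0        # parameter already consumed on segment j
  cur <- rawPoints[1, ]
  while (j <= n - 1L) {
    A <- rawPoints[j, ]; d <- seg[j, ]
    # smallest t in (t0, 1] with |A + t*d - cur| = spacing
    w <- A - cur
    a <- sum(d * d); b <- 2 * sum(w * d); cc <- sum(w * w) - spacing^2
    disc <- b * b - 4 * a * cc
    t <- if (disc < 0) Inf else (-b + sqrt(disc)) / (2 * a)
    if (t > t0 - 1e-12 && t <= 1 + 1e-12) {
      t <- min(max(t, 0), 1)
      cur <- A + t * d
      np <- np + 1L
      pts[np, ] <- cur
      near[np] <- if (t < 0.5) j else j + 1L
      t0 <- t
    } else {
      j <- j + 1L
      t0 <- 0
    }
  }
  pts <- pts[seq_len(np), , drop = FALSE]
  near <- near[seq_len(np)]
  new("ArteryCenterline", points = pts, labels = label[near],
      nsucc = as.integer(nsucc[near]), spacing = spacing)
}

#' Trilinear interpolation of a volume at physical points
#'
#' @param volume an [ImageVolume-class].
#' @param points numeric matrix (m x 3) of positions in mm.
#' @param fill value for points outside the volume bounds.
#' @return List with `values` (numeric m) and `outside` (logical m).
#' @export
trilinearSample <- function(volume, points, fill = -1024) {
  dm <- dim(volumeData(volume))
  sp <- voxelSpacing(volume)
  or <- volumeOrigin(volume)
  v <- sweep(sweep(points, 2, or), 2, sp, "/") # 0-based continuous index
  outside <- v[, 1] < 0 | v[, 1] > dm[1] - 1 |
             v[, 2] < 0 | v[, 2] > dm[2] - 1 |
             v[, 3] < 0 | v[, 3] > dm[3] - 1
  v0 <- pmin(pmax(floor(v), 0), rep(dm, each = nrow(v)) - 2)
  f <- v - v0
  f <- pmin(pmax(f, 0), 1)
  x <- volumeData(volume)
  id <- function(dx, dy, dz)
    1 + (v0[, 1] + dx) + (v0[, 2] + dy) * dm[1] +
      (v0[, 3] + dz) * dm[1] * dm[2]
  fx <- f[, 1]; fy <- f[, 2]; fz <- f[, 3]
  vals <-
    x[id(0, 0, 0)] * (1 - fx) * (1 - fy) * (1 - fz) +
    x[id(1, 0, 0)] * fx       * (1 - fy) * (1 - fz) +
    x[id(0, 1, 0)] * (1 - fx) * fy       * (1 - fz) +
    x[id(1, 1, 0)] * fx       * fy       * (1 - fz) +
    x[id(0, 0, 1)] * (1 - fx) * (1 - fy) * fz +
    x[id(1, 0, 1)] * fx       * (1 - fy) * fz +
    x[id(0, 1, 1)] * (1 - fx) * fy       * fz +
    x[id(1, 1, 1)] * fx       * fy       * fz
  vals[outside] <- fill
  list(values = vals, outside = outside)
}

# Rotation-minimizing frames along resampled points (double reflection).
.rmFrames <- function(pts) {
  S <- nrow(pts)
  tg <- matrix(0, S, 3)
  tg[1, ] <- pts[2, ] - pts[1, ]
  tg[S, ] <- pts[S, ] - pts[S - 1, ]
  if (S > 2)
    tg[2:(S - 1), ] <- pts[3:S, , drop = FALSE] - pts[1:(S - 2), , drop = FALSE]
  nrm <- sqrt(rowSums(tg^2))
  if (any(nrm < 1e-12))
    stop("degenerate tangent: repeated centerline points")
  tg <- tg / nrm
  nn <- matrix(0, S, 3)
  e <- diag(3)[, which.min(abs(tg[1, ]))]
  n1 <- e - sum(e * tg[1, ]) * tg[1, ]
  nn[1, ] <- n1 / sqrt(sum(n1^2))
  if (S > 1) {
    for (i in 1:(S - 1)) {
      v1 <- pts[i + 1, ] - pts[i, ]
      c1 <- sum(v1^2)
      rL <- nn[i, ] - (2 / c1) * sum(v1 * nn[i, ]) * v1
      tL <- tg[i, ] - (2 / c1) * sum(v1 * tg[i, ]) * v1
      v2 <- tg[i + 1, ] - tL
      c2 <- sum(v2^2)
      nn[i + 1, ] <- if (c2 < 1e-16) rL else
        rL - (2 / c2) * sum(v2 * rL) * v2
      nn[i + 1, ] <- nn[i + 1, ] - sum(nn[i + 1, ] * tg[i + 1, ]) * tg[i + 1, ]
      nn[i + 1, ] <- nn[i + 1, ] / sqrt(sum(nn[i + 1, ]^2))
    }
  }
  bb <- cbind(tg[, 2] * nn[, 3] - tg[, 3] * nn[, 2],
              tg[, 3] * nn[, 1] - tg[, 1] * nn[, 3],
              tg[, 1] * nn[, 2] - tg[, 2] * nn[, 1])
  list(tangents = tg, normals = nn, binormals = bb)
}

#' Reconstruct a straightened MPR along an artery centerline
#'
#' Samples, for every resampled centerline point, a 127 x 127 grid with
#' 0.1 mm pixels in the plane perpendicular to the local tangent, centred
#' on the point, using trilinear interpolation. Sample points outside the
#' volume are filled with -1024 HU and counted; an artery with more than
#' `maxFillFraction` filled samples is rejected, mirroring a field-of-view
#' inclusion rule.
#'
#' @param volume an [ImageVolume-class].
#' @param centerline an [ArteryCenterline-class] (0.5 mm spacing).
#' @param size in-plane pixel count per axis (127).
#' @param inplaneSpacing in-plane pixel size in mm (0.1).
#' @param fill HU value for out-of-volume samples.
#' @param maxFillFraction reject the artery above this fill fraction.
#' @return An [MPRVolume-class].
#' @export
reconstructMPR <- function(volume, centerline, size = 127L,
                           inplaneSpacing = 0.1, fill = -1024,
                           maxFillFraction = 0.05) {
  pts <- clPoints(centerline)
  S <- nrow(pts)
  fr <- .rmFrames(pts)
  offs <- (seq_len(size) - (size + 1) / 2) * inplaneSpacing
  gu <- rep(offs, times = size)          # first in-plane axis (rows)
  gv <- rep(offs, each = size)           # second in-plane axis (cols)
  npx <- size * size
  all <- matrix(0, npx * S, 3)
  for (i in seq_len(S)) {
    rows <- ((i - 1) * npx + 1):(i * npx)
    all[rows, ] <- matrix(pts[i, ], npx, 3, byrow = TRUE) +
      outer(gu, fr$normals[i, ]) + outer(gv, fr$binormals[i, ])
  }
  sm <- trilinearSample(volume, all, fill = fill)
  fillFraction <- mean(sm$outside)
  if (fillFraction > maxFillFraction)
    stop(sprintf(
      "artery rejected: %.1f%% of MPR samples fall outside the volume (limit %.0f%%)",
      100 * fillFraction, 100 * maxFillFraction))
  new("MPRVolume", data = array(sm$values, c(size, size, S)),
      inplaneSpacing = inplaneSpacing, sliceSpacing = centerline@spacing,
      centers = pts, tangents = fr$tangents, normals = fr$normals,
      binormals = fr$binormals, fillFraction = fillFraction)
}

#' Fit pooled intensity-normalization statistics
#'
#' Pools all voxels of all training MPRs and fits a single mean and
#' standard deviation, applied as `(x - mean) / sd` at train and test time
#' (no re-fitting on test data).
#'
#' @param mprs list of [MPRVolume-class] objects.
#' @return A [NormalizationStats-class] with one entry named `intensity`.
#' @export
fitIntensityStats <- function(mprs) {
  if (!length(mprs)) stop("need at least one training MPR")
  n <- 0; s <- 0; s2 <- 0
  for (m in mprs) {
    x <- mprData(m)
    n <- n + length(x); s <- s + sum(x); s2 <- s2 + sum(x^2)
  }
  mu <- s / n
  v <- s2 / n - mu^2
  if (v <= 1e-12) stop("zero intensity variance in the training corpus")
  NormalizationStats(mean = c(intensity = mu), sd = c(intensity = sqrt(v)))
}

#' Apply intensity normalization to an MPR
#'
#' @param mpr an [MPRVolume-class].
#' @param stats a [NormalizationStats-class] from [fitIntensityStats()].
#' @return The normalized [MPRVolume-class].
#' @export
applyIntensityNorm <- function(mpr, stats) {
  mpr@data <- (mpr@data - statsMean(stats)[["intensity"]]) /
    statsSd(stats)[["intensity"]]
  mpr
}
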