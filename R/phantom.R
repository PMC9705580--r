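# Synthetic CCTA vessel phantoms: curved contrast-filled tubes with focal
# stenoses and adjacent calcified plaque in a soft-tissue background, plus
# voxel-exact masks, a labeled centerline tree and analytic ground truth.
#
# The tube is rasterized as the union of spheres centred on a densely
# sampled (0.1 mm) centerline with local radius r(s); at that sampling
# density the union deviates from the exact tube by well under a
# thousandth of a millimetre.

.CALCIUM_THICKNESS_MM <- 0.8

# Dense centerline of the main artery: a straight axial path with a smooth
# random in-plane spline perturbation, bounded so the tube cannot
# self-intersect. Returns positions (M x 3), cumulative arc length and the
# axial extent used.
.denseMainCenterline <- function(config, ds = 0.1) {
  L <- config@arteryLengthMM
  ext <- (config@volumeShape - 1) * config@voxelSpacing
  zmargin <- (ext[3] - L) / 2
  if (zmargin < 1) stop("volume too short for the requested artery length")
  t <- seq(0, L, by = ds)
  ctrl <- seq(0, L, length.out = 5)
  ax <- pmin(pmax(stats::rnorm(5, 0, 0.8), -2), 2)
  ay <- pmin(pmax(stats::rnorm(5, 0, 0.8), -2), 2)
  ax <- ax - ax[1]; ay <- ay - ay[1]
  px <- stats::spline(ctrl, ax, xout = t)$y
  py <- stats::spline(ctrl, ay, xout = t)$y
  pts <- cbind(ext[1] / 2 + px, ext[2] / 2 + py, zmargin + t)
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  list(points = pts, arc = c(0, cumsum(seg)))
}

.denseBranchCenterline <- function(mainPts, mainArc, config, ds = 0.1) {
  sTotal <- mainArc[length(mainArc)]
  sB <- 0.45 * sTotal
  i0 <- which.min(abs(mainArc - sB))
  p0 <- mainPts[i0, ]
  tgt <- mainPts[min(i0 + 5, nrow(mainPts)), ] - mainPts[max(i0 - 5, 1), ]
  tgt <- tgt / sqrt(sum(tgt^2))
  # random unit vector perpendicular to the tangent
  v <- stats::rnorm(3)
  v <- v - sum(v * tgt) * tgt
  v <- v / sqrt(sum(v^2))
  theta <- 35 * pi / 180
  dir <- cos(theta) * tgt + sin(theta) * v
  len <- min(12, 0.8 * (sTotal - sB))
  t <- seq(ds, len, by = ds)
  pts <- sweep(outer(t, dir), 2, p0, "+")
  list(points = pts, arc = t, branchIndexMain = i0, branchArc = sB)
}

# Partial-volume tube mask, slice by slice. `samples` has columns
# x, y, z, r. The tube is the union of spheres on the dense centerline;
# each voxel stores the coverage fraction clamp(0.5 - sd/h, 0, 1) of its
# signed distance sd to the tube surface (linear ramp of one voxel width),
# so the 0.5 level of a trilinear resampling tracks the true surface.
.rasterTube <- function(samples, shape, spacing) {
  h <- max(spacing)
  xs <- (seq_len(shape[1]) - 1) * spacing[1]
  ys <- (seq_len(shape[2]) - 1) * spacing[2]
  zs <- (seq_len(shape[3]) - 1) * spacing[3]
  out <- array(0, shape)
  for (k in seq_len(shape[3])) {
    dz <- abs(samples[, 3] - zs[k])
    cand <- which(dz < samples[, 4] + 2 * h)
    if (!length(cand)) next
    sd <- matrix(Inf, shape[1], shape[2])
    for (m in cand) {
      d <- sqrt(outer((xs - samples[m, 1])^2, (ys - samples[m, 2])^2, "+") +
                (samples[m, 3] - zs[k])^2) - samples[m, 4]
      sd <- pmin(sd, d)
    }
    out[, , k] <- pmin(pmax(0.5 - sd / h, 0), 1)
  }
  out
}

# Partial-volume calcified shell: between r and r + thickness around the
# lumen, restricted to an angular arc in the image xy-plane (the tubes are
# near-axial). Radial boundaries carry the same one-voxel linear ramp as
# the lumen; the angular cut is sharp.
.rasterCalciumShell <- function(samples, theta0, halfAngle, shape, spacing) {
  thick <- .CALCIUM_THICKNESS_MM
  h <- max(spacing)
  xs <- (seq_len(shape[1]) - 1) * spacing[1]
  ys <- (seq_len(shape[2]) - 1) * spacing[2]
  zs <- (seq_len(shape[3]) - 1) * spacing[3]
  out <- array(0, shape)
  for (k in seq_len(shape[3])) {
    dz <- abs(samples[, 3] - zs[k])
    cand <- which(dz < samples[, 4] + thick + 2 * h)
    if (!length(cand)) next
    sd <- matrix(Inf, shape[1], shape[2])
    for (m in cand) {
      d <- sqrt(outer((xs - samples[m, 1])^2, (ys - samples[m, 2])^2, "+") +
                (samples[m, 3] - zs[k])^2)
      shell <- pmax(d - (samples[m, 4] + thick), samples[m, 4] - d)
      ang <- atan2(outer(rep(1, length(xs)), ys - samples[m, 2]),
                   outer(xs - samples[m, 1], rep(1, length(ys))))
      dang <- abs(((ang - theta0 + pi) %% (2 * pi)) - pi)
      shell[dang > halfAngle] <- Inf
      sd <- pmin(sd, shell)
    }
    out[, , k] <- pmin(pmax(0.5 - sd / h, 0), 1)
  }
  out
}

#' Generate a synthetic CCTA vessel phantom
#'
#' Builds a curved contrast-filled tube of local radius
#' `r(s) = baselineRadius * sqrt(1 - reduction(s))` following a smooth 3D
#' centerline, optionally with one side branch and calcified plaque shells
#' abutting the lumen, embedded in soft tissue with additive Gaussian HU
#' noise. Voxel-exact lumen and calcium indicator masks are returned
#' alongside the noisy volume, a labeled centerline tree, and analytic
#' per-slice ground truth (areas, attenuation, lesion location and the
#' toy-model FFR). Masks are partial-volume coverage fractions (a linear
#' ramp of one voxel width across the surface; binarize at 0.5 for an
#' indicator), which is also how the HU values mix at the lumen and plaque
#' boundaries. Identical seeds give bit-identical output.
#'
#' @param config a [PhantomConfig-class] object.
#' @return List with elements `volume`, `lumenMask`, `calciumMask`
#'   ([ImageVolume-class]), `tree` ([CenterlineTree-class]), `centerline`
#'   (the resampled main-artery [ArteryCenterline-class]) and
#'   `groundTruth` ([PhantomGroundTruth-class]).
#' @examples
#' ph <- generatePhantom(phantomConfig(arteryLengthMM = 20, seed = 7))
#' ph$groundTruth
#' @export
generatePhantom <- function(config) {
  stopifnot(is(config, "PhantomConfig"))
  L <- config@arteryLengthMM
  for (sp in config@stenosisSpec) {
    if (sp[1] - sp[2] / 2 < 1.5 || sp[1] + sp[2] / 2 > L - 1.5)
      stop(sprintf(
        "stenosis at %.1f mm (length %.1f mm) overlaps the artery end",
        sp[1], sp[2]))
  }
  set.seed(config@seed)
  main <- .denseMainCenterline(config)
  rMain <- config@baselineRadiusMM *
    sqrt(1 - stenosisReduction(main$arc, config@stenosisSpec))
  samples <- cbind(main$points, rMain)

  nodes <- NULL
  branch <- NULL
  mainCl <- resampleCenterline(main$points, label = "LAD")
  nMain <- nrow(clPoints(mainCl))
  nodes <- data.frame(id = seq_len(nMain),
                      x = clPoints(mainCl)[, 1], y = clPoints(mainCl)[, 2],
                      z = clPoints(mainCl)[, 3],
                      parent = c(NA_integer_, seq_len(nMain - 1)),
                      label = "LAD")
  if (config@nArteries > 1L) {
    branch <- .denseBranchCenterline(main$points, main$arc, config)
    rb <- 0.65 * config@baselineRadiusMM
    samples <- rbind(samples, cbind(branch$points, rb))
    bcl <- resampleCenterline(branch$points, label = "side-branch")
    bp <- clPoints(bcl)
    # attach the branch to the nearest main node
    d2 <- colSums((t(nodes[, c("x", "y", "z")]) -
                   main$points[branch$branchIndexMain, ])^2)
    att <- which.min(d2)
    ids <- nMain + seq_len(nrow(bp))
    nodes <- rbind(nodes, data.frame(
      id = ids, x = bp[, 1], y = bp[, 2], z = bp[, 3],
      parent = c(att, ids[-length(ids)]), label = "side-branch"))
  }
  tree <- CenterlineTree(nodes)

  shape <- config@volumeShape
  spacing <- config@voxelSpacing
  lumen <- .rasterTube(samples, shape, spacing)
  calcium <- array(0, shape)
  for (i in seq_along(config@calciumSpec)) {
    cs <- config@calciumSpec[[i]]
    theta0 <- stats::runif(1, -pi, pi)
    active <- abs(main$arc - cs[1]) <= cs[2] / 2
    if (any(active)) {
      calcium <- pmax(calcium,
        .rasterCalciumShell(samples[active, , drop = FALSE], theta0,
                            pi * cs[3], shape, spacing))
    }
  }
  calcium <- calcium * (1 - lumen)
  hu <- config@backgroundHU +
    lumen * (config@lumenHU - config@backgroundHU) +
    calcium * (config@calciumHU - config@backgroundHU)
  noisy <- hu + array(stats::rnorm(length(hu), 0, config@noiseSD), shape)

  # analytic ground truth on the resampled (0.5 mm) main centerline
  sGrid <- (seq_len(nMain) - 1) * 0.5
  red <- stenosisReduction(sGrid, config@stenosisSpec)
  rGrid <- config@baselineRadiusMM * sqrt(1 - red)
  areaGT <- pi * rGrid^2
  thick <- .CALCIUM_THICKNESS_MM
  calcAreaGT <- numeric(nMain)
  for (cs in config@calciumSpec) {
    act <- abs(sGrid - cs[1]) <= cs[2] / 2
    calcAreaGT[act] <- calcAreaGT[act] +
      cs[3] * pi * ((rGrid[act] + thick)^2 - rGrid[act]^2)
  }
  lesion <- if (length(config@stenosisSpec) && any(red > 0))
    which.min(areaGT) else NA_integer_
  gt <- new("PhantomGroundTruth", lumenArea = areaGT,
            attenuation = rep(config@lumenHU, nMain),
            calciumArea = calcAreaGT, lesionLocation = as.integer(lesion),
            trueFFR = simulateFFR(areaGT))

  list(volume = ImageVolume(noisy, spacing),
       lumenMask = ImageVolume(array(as.numeric(lumen), shape), spacing),
       calciumMask = ImageVolume(array(as.numeric(calcium), shape), spacing),
       tree = tree, centerline = mainCl, groundTruth = gt)
}

#' Reference characteristics from MPR-resampled segmentation masks
#'
#' Computes the per-slice reference lumen area and calcium area by summing
#' mask pixels in each cross-sectional MPR slice (pixel area 0.01 mm^2 at
#' the 0.1 mm in-plane spacing; resampled partial-volume masks contribute
#' their coverage fraction, clamped to `[0, 1]`), and the mean lumen
#' attenuation as the average image intensity within the binarized
#' (>= 0.5) lumen mask of each slice. A slice with no lumen pixels yields
#' an undefined attenuation, propagated as `NA` and mapped to 0 after
#' normalization (see [applyCharacteristicNorm()]).
#'
#' @param mprLumenMask,mprCalciumMask [MPRVolume-class] objects obtained by
#'   reconstructing the mask volumes along the same centerline as `mprImage`.
#' @param mprImage the intensity [MPRVolume-class].
#' @return A [CharacteristicProfile-class] (bifurcation and main-branch
#'   flags are left at their defaults; see [extractTreeCharacteristics()]).
#' @export
referenceCharacteristics <- function(mprLumenMask, mprCalciumMask, mprImage) {
  geoOf <- function(m) c(dim(mprData(m)), m@inplaneSpacing, m@sliceSpacing)
  if (!isTRUE(all.equal(geoOf(mprLumenMask), geoOf(mprImage))) ||
      !isTRUE(all.equal(geoOf(mprCalciumMask), geoOf(mprImage))) ||
      max(abs(mprLumenMask@centers - mprImage@centers)) > 1e-6)
    stop("masks and image must share the same MPR geometry")
  px <- mprImage@inplaneSpacing^2
  S <- nSlices(mprImage)
  lumF <- pmin(pmax(mprData(mprLumenMask), 0), 1)
  calF <- pmin(pmax(mprData(mprCalciumMask), 0), 1)
  lum <- lumF >= 0.5
  img <- mprData(mprImage)
  lumenAreaPerSlice <- apply(lumF, 3, sum) * px
  calciumAreaPerSlice <- apply(calF, 3, sum) * px
  att <- vapply(seq_len(S), function(i) {
    m <- lum[, , i]
    if (!any(m)) NA_real_ else mean(img[, , i][m])
  }, numeric(1))
  CharacteristicProfile(lumenAreaPerSlice, att, calciumAreaPerSlice)
}
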