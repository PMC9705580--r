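#' @import methods
NULL

# -- imaging -----------------------------------------------------------------

#' 3D image volume in Hounsfield units
#'
#' A minimal container for a CT volume: a 3D intensity array with physical
#' voxel spacing and origin in millimetres. Coordinates of voxel
#' `(i, j, k)` (1-based) are `origin + (c(i, j, k) - 1) * spacing`.
#'
#' @slot data 3D numeric array of intensities (HU).
#' @slot spacing numeric(3), voxel spacing in mm per axis (strictly positive).
#' @slot origin numeric(3), position of the first voxel centre in mm.
#' @export
setClass("ImageVolume",
  representation(data = "array", spacing = "numeric", origin = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(dim(object@data)) != 3L)
      msg <- c(msg, "data must be a 3D array")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      msg <- c(msg, "spacing must be 3 strictly positive values")
    if (length(object@origin) != 3L)
      msg <- c(msg, "origin must have length 3")
    if (is.null(msg)) TRUE else msg
  })

#' Construct an ImageVolume
#'
#' @param data 3D numeric array (HU).
#' @param spacing voxel spacing in mm (length 3).
#' @param origin position of the first voxel centre in mm (length 3).
#' @return An [ImageVolume-class] object.
#' @export
ImageVolume <- function(data, spacing, origin = c(0, 0, 0)) {
  new("ImageVolume", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

# -- centerlines -------------------------------------------------------------

#' Labeled coronary centerline tree
#'
#' Nodes of a coronary centerline tree with parent/child topology and
#' anatomical segment labels. The tree is acyclic, every non-root node has
#' exactly one parent, and labels are one of `LM`, `LAD`, `LCX`, `RCA` or
#' `side-branch`.
#'
#' @slot nodes data.frame with columns `id` (integer), `x`, `y`, `z`
#'   (positions in mm), `parent` (integer id or `NA` for a root) and
#'   `label` (character).
#' @export
setClass("CenterlineTree",
  representation(nodes = "data.frame"),
  validity = function(object) {
    nd <- object@nodes
    need <- c("id", "x", "y", "z", "parent", "label")
    if (!all(need %in% names(nd)))
      return(paste("nodes must have columns", paste(need, collapse = ", ")))
    if (anyDuplicated(nd$id)) return("node ids must be unique")
    if (!any(is.na(nd$parent))) return("tree must have at least one root")
    known <- c("LM", "LAD", "LCX", "RCA", "side-branch")
    if (!all(nd$label %in% known))
      return(paste("labels must be one of", paste(known, collapse = ", ")))
    nonroot <- nd$parent[!is.na(nd$parent)]
    if (!all(nonroot %in% nd$id)) return("parent ids must reference nodes")
    # acyclicity: walk each node to a root, bounded by node count
    idx <- match(nd$parent, nd$id)
    for (i in seq_len(nrow(nd))) {
      j <- i; steps <- 0L
      while (!is.na(idx[j])) {
        j <- idx[j]; steps <- steps + 1L
        if (steps > nrow(nd)) return("tree contains a cycle")
      }
    }
    TRUE
  })

#' Construct a CenterlineTree
#' @param nodes data.frame with columns `id`, `x`, `y`, `z`, `parent`, `label`.
#' @return A [CenterlineTree-class] object.
#' @export
CenterlineTree <- function(nodes) new("CenterlineTree", nodes = nodes)

#' Resampled artery centerline
#'
#' An ordered polyline from ostium to distal end resampled at a fixed
#' arc-length step (0.5 mm for MPR reconstruction), carrying the anatomical
#' segment label and the successor count of the nearest tree node at each
#' point.
#'
#' @slot points numeric matrix (n x 3) of positions in mm.
#' @slot labels character vector, anatomical label per point.
#' @slot nsucc integer vector, number of child nodes of the mapped tree node.
#' @slot spacing arc-length step between consecutive points in mm.
#' @export
setClass("ArteryCenterline",
  representation(points = "matrix", labels = "character", nsucc = "integer",
                 spacing = "numeric"),
  validity = function(object) {
    n <- nrow(object@points)
    if (ncol(object@points) != 3L) return("points must be n x 3")
    if (n < 3L) return("centerline needs at least 3 points")
    if (length(object@labels) != n || length(object@nsucc) != n)
      return("labels and nsucc must match point count")
    d <- sqrt(rowSums((object@points[-1, , drop = FALSE] -
                       object@points[-n, , drop = FALSE])^2))
    if (any(abs(d - object@spacing) > 1e-6))
      return("consecutive point distance must equal spacing within 1e-6")
    TRUE
  })

#' Straightened multiplanar reformation of an artery
#'
#' A stack of 127 x 127 cross-sections with 0.1 mm in-plane spacing sampled
#' perpendicular to the artery centerline every 0.5 mm, together with the
#' per-slice orthonormal frame (tangent and two in-plane axes) used for
#' sampling. Pixel (64, 64) (1-based) of every slice is the centerline
#' point.
#'
#' @slot data numeric array (127 x 127 x S) of interpolated intensities.
#' @slot inplaneSpacing in-plane pixel size in mm (0.1).
#' @slot sliceSpacing distance between slices in mm (0.5).
#' @slot centers numeric matrix (S x 3), centerline points in mm.
#' @slot tangents numeric matrix (S x 3), unit tangents.
#' @slot normals numeric matrix (S x 3), first in-plane unit axis.
#' @slot binormals numeric matrix (S x 3), second in-plane unit axis.
#' @slot fillFraction fraction of sampled points outside the volume that
#'   were filled with -1024 HU.
#' @export
setClass("MPRVolume",
  representation(data = "array", inplaneSpacing = "numeric",
                 sliceSpacing = "numeric", centers = "matrix",
                 tangents = "matrix", normals = "matrix",
                 binormals = "matrix", fillFraction = "numeric"),
  validity = function(object) {
    d <- dim(object@data)
    if (length(d) != 3L) return("data must be a 3D array (H x W x S)")
    S <- d[3]
    for (nm in c("centers", "tangents", "normals", "binormals")) {
      m <- slot(object, nm)
      if (nrow(m) != S || ncol(m) != 3L)
        return(sprintf("%s must be S x 3", nm))
    }
    # frames orthonormal to 1e-9
    t. <- object@tangents; n. <- object@normals; b. <- object@binormals
    if (max(abs(rowSums(t.^2) - 1), abs(rowSums(n.^2) - 1),
            abs(rowSums(b.^2) - 1), abs(rowSums(t. * n.)),
            abs(rowSums(t. * b.)), abs(rowSums(n. * b.))) > 1e-9)
      return("per-slice frames must be orthonormal to 1e-9")
    TRUE
  })

# -- characteristics ---------------------------------------------------------

#' Per-slice artery characteristics
#'
#' The five per-cross-section artery characteristics consumed by the
#' stenosis-assessment network: lumen area (mm^2), mean lumen attenuation
#' (HU), calcium area (mm^2), a binary bifurcation indicator and a binary
#' main-branch indicator. All five series share the same length (the MPR
#' slice count).
#'
#' @slot lumenArea numeric vector (mm^2).
#' @slot attenuation numeric vector (HU).
#' @slot calciumArea numeric vector (mm^2).
#' @slot bifurcation numeric vector in \{0, 1\}.
#' @slot mainBranch numeric vector in \{0, 1\}.
#' @export
setClass("CharacteristicProfile",
  representation(lumenArea = "numeric", attenuation = "numeric",
                 calciumArea = "numeric", bifurcation = "numeric",
                 mainBranch = "numeric"),
  validity = function(object) {
    n <- length(object@lumenArea)
    if (any(c(length(object@attenuation), length(object@calciumArea),
              length(object@bifurcation), length(object@mainBranch)) != n))
      return("all five series must share the same length")
    if (!all(object@bifurcation %in% c(0, 1)) ||
        !all(object@mainBranch %in% c(0, 1)))
      return("bifurcation and mainBranch flags must be binary")
    TRUE
  })

#' Construct a CharacteristicProfile
#'
#' @param lumenArea,attenuation,calciumArea per-slice series.
#' @param bifurcation,mainBranch binary per-slice flags (default 0 / 1).
#' @return A [CharacteristicProfile-class] object.
#' @export
CharacteristicProfile <- function(lumenArea, attenuation, calciumArea,
                                  bifurcation = rep(0, length(lumenArea)),
                                  mainBranch = rep(1, length(lumenArea))) {
  new("CharacteristicProfile", lumenArea = as.numeric(lumenArea),
      attenuation = as.numeric(attenuation),
      calciumArea = as.numeric(calciumArea),
      bifurcation = as.numeric(bifurcation),
      mainBranch = as.numeric(mainBranch))
}

#' Normalization statistics
#'
#' Mean and standard deviation fitted on a training corpus and re-applied
#' unchanged at test time, either to pooled MPR intensities (a single
#' entry) or per artery characteristic (five named entries).
#'
#' @slot mean named numeric vector.
#' @slot sd named numeric vector, same names, strictly positive.
#' @export
setClass("NormalizationStats",
  representation(mean = "numeric", sd = "numeric"),
  validity = function(object) {
    if (length(object@mean) != length(object@sd))
      return("mean and sd must have equal length")
    if (any(object@sd <= 0)) return("sd must be strictly positive")
    TRUE
  })

#' @rdname NormalizationStats-class
#' @param mean,sd named numeric vectors.
#' @export
NormalizationStats <- function(mean, sd) {
  new("NormalizationStats", mean = mean, sd = sd)
}

# -- references and predictions ----------------------------------------------

#' Invasive FFR reference for one artery
#'
#' @slot ffr measured fractional flow reserve, in (0, 1].
#' @slot label logical, `TRUE` iff `ffr <= 0.8` (functionally significant).
#' @slot lesionLocation integer slice index (1-based) of the most severe
#'   stenosis, or `NA` when no lesion was annotated.
#' @slot measurementIndex integer slice index of the assumed pressure-wire
#'   measurement location.
#' @export
setClass("FFRReference",
  representation(ffr = "numeric", label = "logical",
                 lesionLocation = "integer", measurementIndex = "integer"),
  validity = function(object) {
    if (object@ffr <= 0 || object@ffr > 1) return("ffr must be in (0, 1]")
    if (object@label != (object@ffr <= 0.8))
      return("label inconsistent with ffr and the 0.8 threshold")
    TRUE
  })

#' @rdname FFRReference-class
#' @param ffr measured FFR.
#' @param lesionLocation slice index of the most severe stenosis or `NA`.
#' @param measurementIndex slice index of the measurement location.
#' @export
FFRReference <- function(ffr, lesionLocation = NA_integer_,
                         measurementIndex = NA_integer_) {
  new("FFRReference", ffr = ffr, label = ffr <= 0.8,
      lesionLocation = as.integer(lesionLocation),
      measurementIndex = as.integer(measurementIndex))
}

#' Stenosis-assessment prediction for one artery
#'
#' Holds the regressed FFR, the classification probability, the
#' pseudo-probability derived from the regressed FFR, their merged
#' probability, and (for ensembles) the spread of the members.
#'
#' @slot ffrRegressed regressed FFR (at most 1 by construction).
#' @slot probClass classification-head probability in `[0, 1]`.
#' @slot probPseudo pseudo-probability in `[0, 1]`.
#' @slot probMerged mean of `probClass` and `probPseudo`.
#' @slot uncertaintyProb sd of merged probability across ensemble members
#'   (`NA` for a single model).
#' @slot uncertaintyFFR sd of regressed FFR across ensemble members.
#' @export
setClass("Prediction",
  representation(ffrRegressed = "numeric", probClass = "numeric",
                 probPseudo = "numeric", probMerged = "numeric",
                 uncertaintyProb = "numeric", uncertaintyFFR = "numeric"),
  validity = function(object) {
    p <- c(object@probClass, object@probPseudo, object@probMerged)
    if (any(p < 0 | p > 1)) return("probabilities must lie in [0, 1]")
    if (object@ffrRegressed > 1 + 1e-12) return("ffrRegressed must be <= 1")
    u <- c(object@uncertaintyProb, object@uncertaintyFFR)
    if (any(!is.na(u) & u < 0)) return("uncertainties must be >= 0")
    TRUE
  })

#' @rdname Prediction-class
#' @param ffrRegressed,probClass,probPseudo,probMerged scalar outputs.
#' @param uncertaintyProb,uncertaintyFFR ensemble spreads (NA for one model).
#' @export
Prediction <- function(ffrRegressed, probClass, probPseudo, probMerged,
                       uncertaintyProb = NA_real_,
                       uncertaintyFFR = NA_real_) {
  new("Prediction", ffrRegressed = as.numeric(ffrRegressed),
      probClass = as.numeric(probClass),
      probPseudo = as.numeric(probPseudo),
      probMerged = as.numeric(probMerged),
      uncertaintyProb = as.numeric(uncertaintyProb),
      uncertaintyFFR = as.numeric(uncertaintyFFR))
}

# -- phantoms ----------------------------------------------------------------

#' Configuration of a synthetic vessel phantom
#'
#' Describes one contrast-filled tubular artery embedded in soft-tissue
#' background: grid geometry, HU levels, noise, tree complexity, and focal
#' stenoses / calcified-plaque lesions along the vessel. All phantom
#' distributions are artifact choices of this package, not estimates from
#' any clinical dataset; defaults sit inside typical CCTA acquisition
#' ranges (contrast lumen ~400 HU, soft tissue ~50 HU, calcium ~800 HU).
#'
#' @slot volumeShape integer(3), voxels per axis.
#' @slot voxelSpacing numeric(3), mm per axis.
#' @slot lumenHU,backgroundHU,calciumHU mean HU of lumen, tissue, plaque.
#' @slot noiseSD additive Gaussian HU noise.
#' @slot nArteries number of branches (1 = unbranched; 2 adds a side branch).
#' @slot arteryLengthMM main artery length in mm.
#' @slot baselineRadiusMM unobstructed lumen radius in mm.
#' @slot stenosisSpec list of `c(center_mm, length_mm, reduction)` with
#'   fractional area reduction in `[0, 0.95]`.
#' @slot calciumSpec list of `c(center_mm, length_mm, arc_fraction)`.
#' @slot seed RNG seed.
#' @export
setClass("PhantomConfig",
  representation(volumeShape = "integer", voxelSpacing = "numeric",
                 lumenHU = "numeric", backgroundHU = "numeric",
                 calciumHU = "numeric", noiseSD = "numeric",
                 nArteries = "integer", arteryLengthMM = "numeric",
                 baselineRadiusMM = "numeric", stenosisSpec = "list",
                 calciumSpec = "list", seed = "integer"),
  validity = function(object) {
    if (object@baselineRadiusMM <= 0) return("baselineRadiusMM must be > 0")
    if (any(object@voxelSpacing <= 0)) return("voxelSpacing must be > 0")
    for (s in object@stenosisSpec) {
      if (length(s) != 3) return("stenosisSpec entries are (center, length, reduction)")
      if (s[3] < 0 || s[3] > 0.95)
        return("fractional area reduction must be in [0, 0.95]")
      if (s[1] < 0 || s[1] > object@arteryLengthMM)
        return("stenosis center must lie within the artery length")
    }
    for (s in object@calciumSpec) {
      if (length(s) != 3) return("calciumSpec entries are (center, length, arc_fraction)")
      if (s[3] < 0 || s[3] > 1) return("arc fraction must be in [0, 1]")
      if (s[1] < 0 || s[1] > object@arteryLengthMM)
        return("calcium center must lie within the artery length")
    }
    TRUE
  })

#' Construct a PhantomConfig
#'
#' @param volumeShape voxels per axis; default is sized to hold the artery.
#' @param voxelSpacing mm per axis.
#' @param lumenHU,backgroundHU,calciumHU,noiseSD HU levels and noise sd.
#' @param nArteries 1 or 2 (2 adds one side branch).
#' @param arteryLengthMM,baselineRadiusMM main-vessel geometry in mm.
#' @param stenosisSpec list of `c(center_mm, length_mm, reduction)`.
#' @param calciumSpec list of `c(center_mm, length_mm, arc_fraction)`.
#' @param seed RNG seed.
#' @return A [PhantomConfig-class] object.
#' @export
phantomConfig <- function(volumeShape = NULL, voxelSpacing = c(0.3, 0.3, 0.3),
                          lumenHU = 400, backgroundHU = 50, calciumHU = 800,
                          noiseSD = 20, nArteries = 1L, arteryLengthMM = 40,
                          baselineRadiusMM = 1.4, stenosisSpec = list(),
                          calciumSpec = list(), seed = 1L) {
  if (is.null(volumeShape)) {
    # lateral extent covers the 12.7 mm MPR plane around a centerline that
    # may wander +-2 mm, plus room for a side branch if present
    pad <- 16 + if (nArteries > 1) 10 else 0
    lateral <- ceiling((2 * baselineRadiusMM + pad) / voxelSpacing[1:2])
    axial <- ceiling((arteryLengthMM + 8) / voxelSpacing[3])
    volumeShape <- as.integer(c(lateral, axial))
  }
  new("PhantomConfig", volumeShape = as.integer(volumeShape),
      voxelSpacing = as.numeric(voxelSpacing), lumenHU = lumenHU,
      backgroundHU = backgroundHU, calciumHU = calciumHU, noiseSD = noiseSD,
      nArteries = as.integer(nArteries), arteryLengthMM = arteryLengthMM,
      baselineRadiusMM = baselineRadiusMM, stenosisSpec = stenosisSpec,
      calciumSpec = calciumSpec, seed = as.integer(seed))
}

#' Analytic ground truth of a phantom artery
#'
#' Per-slice true lumen area, mean lumen attenuation and calcium area
#' computed from the phantom's tube geometry (not from voxel masks),
#' together with the lesion location and the toy-model FFR label.
#'
#' @slot lumenArea,attenuation,calciumArea per-slice series (0.5 mm step).
#' @slot lesionLocation slice index of the most severe stenosis, `NA` if none.
#' @slot trueFFR toy-model FFR in (0, 1].
#' @export
setClass("PhantomGroundTruth",
  representation(lumenArea = "numeric", attenuation = "numeric",
                 calciumArea = "numeric", lesionLocation = "integer",
                 trueFFR = "numeric"),
  validity = function(object) {
    if (any(object@lumenArea < 0) || any(object@calciumArea < 0))
      return("areas must be >= 0")
    if (object@trueFFR <= 0 || object@trueFFR > 1)
      return("trueFFR must be in (0, 1]")
    if (!is.na(object@lesionLocation) &&
        (object@lesionLocation < 1 ||
         object@lesionLocation > length(object@lumenArea)))
      return("lesionLocation must index into the profile")
    TRUE
  })
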