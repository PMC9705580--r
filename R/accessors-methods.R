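# Accessors and show() methods.

#' @describeIn ImageVolume-class intensity array
#' @param x object
#' @export
setMethod("volumeData", "ImageVolume", function(x) x@data)
#' @describeIn ImageVolume-class voxel spacing in mm
#' @export
setMethod("voxelSpacing", "ImageVolume", function(x) x@spacing)
#' @describeIn ImageVolume-class origin in mm
#' @export
setMethod("volumeOrigin", "ImageVolume", function(x) x@origin)

#' @describeIn CenterlineTree-class node table
#' @param x object
#' @export
setMethod("treeNodes", "CenterlineTree", function(x) x@nodes)

#' @describeIn ArteryCenterline-class point matrix (n x 3, mm)
#' @param x object
#' @export
setMethod("clPoints", "ArteryCenterline", function(x) x@points)
#' @describeIn ArteryCenterline-class per-point anatomical labels
#' @export
setMethod("clLabels", "ArteryCenterline", function(x) x@labels)
#' @describeIn ArteryCenterline-class per-point successor counts
#' @export
setMethod("clSuccessors", "ArteryCenterline", function(x) x@nsucc)

#' @describeIn MPRVolume-class intensity stack (127 x 127 x S)
#' @param x object
#' @export
setMethod("mprData", "MPRVolume", function(x) x@data)
#' @describeIn MPRVolume-class number of slices
#' @export
setMethod("nSlices", "MPRVolume", function(x) dim(x@data)[3])

#' @describeIn CharacteristicProfile-class number of slices
#' @export
setMethod("nSlices", "CharacteristicProfile",
          function(x) length(x@lumenArea))
#' @describeIn CharacteristicProfile-class lumen area series (mm^2)
#' @param x object
#' @export
setMethod("lumenArea", "CharacteristicProfile", function(x) x@lumenArea)
#' @describeIn CharacteristicProfile-class mean lumen attenuation series (HU)
#' @export
setMethod("attenuation", "CharacteristicProfile", function(x) x@attenuation)
#' @describeIn CharacteristicProfile-class calcium area series (mm^2)
#' @export
setMethod("calciumArea", "CharacteristicProfile", function(x) x@calciumArea)
#' @describeIn CharacteristicProfile-class binary bifurcation indicator
#' @export
setMethod("bifurcationFlags", "CharacteristicProfile",
          function(x) x@bifurcation)
#' @describeIn CharacteristicProfile-class binary main-branch indicator
#' @export
setMethod("mainBranchFlags", "CharacteristicProfile", function(x) x@mainBranch)

#' @describeIn PhantomGroundTruth-class true lumen area series (mm^2)
#' @param x object
#' @export
setMethod("lumenArea", "PhantomGroundTruth", function(x) x@lumenArea)
#' @describeIn PhantomGroundTruth-class true attenuation series (HU)
#' @export
setMethod("attenuation", "PhantomGroundTruth", function(x) x@attenuation)
#' @describeIn PhantomGroundTruth-class true calcium area series (mm^2)
#' @export
setMethod("calciumArea", "PhantomGroundTruth", function(x) x@calciumArea)
#' @describeIn PhantomGroundTruth-class slice index of most severe stenosis
#' @export
setMethod("lesionLocation", "PhantomGroundTruth",
          function(x) x@lesionLocation)
#' @describeIn PhantomGroundTruth-class toy-model FFR
#' @export
setMethod("trueFFR", "PhantomGroundTruth", function(x) x@trueFFR)

#' @describeIn NormalizationStats-class fitted means
#' @param x object
#' @export
setMethod("statsMean", "NormalizationStats", function(x) x@mean)
#' @describeIn NormalizationStats-class fitted standard deviations
#' @export
setMethod("statsSd", "NormalizationStats", function(x) x@sd)

#' @describeIn FFRReference-class measured FFR
#' @param x object
#' @export
setMethod("ffrValue", "FFRReference", function(x) x@ffr)
#' @describeIn FFRReference-class slice index of annotated lesion (NA if none)
#' @export
setMethod("lesionLocation", "FFRReference", function(x) x@lesionLocation)
#' @describeIn FFRReference-class assumed measurement slice index
#' @export
setMethod("measurementIndex", "FFRReference", function(x) x@measurementIndex)

#' @describeIn Prediction-class regressed FFR
#' @param x object
#' @export
setMethod("ffrRegressed", "Prediction", function(x) x@ffrRegressed)
#' @describeIn Prediction-class classification-head probability
#' @export
setMethod("probClass", "Prediction", function(x) x@probClass)
#' @describeIn Prediction-class pseudo-probability from regressed FFR
#' @export
setMethod("probPseudo", "Prediction", function(x) x@probPseudo)
#' @describeIn Prediction-class merged probability
#' @export
setMethod("probMerged", "Prediction", function(x) x@probMerged)
#' @describeIn Prediction-class ensemble sd of merged probability
#' @export
setMethod("uncertaintyProb", "Prediction", function(x) x@uncertaintyProb)
#' @describeIn Prediction-class ensemble sd of regressed FFR
#' @export
setMethod("uncertaintyFFR", "Prediction", function(x) x@uncertaintyFFR)

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("ImageVolume %d x %d x %d voxels, spacing %s mm, HU range [%g, %g]\n",
              d[1], d[2], d[3],
              paste(format(object@spacing, digits = 3), collapse = " x "),
              min(object@data), max(object@data)))
})

setMethod("show", "CenterlineTree", function(object) {
  nd <- object@nodes
  cat(sprintf("CenterlineTree with %d nodes (%d root%s); labels: %s\n",
              nrow(nd), sum(is.na(nd$parent)),
              if (sum(is.na(nd$parent)) == 1) "" else "s",
              paste(unique(nd$label), collapse = ", ")))
})

setMethod("show", "ArteryCenterline", function(object) {
  cat(sprintf("ArteryCenterline: %d points at %.3g mm spacing (%.1f mm)\n",
              nrow(object@points), object@spacing,
              (nrow(object@points) - 1) * object@spacing))
})

setMethod("show", "MPRVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("MPRVolume: %d slices of %d x %d px (%.2g mm in-plane, %.2g mm between slices)\n",
              d[3], d[1], d[2], object@inplaneSpacing, object@sliceSpacing))
  if (object@fillFraction > 0)
    cat(sprintf("  %.2f%% of samples outside the volume (filled with -1024 HU)\n",
                100 * object@fillFraction))
})

setMethod("show", "CharacteristicProfile", function(object) {
  cat(sprintf("CharacteristicProfile over %d slices; lumen area %.2f-%.2f mm^2, calcium present in %d slices\n",
              length(object@lumenArea), min(object@lumenArea),
              max(object@lumenArea), sum(object@calciumArea > 0)))
})

setMethod("show", "NormalizationStats", function(object) {
  cat("NormalizationStats:\n")
  print(data.frame(mean = object@mean, sd = object@sd))
})

setMethod("show", "FFRReference", function(object) {
  cat(sprintf("FFRReference: FFR %.3f (%s), lesion slice %s, measurement slice %s\n",
              object@ffr,
              if (object@label) "functionally significant" else "not significant",
              ifelse(is.na(object@lesionLocation), "none",
                     object@lesionLocation),
              ifelse(is.na(object@measurementIndex), "NA",
                     object@measurementIndex)))
})

setMethod("show", "Prediction", function(object) {
  cat(sprintf("Prediction: FFR %.3f | p(class) %.3f | p(pseudo) %.3f | p(merged) %.3f\n",
              object@ffrRegressed, object@probClass, object@probPseudo,
              object@probMerged))
  if (!is.na(object@uncertaintyProb))
    cat(sprintf("  ensemble sd: prob %.4f, FFR %.4f\n",
                object@uncertaintyProb, object@uncertaintyFFR))
})

setMethod("show", "PhantomGroundTruth", function(object) {
  cat(sprintf("PhantomGroundTruth: %d slices, min lumen area %.2f mm^2, true FFR %.3f\n",
              length(object@lumenArea), min(object@lumenArea), object@trueFFR))
})

setMethod("show", "PhantomConfig", function(object) {
  cat(sprintf("PhantomConfig: %s voxels @ %s mm; artery %.0f mm, r0 %.2f mm; %d stenosis(es), %d calcium lesion(s)\n",
              paste(object@volumeShape, collapse = "x"),
              paste(object@voxelSpacing, collapse = "x"),
              object@arteryLengthMM, object@baselineRadiusMM,
              length(object@stenosisSpec), length(object@calciumSpec)))
})
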