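# Generics for the core containers. Accessor-style API; no direct slot
# access is expected from user code.

#' @export
setGeneric("volumeData", function(x) standardGeneric("volumeData"))
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @export
setGeneric("volumeOrigin", function(x) standardGeneric("volumeOrigin"))
#' @export
setGeneric("clPoints", function(x) standardGeneric("clPoints"))
#' @export
setGeneric("clLabels", function(x) standardGeneric("clLabels"))
#' @export
setGeneric("clSuccessors", function(x) standardGeneric("clSuccessors"))
#' @export
setGeneric("treeNodes", function(x) standardGeneric("treeNodes"))
#' @export
setGeneric("mprData", function(x) standardGeneric("mprData"))
#' @export
setGeneric("nSlices", function(x) standardGeneric("nSlices"))
#' @export
setGeneric("lumenArea", function(x) standardGeneric("lumenArea"))
#' @export
setGeneric("attenuation", function(x) standardGeneric("attenuation"))
#' @export
setGeneric("calciumArea", function(x) standardGeneric("calciumArea"))
#' @export
setGeneric("bifurcationFlags", function(x) standardGeneric("bifurcationFlags"))
#' @export
setGeneric("mainBranchFlags", function(x) standardGeneric("mainBranchFlags"))
#' @export
setGeneric("statsMean", function(x) standardGeneric("statsMean"))
#' @export
setGeneric("statsSd", function(x) standardGeneric("statsSd"))
#' @export
setGeneric("trueFFR", function(x) standardGeneric("trueFFR"))
#' @export
setGeneric("lesionLocation", function(x) standardGeneric("lesionLocation"))
#' @export
setGeneric("measurementIndex", function(x) standardGeneric("measurementIndex"))
#' @export
setGeneric("ffrValue", function(x) standardGeneric("ffrValue"))
#' @export
setGeneric("ffrRegressed", function(x) standardGeneric("ffrRegressed"))
#' @export
setGeneric("probClass", function(x) standardGeneric("probClass"))
#' @export
setGeneric("probPseudo", function(x) standardGeneric("probPseudo"))
#' @export
setGeneric("probMerged", function(x) standardGeneric("probMerged"))
#' @export
setGeneric("uncertaintyProb", function(x) standardGeneric("uncertaintyProb"))
#' @export
setGeneric("uncertaintyFFR", function(x) standardGeneric("uncertaintyFFR"))
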