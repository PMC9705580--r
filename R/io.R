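# Readers and writers for the pipeline's on-disk formats: NIfTI volumes
# (via RNifti, spacing in the header), centerline trees and normalization
# statistics as JSON, profiles / ground truth / predictions as CSV, and
# model checkpoints as RDS.

#' Write an ImageVolume as NIfTI
#' @param volume an [ImageVolume-class].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return The path, invisibly.
#' @export
writeImageVolume <- function(volume, path) {
  img <- RNifti::asNifti(volumeData(volume))
  RNifti::pixdim(img) <- voxelSpacing(volume)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read an ImageVolume from NIfTI
#' @param path NIfTI file.
#' @return An [ImageVolume-class] (origin at 0).
#' @export
readImageVolume <- function(path) {
  img <- RNifti::readNifti(path)
  ImageVolume(array(as.numeric(img), dim(img)), RNifti::pixdim(img))
}

#' Write an MPR stack as NIfTI (spacing 0.1 x 0.1 x 0.5 mm)
#' @param mpr an [MPRVolume-class].
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeMPR <- function(mpr, path) {
  img <- RNifti::asNifti(mprData(mpr))
  RNifti::pixdim(img) <- c(mpr@inplaneSpacing, mpr@inplaneSpacing,
                           mpr@sliceSpacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a centerline tree as JSON
#'
#' Nodes are serialized as objects with `id`, `xyz` (mm), `parent`
#' (`null` for a root) and `label`.
#'
#' @param tree a [CenterlineTree-class].
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeCenterlineTree <- function(tree, path) {
  nd <- treeNodes(tree)
  nodes <- lapply(seq_len(nrow(nd)), function(i) list(
    id = nd$id[i], xyz = c(nd$x[i], nd$y[i], nd$z[i]),
    parent = if (is.na(nd$parent[i])) NULL else nd$parent[i],
    label = nd$label[i]))
  jsonlite::write_json(list(nodes = nodes), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a centerline tree from JSON
#' @param path JSON file written by [writeCenterlineTree()].
#' @return A [CenterlineTree-class].
#' @export
readCenterlineTree <- function(path) {
  js <- jsonlite::read_json(path)
  nd <- do.call(rbind, lapply(js$nodes, function(n) data.frame(
    id = as.integer(n$id), x = n$xyz[[1]], y = n$xyz[[2]], z = n$xyz[[3]],
    parent = if (length(n$parent) == 0) NA_integer_
             else as.integer(n$parent),
    label = n$label)))
  CenterlineTree(nd)
}

#' Persist normalization statistics as JSON
#' @param stats a [NormalizationStats-class].
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeNormalizationStats <- function(stats, path) {
  jsonlite::write_json(list(mean = as.list(statsMean(stats)),
                            sd = as.list(statsSd(stats))),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read normalization statistics from JSON
#' @param path JSON file written by [writeNormalizationStats()].
#' @return A [NormalizationStats-class].
#' @export
readNormalizationStats <- function(path) {
  js <- jsonlite::read_json(path)
  NormalizationStats(mean = unlist(js$mean), sd = unlist(js$sd))
}

#' Write a characteristic profile as CSV
#' @param profile a [CharacteristicProfile-class].
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeProfileCSV <- function(profile, path) {
  utils::write.csv(data.frame(slice = seq_len(nSlices(profile)),
                              .profileMatrix(profile)),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a characteristic profile from CSV
#' @param path CSV written by [writeProfileCSV()].
#' @return A [CharacteristicProfile-class].
#' @export
readProfileCSV <- function(path) {
  d <- utils::read.csv(path)
  CharacteristicProfile(d$lumenArea, d$attenuation, d$calciumArea,
                        d$bifurcation, d$mainBranch)
}

#' Write phantom ground truth (per-slice CSV + per-artery JSON)
#'
#' @param gt a [PhantomGroundTruth-class].
#' @param csvPath per-slice table (slice, areas, attenuation).
#' @param jsonPath per-artery record (`true_ffr`, `lesion_location`).
#' @return `csvPath`, invisibly.
#' @export
writeGroundTruth <- function(gt, csvPath, jsonPath) {
  utils::write.csv(data.frame(
    slice = seq_along(lumenArea(gt)), lumenArea = lumenArea(gt),
    attenuation = attenuation(gt), calciumArea = calciumArea(gt)),
    csvPath, row.names = FALSE)
  jsonlite::write_json(
    list(true_ffr = trueFFR(gt),
         lesion_location = if (is.na(lesionLocation(gt))) NULL
                           else lesionLocation(gt)),
    jsonPath, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(csvPath)
}

#' Save / load a model checkpoint
#'
#' Checkpoints embed the configuration and any normalization statistics
#' carried by the model. RDS is used for weights; checkpoints are run-time
#' artifacts, not package data.
#'
#' @param model a [CharacterizerModel-class], [StenosisNetModel-class] or
#'   an ensemble list from [crossvalTrain()].
#' @param path output path (`.rds`).
#' @return The path, invisibly.
#' @export
saveModel <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) readRDS(path)

#' Metrics report as a plain list / JSON
#' @param report a [MetricsReport-class].
#' @param path optional JSON output path.
#' @return The list, invisibly when writing.
#' @export
metricsAsList <- function(report, path = NULL) {
  x <- list(auc = report@auc, accuracy = report@accuracy,
            sensitivity = report@sensitivity,
            specificity = report@specificity,
            n_arteries = report@nArteries, n_positive = report@nPositive,
            threshold = report@threshold)
  if (!is.null(path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null")
    return(invisible(x))
  }
  x
}
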