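# Bifurcation and main/side-branch characteristics from the centerline
# tree, and normalization of the five artery characteristics.

#' Extract bifurcation and main-branch series for an artery
#'
#' Maps every resampled artery centerline point to its nearest tree node
#' (within 1.0 mm) and derives two binary series: `bifurcation[i] = 1` iff
#' the mapped node has two or more children (trifurcations count as
#' bifurcations), and `mainBranch[i] = 1` iff the node's anatomical label
#' is one of LM, LAD, LCX, RCA.
#'
#' @param tree a [CenterlineTree-class].
#' @param artery an [ArteryCenterline-class].
#' @param tol maximum point-to-node mapping distance in mm.
#' @return List with numeric vectors `bifurcation` and `mainBranch`.
#' @export
extractTreeCharacteristics <- function(tree, artery, tol = 1.0) {
  nd <- treeNodes(tree)
  pts <- clPoints(artery)
  nodePos <- as.matrix(nd[, c("x", "y", "z")])
  nChild <- table(factor(nd$parent[!is.na(nd$parent)], levels = nd$id))
  nearest <- integer(nrow(pts))
  dist <- numeric(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    d2 <- colSums((t(nodePos) - pts[i, ])^2)
    nearest[i] <- which.min(d2)
    dist[i] <- sqrt(min(d2))
  }
  bad <- which(dist > tol)
  if (length(bad))
    stop(sprintf(
      "artery points not mapped to any tree node within %.1f mm: indices %s",
      tol, paste(utils::head(bad, 10), collapse = ", ")))
  list(bifurcation = as.numeric(nChild[nearest] >= 2),
       mainBranch = as.numeric(nd$label[nearest] %in%
                               c("LM", "LAD", "LCX", "RCA")))
}

.CHAR_NAMES <- c("lumenArea", "attenuation", "calciumArea", "bifurcation",
                 "mainBranch")

.profileMatrix <- function(profile) {
  cbind(lumenArea = lumenArea(profile), attenuation = attenuation(profile),
        calciumArea = calciumArea(profile),
        bifurcation = bifurcationFlags(profile),
        mainBranch = mainBranchFlags(profile))
}

#' Fit normalization statistics for the five artery characteristics
#'
#' Mean and standard deviation per characteristic, pooled over all slices
#' of all training arteries. Undefined attenuation values (`NA`, from
#' slices with no lumen pixels) are excluded from the fit. A characteristic
#' with zero variance (e.g. an all-zero calcium corpus) keeps its mean and
#' gets sd 1, with a warning: degenerate but valid.
#'
#' @param profiles list of [CharacteristicProfile-class] (at least 2).
#' @return A [NormalizationStats-class] with five named entries.
#' @export
fitCharacteristicStats <- function(profiles) {
  if (length(profiles) < 2) stop("need at least 2 training profiles")
  m <- do.call(rbind, lapply(profiles, .profileMatrix))
  mu <- colMeans(m, na.rm = TRUE)
  sd <- sqrt(colMeans(sweep(m, 2, mu)^2, na.rm = TRUE))
  degen <- sd <= 1e-12
  if (any(degen)) {
    warning(sprintf("zero-variance characteristic(s) %s: sd set to 1",
                    paste(.CHAR_NAMES[degen], collapse = ", ")))
    sd[degen] <- 1
  }
  NormalizationStats(mean = mu, sd = sd)
}

#' Normalize a characteristic profile
#'
#' Applies `(x - mean) / sd` per characteristic with training statistics.
#' Undefined attenuation values are mapped to 0 after normalization (the
#' training-corpus mean). The result is a plain numeric matrix because
#' normalized flags are no longer binary.
#'
#' @param profile a [CharacteristicProfile-class].
#' @param stats a [NormalizationStats-class] from
#'   [fitCharacteristicStats()].
#' @return Numeric matrix (S x 5) with the characteristic columns.
#' @export
applyCharacteristicNorm <- function(profile, stats) {
  m <- .profileMatrix(profile)
  mu <- statsMean(stats)[.CHAR_NAMES]
  sd <- statsSd(stats)[.CHAR_NAMES]
  out <- sweep(sweep(m, 2, mu), 2, sd, "/")
  out[is.na(out)] <- 0
  out
}
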