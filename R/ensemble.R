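# Pseudo-probability transformation of regressed FFR values, merging of
# the two heads, patient-level cross-validation ensembling and predictive
# uncertainty.

#' Pseudo-probability of functional significance from a regressed FFR
#'
#' Linearly rescales a symmetric window around the 0.8 decision threshold:
#' `p = 0.5 - (FFR - 0.8) / 0.4` for FFR in `[0.6, 1.0]` and `p = 1` for
#' FFR in `[0, 0.6)`. The transformation is continuous at 0.6, monotone
#' non-increasing, maps 0.8 to 0.5 and 1.0 to 0, and dichotomizing the
#' result at 0.5 is equivalent to dichotomizing the FFR at 0.8.
#'
#' @param ffr regressed FFR value(s). Values above 1 are clipped to 1 and
#'   values below 0 to 0, each with a warning (neither can occur for the
#'   regression head, whose output is 1 minus a non-negative sum).
#' @return Pseudo-probability in `[0, 1]`.
#' @examples
#' pseudoProbability(c(0.8, 0.55, 1.0))  # 0.5, 1.0, 0.0
#' @export
pseudoProbability <- function(ffr) {
  if (any(ffr > 1)) {
    warning("regressed FFR above 1 clipped to 1")
    ffr <- pmin(ffr, 1)
  }
  if (any(ffr < 0)) {
    warning("regressed FFR below 0 clipped to 0")
    ffr <- pmax(ffr, 0)
  }
  ifelse(ffr < 0.6, 1.0, 0.5 - (ffr - 0.8) / 0.4)
}

#' Merge classification and pseudo-probabilities
#'
#' Arithmetic mean of the classification-head probability and the
#' pseudo-probability derived from the regressed FFR.
#'
#' @param probClass,probPseudo probabilities in `[0, 1]`.
#' @return Merged probability.
#' @export
mergeOutputs <- function(probClass, probPseudo) {
  stopifnot(all(probClass >= 0 & probClass <= 1),
            all(probPseudo >= 0 & probPseudo <= 1))
  (probClass + probPseudo) / 2
}

#' Patient-level k-fold cross-validation training
#'
#' Randomly partitions patients (not arteries) into `k` folds and trains
#' one stenosis-assessment network per fold on the remaining 90% of
#' patients. All members share the characteristic-normalization statistics
#' fitted on the full record set, so they can be ensembled.
#'
#' @param records list of artery records (`profile`, `reference`,
#'   `patient`).
#' @param k number of folds (default 10).
#' @param seed RNG seed for the fold assignment and member training.
#' @param config base [stenosisNetConfig()]; member `m` trains with
#'   `seed + m`.
#' @param epochs override of the config epoch count.
#' @param verbose print member progress.
#' @return List with `models` (k trained members), `foldOfPatient` (named
#'   integer), `foldOfRecord` (integer per record), `charStats`.
#' @export
crossvalTrain <- function(records, k = 10L, seed = 1L,
                          config = stenosisNetConfig(), epochs = NULL,
                          verbose = FALSE) {
  patients <- vapply(records, `[[`, numeric(1), "patient")
  up <- unique(patients)
  if (k > length(up))
    stop(sprintf("k = %d exceeds the number of patients (%d)",
                 k, length(up)))
  set.seed(seed)
  foldOfPatient <- stats::setNames(
    sample(rep(seq_len(k), length.out = length(up))), up)
  foldOfRecord <- foldOfPatient[as.character(patients)]
  charStats <- suppressWarnings(
    fitCharacteristicStats(lapply(records, `[[`, "profile")))
  models <- vector("list", k)
  for (m in seq_len(k)) {
    cfg <- config
    cfg$seed <- as.integer(config$seed + m)
    net <- buildStenosisNet(cfg)
    trainRec <- records[foldOfRecord != m]
    if (verbose)
      message(sprintf("fold %d: training on %d arteries", m,
                      length(trainRec)))
    models[[m]] <- trainStenosisNet(net, trainRec, epochs = epochs,
                                    charStats = charStats)
  }
  list(models = models, foldOfPatient = foldOfPatient,
       foldOfRecord = as.integer(foldOfRecord), charStats = charStats)
}

#' Out-of-fold predictions from a cross-validation run
#'
#' Each artery is predicted by the member that did not see its patient
#' during training, giving held-out predictions for the whole record set.
#'
#' @param cv result of [crossvalTrain()].
#' @param records the record list used for training.
#' @return data.frame with patient, artery index, reference FFR/label and
#'   the member's prediction columns.
#' @export
crossvalPredict <- function(cv, records) {
  out <- lapply(seq_along(records), function(i) {
    r <- records[[i]]
    pred <- predictStenosis(cv$models[[cv$foldOfRecord[i]]], r$profile,
                            lesionLocation = lesionLocation(r$reference))
    data.frame(patient = r$patient, artery = i,
               ffr = ffrValue(r$reference),
               label = ffrValue(r$reference) <= 0.8,
               ffrRegressed = ffrRegressed(pred),
               probClass = probClass(pred), probPseudo = probPseudo(pred),
               probMerged = probMerged(pred))
  })
  do.call(rbind, out)
}

#' Ensemble prediction with uncertainty
#'
#' Averages the member predictions (probabilities and FFR values) and
#' reports the population standard deviation across members of the merged
#' probability and of the regressed FFR as prediction uncertainties. Each
#' member's heads are merged first; with arithmetic means this equals
#' merging after averaging.
#'
#' @param models list of at least 2 [StenosisNetModel-class] members
#'   sharing identical normalization statistics.
#' @param profile a [CharacteristicProfile-class].
#' @param lesionLocation annotated lesion slice or `NA`.
#' @return List with `members` (per-member [Prediction-class]) and
#'   `ensemble` (a [Prediction-class] with uncertainties).
#' @export
ensemblePredict <- function(models, profile, lesionLocation = NA) {
  if (length(models) < 2) stop("need at least 2 ensemble members")
  s0 <- models[[1]]@charStats
  for (m in models[-1]) {
    if (!isTRUE(all.equal(statsMean(m@charStats), statsMean(s0))) ||
        !isTRUE(all.equal(statsSd(m@charStats), statsSd(s0))))
      stop("ensemble members do not share normalization statistics")
  }
  members <- lapply(models, predictStenosis, profile = profile,
                    lesionLocation = lesionLocation)
  popSd <- function(x) sqrt(mean((x - mean(x))^2))
  fr <- vapply(members, ffrRegressed, numeric(1))
  pc <- vapply(members, probClass, numeric(1))
  pp <- vapply(members, probPseudo, numeric(1))
  pm <- vapply(members, probMerged, numeric(1))
  ens <- Prediction(ffrRegressed = mean(fr), probClass = mean(pc),
                    probPseudo = mean(pp), probMerged = mean(pm),
                    uncertaintyProb = popSd(pm), uncertaintyFFR = popSd(fr))
  list(members = members, ensemble = ens)
}
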