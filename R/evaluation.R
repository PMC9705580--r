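# Artery- and patient-level evaluation: Mann-Whitney AUC, accuracy,
# sensitivity, specificity; paired AUC permutation testing; the
# uncertainty-based referral simulation; and the characteristic-ablation
# harness.

#' Evaluation metrics report
#'
#' @slot auc area under the ROC curve (`NA` for a single-class reference).
#' @slot accuracy,sensitivity,specificity operating-point metrics.
#' @slot nArteries,nPositive case counts.
#' @slot threshold operating threshold applied to the scores.
#' @export
setClass("MetricsReport",
  representation(auc = "numeric", accuracy = "numeric",
                 sensitivity = "numeric", specificity = "numeric",
                 nArteries = "integer", nPositive = "integer",
                 threshold = "numeric"))

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf(
    "MetricsReport (n = %d, %d positive): AUC %s | acc %.3f | sens %.3f | spec %.3f @ %.2f\n",
    object@nArteries, object@nPositive,
    ifelse(is.na(object@auc), "NA", sprintf("%.3f", object@auc)),
    object@accuracy, object@sensitivity, object@specificity,
    object@threshold))
})

#' Dichotomize scores into significance calls
#'
#' FFR values are positive (functionally significant) at or below the
#' threshold (default 0.8); probabilities are positive at or above the
#' operating threshold (default 0.5 — ties count as positive).
#'
#' @param values numeric scores.
#' @param mode `"ffr"` or `"probability"`.
#' @param threshold decision threshold; defaults to 0.8 for FFR and 0.5
#'   for probabilities.
#' @return Logical vector of positive calls.
#' @export
dichotomize <- function(values, mode = c("ffr", "probability"),
                        threshold = NULL) {
  mode <- match.arg(mode)
  if (is.null(threshold)) threshold <- if (mode == "ffr") 0.8 else 0.5
  stopifnot(all(is.finite(values)))
  if (mode == "ffr") values <= threshold else values >= threshold
}

# Mann-Whitney AUC with ties counted 1/2, via midranks.
.aucMW <- function(scores, labels) {
  npos <- sum(labels); nneg <- sum(!labels)
  if (npos == 0 || nneg == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Compute evaluation metrics for scored cases
#'
#' AUC follows the Mann-Whitney construction (probability that a random
#' positive outscores a random negative, ties counted one half);
#' sensitivity, specificity and accuracy are computed at the operating
#' threshold. With a single-class reference the AUC is undefined and
#' reported as `NA` while the other metrics are still computed.
#'
#' @param scores numeric scores (higher = more likely positive for
#'   `mode = "probability"`; lower = more likely positive for
#'   `mode = "ffr"`, where internally `1 - score` ranking is used).
#' @param labels logical (or 0/1) reference labels, `TRUE` = positive.
#' @param mode,threshold see [dichotomize()].
#' @return A [MetricsReport-class].
#' @export
computeMetrics <- function(scores, labels, mode = "probability",
                           threshold = NULL) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), length(scores) >= 1)
  pred <- dichotomize(scores, mode, threshold)
  rankScores <- if (mode == "ffr") -scores else scores
  tp <- sum(pred & labels); tn <- sum(!pred & !labels)
  fp <- sum(pred & !labels); fn <- sum(!pred & labels)
  new("MetricsReport",
      auc = .aucMW(rankScores, labels),
      accuracy = (tp + tn) / length(labels),
      sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
      nArteries = length(labels), nPositive = as.integer(sum(labels)),
      threshold = if (is.null(threshold)) {
        if (mode == "ffr") 0.8 else 0.5
      } else threshold)
}

#' Aggregate artery predictions to the patient level
#'
#' The patient score is the highest output value of all classified
#' arteries of the patient; the patient is reference-negative iff none of
#' the measured arteries has FFR at or below 0.8. Patients listed without
#' any artery are excluded with a warning.
#'
#' @param patients patient identifier per artery (vector or factor; unused
#'   factor levels mark zero-artery patients).
#' @param scores per-artery scores (e.g. merged probabilities).
#' @param ffr per-artery reference FFR values.
#' @return data.frame with columns `patient`, `score`, `label`.
#' @export
patientLevel <- function(patients, scores, ffr) {
  stopifnot(length(patients) == length(scores),
            length(scores) == length(ffr))
  if (is.factor(patients)) {
    empty <- setdiff(levels(patients), as.character(unique(patients)))
    if (length(empty))
      warning(sprintf("excluding %d patient(s) with zero arteries: %s",
                      length(empty), paste(empty, collapse = ", ")))
    patients <- as.character(patients)
  }
  sp <- split(seq_along(scores), patients)
  out <- data.frame(
    patient = names(sp),
    score = vapply(sp, function(i) max(scores[i]), numeric(1)),
    label = vapply(sp, function(i) any(ffr[i] <= 0.8), logical(1)))
  rownames(out) <- NULL
  out
}

#' Uncertainty-based referral simulation
#'
#' Emulates a semi-automatic setting in which the `fraction` of cases with
#' the highest prediction uncertainty is referred for invasive
#' measurement: those `ceiling(fraction * n)` cases are either removed
#' (`exclude`) or replaced by their reference outcome (`correct`: score 1
#' for reference positives, 0 for negatives), and the metrics are
#' recomputed. Ties in uncertainty are broken by case id for determinism.
#'
#' @param scores,labels per-case probabilities and reference labels.
#' @param uncertainties per-case prediction uncertainty.
#' @param fraction fraction of cases referred (e.g. 0.05, 0.10, 0.20).
#' @param mode `"exclude"` or `"correct"`.
#' @param ids case identifiers used for tie-breaking.
#' @param threshold operating threshold.
#' @return A [MetricsReport-class].
#' @export
referralSimulation <- function(scores, labels, uncertainties,
                               fraction, mode = c("exclude", "correct"),
                               ids = seq_along(scores), threshold = NULL) {
  mode <- match.arg(mode)
  labels <- as.logical(labels)
  n <- length(scores)
  stopifnot(length(labels) == n, length(uncertainties) == n,
            fraction >= 0)
  if (mode == "exclude" && fraction >= 1)
    stop("cannot exclude all cases: fraction must be < 1 in exclude mode")
  nref <- ceiling(fraction * n)
  referred <- utils::head(order(-uncertainties, ids), nref)
  if (mode == "exclude") {
    keep <- setdiff(seq_len(n), referred)
    computeMetrics(scores[keep], labels[keep], threshold = threshold)
  } else {
    scores[referred] <- as.numeric(labels[referred])
    computeMetrics(scores, labels, threshold = threshold)
  }
}

#' Paired permutation test for an AUC difference
#'
#' Tests whether two models' AUCs on the same cases differ beyond chance:
#' the observed statistic is `|AUC_a - AUC_b|`; under the null the two
#' models are exchangeable, so each iteration independently swaps the two
#' scores of each case with probability one half. The p-value uses add-one
#' smoothing: `(#{permuted >= observed} + 1) / (nIter + 1)`.
#'
#' @param scoresA,scoresB paired per-case scores of the two models.
#' @param labels reference labels.
#' @param nIter permutation iterations (default 1000).
#' @param seed RNG seed.
#' @return List with `pValue`, `observed` (the absolute AUC difference)
#'   and `aucA`, `aucB`.
#' @export
aucPermutationTest <- function(scoresA, scoresB, labels, nIter = 1000L,
                               seed = 1L) {
  n <- length(labels)
  if (length(scoresA) != n || length(scoresB) != n)
    stop("scoresA, scoresB and labels must be paired (equal length)")
  labels <- as.logical(labels)
  aucA <- .aucMW(scoresA, labels)
  aucB <- .aucMW(scoresB, labels)
  obs <- abs(aucA - aucB)
  set.seed(seed)
  count <- 0L
  for (it in seq_len(nIter)) {
    swap <- stats::runif(n) < 0.5
    a <- ifelse(swap, scoresB, scoresA)
    b <- ifelse(swap, scoresA, scoresB)
    if (abs(.aucMW(a, labels) - .aucMW(b, labels)) >= obs - 1e-12)
      count <- count + 1L
  }
  list(pValue = (count + 1) / (nIter + 1), observed = obs,
       aucA = aucA, aucB = aucB)
}

#' Characteristic-ablation harness
#'
#' Trains and evaluates one stenosis-assessment network per characteristic
#' subset by zeroing the excluded input channels at train and test time
#' (for lumen area and attenuation this includes their
#' percentage-difference pre-encoder inputs), leaving the architecture
#' unchanged.
#'
#' @param trainRecords,testRecords artery record lists (`profile`,
#'   `reference`, `patient`).
#' @param subsets named list of character vectors of included
#'   characteristics (subsets of
#'   `c("lumenArea", "attenuation", "calciumArea", "bifurcation",
#'   "mainBranch")`); e.g. `list(all = ..., "no lumen" = ...)`.
#' @param config base [stenosisNetConfig()].
#' @param epochs override of the config epoch count.
#' @param verbose print progress.
#' @return Named list (per subset) with elements `metrics`
#'   ([MetricsReport-class]), `model` and `predictions`.
#' @export
ablationHarness <- function(trainRecords, testRecords, subsets,
                            config = stenosisNetConfig(), epochs = NULL,
                            verbose = FALSE) {
  out <- vector("list", length(subsets))
  names(out) <- names(subsets)
  for (nm in names(subsets)) {
    keep <- subsets[[nm]]
    if (!length(keep)) stop("empty characteristic subset: ", nm)
    if (!all(keep %in% .CHAR_NAMES))
      stop("unknown characteristic(s): ",
           paste(setdiff(keep, .CHAR_NAMES), collapse = ", "))
    cfg <- config
    cfg$channelMask <- stats::setNames(.CHAR_NAMES %in% keep, .CHAR_NAMES)
    if (verbose) message("ablation subset: ", nm)
    model <- trainStenosisNet(buildStenosisNet(cfg), trainRecords,
                              epochs = epochs)
    preds <- vapply(testRecords, function(r)
      probMerged(predictStenosis(model, r$profile,
                                 lesionLocation(r$reference))),
      numeric(1))
    labs <- vapply(testRecords, function(r) ffrValue(r$reference) <= 0.8,
                   logical(1))
    out[[nm]] <- list(metrics = computeMetrics(preds, labs),
                      model = model, predictions = preds)
  }
  out
}
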