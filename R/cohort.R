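# Synthetic development cohorts: per patient 1-3 arteries with stenosis
# severities drawn to reach a requested prevalence of functionally
# significant (toy-model FFR <= 0.8) arteries.

#' Generate a synthetic cohort of phantom arteries
#'
#' Draws, per patient, 1-3 arteries with randomized geometry (length 40-80
#' mm, baseline radius 1.1-1.6 mm), focal stenoses, optional calcified
#' plaque placed independently of the stenoses, optional side branches and
#' main/side-branch identity. Stenosis severities are rejection-sampled so
#' that the fraction of arteries with FFR <= 0.8 matches `classBalance`
#' (default 0.42, a typical development prevalence for FFR cohorts); if a
#' draw cannot reach its assigned class a warning is emitted and the best
#' attempt is kept. Reference characteristic profiles are analytic, with
#' optional additive observation noise emulating characterization error.
#'
#' @param nPatients number of patients (>= 1).
#' @param classBalance target fraction of FFR-positive arteries.
#' @param seed RNG seed; identical seeds give identical cohorts.
#' @param profilesOnly if `TRUE` (default) only profiles and references are
#'   generated; if `FALSE` each artery also carries full phantom artifacts
#'   from [generatePhantom()] (volumes, masks, tree).
#' @param profileNoise add observation noise to the characteristic series
#'   (lumen area sd 0.2 mm^2, attenuation sd 15 HU, calcium sd 0.15 mm^2).
#' @return List with `arteries` (one record per artery: `profile`,
#'   `reference`, `patient`, `artery`, plus `phantom` when
#'   `profilesOnly = FALSE`) and `index` (a data.frame with one row per
#'   artery: patient, artery, ffr, label).
#' @examples
#' coh <- generateCohort(5, seed = 1)
#' coh$index
#' @export
generateCohort <- function(nPatients, classBalance = 0.42, seed = 1L,
                           profilesOnly = TRUE, profileNoise = TRUE) {
  if (nPatients < 1) stop("nPatients must be >= 1")
  set.seed(seed)
  nArt <- sample(1:3, nPatients, replace = TRUE)
  ntot <- sum(nArt)
  npos <- round(classBalance * ntot)
  posFlags <- rep(FALSE, ntot)
  posFlags[sample(ntot, npos)] <- TRUE

  arteries <- vector("list", ntot)
  idx <- data.frame(patient = integer(ntot), artery = integer(ntot),
                    ffr = numeric(ntot), label = logical(ntot))
  misses <- 0L
  aid <- 0L
  for (p in seq_len(nPatients)) {
    for (a in seq_len(nArt[p])) {
      aid <- aid + 1L
      wantPos <- posFlags[aid]
      L <- stats::runif(1, 40, 80)
      S <- floor(L / 0.5) + 1L
      sGrid <- (seq_len(S) - 1) * 0.5
      r0 <- stats::runif(1, 1.1, 1.6)
      A0 <- pi * r0^2

      best <- NULL
      for (try in 1:60) {
        sten <- list()
        if (wantPos || stats::runif(1) > 0.25) {
          sev <- if (wantPos) stats::runif(1, 0.6, 0.92)
                 else stats::runif(1, 0.05, 0.55)
          sten <- list(c(stats::runif(1, 0.3 * L, 0.7 * L),
                         stats::runif(1, 8, 16), sev))
        }
        areas <- A0 * (1 - stenosisReduction(sGrid, sten))
        ffr <- simulateFFR(areas)
        best <- list(sten = sten, areas = areas, ffr = ffr)
        if ((ffr <= 0.8) == wantPos) break
      }
      if ((best$ffr <= 0.8) != wantPos) misses <- misses + 1L
      sten <- best$sten; areas <- best$areas; ffr <- best$ffr

      calc <- list()
      calcArea <- numeric(S)
      if (stats::runif(1) < 0.4) {
        for (j in seq_len(sample(1:2, 1))) {
          cs <- c(stats::runif(1, 0.2 * L, 0.8 * L), stats::runif(1, 4, 10),
                  stats::runif(1, 0.2, 0.6))
          calc[[length(calc) + 1]] <- cs
          act <- abs(sGrid - cs[1]) <= cs[2] / 2
          rAct <- sqrt(areas[act] / pi)
          calcArea[act] <- calcArea[act] +
            cs[3] * pi * ((rAct + .CALCIUM_THICKNESS_MM)^2 - rAct^2)
        }
      }

      hasSB <- stats::runif(1) < 0.5
      bif <- numeric(S)
      if (hasSB) bif[round(stats::runif(1, 0.3, 0.7) * S)] <- 1
      isMain <- stats::runif(1) < 0.85

      if (profileNoise) {
        lumObs <- pmax(areas + stats::rnorm(S, 0, 0.2), 0.05)
        attObs <- 400 + stats::rnorm(S, 0, 15)
        calObs <- pmax(calcArea + stats::rnorm(S, 0, 0.15), 0)
      } else {
        lumObs <- areas; attObs <- rep(400, S); calObs <- calcArea
      }
      prof <- CharacteristicProfile(lumObs, attObs, calObs, bif,
                                    rep(as.numeric(isMain), S))
      lesion <- if (length(sten)) which.min(areas) else NA_integer_
      measIdx <- if (!is.na(lesion)) min(lesion + 20L, S)
                 else max(which(areas > 2))
      ref <- FFRReference(ffr, lesion, measIdx)
      rec <- list(profile = prof, reference = ref, patient = p, artery = aid,
                  trueAreas = areas,
                  stenosisSpec = sten, calciumSpec = calc,
                  lengthMM = L, baselineRadiusMM = r0)
      arteries[[aid]] <- rec
      idx[aid, ] <- list(p, aid, ffr, ffr <= 0.8)
    }
  }
  if (misses > 0)
    warning(sprintf(
      "requested class balance not exactly reachable: %d arteries kept with the other class",
      misses))

  if (!profilesOnly) {
    for (i in seq_len(ntot)) {
      rec <- arteries[[i]]
      cfg <- phantomConfig(
        arteryLengthMM = rec$lengthMM, baselineRadiusMM = rec$baselineRadiusMM,
        stenosisSpec = rec$stenosisSpec, calciumSpec = rec$calciumSpec,
        seed = seed + 131L * i)
      arteries[[i]]$phantom <- generatePhantom(cfg)
    }
  }
  list(arteries = arteries, index = idx)
}
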