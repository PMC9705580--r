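# Toy hemodynamic model assigning ground-truth FFR to phantom arteries.
#
# The pressure drop is a serial Poiseuille-type viscous term (one resistance
# per slice, additive along the artery) plus a single quadratic
# flow-separation term driven by the minimum lumen area relative to a fixed
# reference caliber. Constants are fixed by two calibration anchors, not by
# fitting to any data: an unobstructed 3 mm^2 artery of 100 mm yields
# FFR 0.98, and a 70%-area stenosis of 10 mm length in that artery yields
# FFR 0.70.

#' Parameters of the toy FFR model
#'
#' Returns the frozen, calibrated constants of the analytic pressure-drop
#' model used to label synthetic arteries. `c` scales the per-slice viscous
#' resistance `Q * c * l / A^2`; `k` scales the quadratic separation term
#' `k * Q^2 * max(0, 1/A_min - 1/Aref)^2`; `Q` is the (arbitrary-unit) flow;
#' `Pa` the aortic pressure; `Aref` the fixed reference caliber in mm^2
#' below which the separation term activates. See [calibrateFFRModel()] for
#' how the constants were derived.
#'
#' @return Named list of model constants.
#' @export
ffrModelParams <- function() {
  list(c = 0.1791044776119403, k = 45.3133609650669, Q = 1, Pa = 100,
       Aref = 3)
}

#' Fractional area-reduction profile of focal stenoses
#'
#' Smooth cosine-bump narrowing: each stenosis `(center, length, reduction)`
#' contributes `reduction * 0.5 * (1 + cos(2*pi*(s - center)/length))` for
#' `|s - center| <= length/2`. Overlapping bumps combine by their maximum so
#' the fractional reduction stays within `[0, 0.95]`.
#'
#' @param s arc-length positions along the artery in mm.
#' @param stenosisSpec list of `c(center_mm, length_mm, reduction)`.
#' @return Fractional area reduction at each `s`.
#' @export
stenosisReduction <- function(s, stenosisSpec) {
  red <- numeric(length(s))
  for (sp in stenosisSpec) {
    inb <- abs(s - sp[1]) <= sp[2] / 2
    bump <- numeric(length(s))
    bump[inb] <- sp[3] * 0.5 * (1 + cos(2 * pi * (s[inb] - sp[1]) / sp[2]))
    red <- pmax(red, bump)
  }
  red
}

#' Assign a ground-truth FFR to a lumen-area profile
#'
#' Computes `FFR = (Pa - dP) / Pa` with
#' `dP = Q * c * sum_i(l / A_i^2) + k * Q^2 * max(0, 1/min(A) - 1/Aref)^2`,
#' clipped to (0, 1]. The model is monotone non-increasing under pointwise
#' area reduction: both terms can only grow when any area shrinks.
#'
#' @param areas per-slice lumen areas in mm^2 (all strictly positive).
#' @param sliceSpacing distance between slices in mm (default 0.5).
#' @param params model constants, see [ffrModelParams()].
#' @return FFR value in (0, 1].
#' @examples
#' simulateFFR(rep(3, 201))            # unobstructed: ~0.98
#' @export
simulateFFR <- function(areas, sliceSpacing = 0.5, params = ffrModelParams()) {
  if (any(!is.finite(areas)) || any(areas <= 0))
    stop("simulateFFR: all lumen areas must be finite and > 0")
  visc <- params$Q * params$c * sum(sliceSpacing / areas^2)
  sep <- params$k * params$Q^2 *
    max(0, 1 / min(areas) - 1 / params$Aref)^2
  ffr <- (params$Pa - (visc + sep)) / params$Pa
  min(max(ffr, 1e-6), 1)
}

#' Re-derive the toy FFR model constants from the calibration anchors
#'
#' Solves for the two free constants: `c` such that an unobstructed 3 mm^2
#' artery of 100 mm yields FFR 0.98, then `k` by root-finding such that a
#' 70%-area stenosis of 10 mm length centred in the same artery yields
#' FFR 0.70. The frozen values returned by [ffrModelParams()] were produced
#' by this function.
#'
#' @return Named list with the same structure as [ffrModelParams()].
#' @export
calibrateFFRModel <- function() {
  Pa <- 100; Q <- 1; Aref <- 3
  s <- seq(0, 100, by = 0.5)
  A0 <- rep(3, length(s))
  cvisc <- (Pa - 0.98 * Pa) / (Q * sum(0.5 / A0^2))
  Ast <- 3 * (1 - stenosisReduction(s, list(c(50, 10, 0.7))))
  target <- function(k) {
    dP <- Q * cvisc * sum(0.5 / Ast^2) +
      k * Q^2 * max(0, 1 / min(Ast) - 1 / Aref)^2
    (Pa - dP) / Pa - 0.70
  }
  k <- stats::uniroot(target, c(0, 500), tol = 1e-10)$root
  list(c = cvisc, k = k, Q = Q, Pa = Pa, Aref = Aref)
}
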