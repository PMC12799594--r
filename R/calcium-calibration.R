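# Resting-[Ca2+] determination from basal and ionophore-saturated
# single-wavelength indicator signals by Hill-equation inversion. The
# saturating ionophore application gives each ROI its own F_max, so the
# computation is invariant to expression level.

#' Resting [Ca2+] from basal and maximal indicator signals
#'
#' Inverts the Hill saturation curve: with
#' \eqn{F_{min} = F_{max}/R_f},
#' \deqn{[Ca] = K_d \left(\frac{F_{basal}-F_{min}}
#'       {F_{max}-F_{basal}}\right)^{1/n}.}
#' Strictly increasing in \code{fBasal} on its domain and invariant under a
#' common rescaling of \code{fBasal} and \code{fMax}.
#'
#' @param fBasal basal (resting) signal(s), a.u., > 0.
#' @param fMax ionophore-saturated maximal signal(s), a.u.; recycled
#'   against \code{fBasal}.
#' @param calib \linkS4class{CalibrationParams} of the indicator. The
#'   constants must come from a published calibration of the indicator
#'   used; there are no scientific defaults.
#' @return numeric, resting [Ca2+] in nM.
#' @examples
#' calib <- CalibrationParams(kd = 460, nHill = 2.5, dynamicRange = 32.7)
#' fmin <- 1000 / 32.7
#' restingCalcium((fmin + 1000) / 2, 1000,
#'                CalibrationParams(460, 1, 32.7))  # Hill midpoint: Kd
#' @export
restingCalcium <- function(fBasal, fMax, calib) {
  stopifnot(is(calib, "CalibrationParams"))
  validObject(calib)
  k <- max(length(fBasal), length(fMax))
  fBasal <- rep_len(fBasal, k); fMax <- rep_len(fMax, k)
  if (any(fBasal <= 0) || any(fMax <= 0))
    .stopParam("signals must be positive")
  fMin <- fMax / calib@dynamicRange
  if (any(fBasal >= fMax))
    .stopParam("saturated: fBasal must be below fMax")
  if (any(fBasal < fMin - 1e-9 * fMax))
    .stopParam("fBasal below fMin = fMax/dynamicRange: outside the ",
               "calibratable range")
  ratio <- pmax(fBasal - fMin, 0) / (fMax - fBasal)
  calib@kd * ratio^(1 / calib@nHill)
}

#' Group difference in resting [Ca2+]
#'
#' @param groupA,groupB non-empty numeric vectors of per-ROI [Ca2+] (nM).
#' @return numeric(1), \code{mean(groupB) - mean(groupA)} in nM.
#' @examples
#' groupDeltaCalcium(c(90, 110), c(150, 170))  # 60
#' @export
groupDeltaCalcium <- function(groupA, groupB) {
  if (!length(groupA) || !length(groupB))
    .stopParam("both groups must be non-empty")
  mean(groupB) - mean(groupA)
}

#' Illustrative GCaMP5-like calibration constants
#'
#' Example constants in the range published for GCaMP5-family indicators
#' (Kd 460 nM, Hill coefficient 2.5, dynamic range 32.7). These are
#' illustrative values for demonstrations and tests; scientific use
#' requires the constants of the actual indicator and calibration
#' conditions.
#'
#' @return A \linkS4class{CalibrationParams}.
#' @export
exampleCalibration <- function() {
  CalibrationParams(kd = 460, nHill = 2.5, dynamicRange = 32.7)
}

#' Read calibration constants from a YAML file
#'
#' Expects top-level keys \code{kd} (nM), \code{n_hill} and
#' \code{dynamic_range}.
#'
#' @param path YAML file path.
#' @return A \linkS4class{CalibrationParams}.
#' @export
readCalibrationYaml <- function(path) {
  y <- yaml::read_yaml(path)
  need <- c("kd", "n_hill", "dynamic_range")
  if (!all(need %in% names(y)))
    .stopParam("calibration YAML needs keys: ", paste(need, collapse = ", "))
  CalibrationParams(y$kd, y$n_hill, y$dynamic_range)
}
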