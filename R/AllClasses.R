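#' @import methods
#' @importFrom stats dbinom rbinom rnorm var sd optim optimize setNames
#'   coef lm predict IQR dnorm qlogis plogis resid
#' @importFrom utils read.csv write.csv packageVersion head tail
#' @useDynLib presynquant, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

.posScalar <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0
.nonNegScalar <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0

#' Quantal parameters of the binomial Ca2+-channel model
#'
#' A bouton's single-stimulus Ca2+ transient is modelled as the summed
#' contribution of \code{nChannels} voltage-gated Ca2+ channels, each opening
#' independently with probability \code{openProb} per action potential and
#' contributing a unitary fluorescence signal \code{unitaryAmplitude} when
#' open, plus additive Gaussian measurement noise of standard deviation
#' \code{noiseSd}. Under this model the trial mean is \eqn{Npq} and, with no
#' measurement noise, the inverse squared coefficient of variation is
#' \eqn{CV^{-2} = Np/(1-p)} -- independent of \eqn{q}.
#'
#' @slot nChannels integer(1), number of channels per bouton (N >= 1).
#' @slot openProb numeric(1), per-stimulus open probability p in (0, 1].
#' @slot unitaryAmplitude numeric(1), fluorescence contribution q of one open
#'   channel (a.u., > 0).
#' @slot noiseSd numeric(1), additive trial noise SD (a.u., >= 0).
#' @exportClass ChannelModelParams
setClass("ChannelModelParams",
  representation(nChannels = "integer", openProb = "numeric",
                 unitaryAmplitude = "numeric", noiseSd = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@nChannels) != 1L || is.na(object@nChannels) ||
        object@nChannels < 1L)
      msg <- c(msg, "nChannels must be a single integer >= 1")
    if (!is.numeric(object@openProb) || length(object@openProb) != 1L ||
        is.na(object@openProb) ||
        object@openProb <= 0 || object@openProb > 1)
      msg <- c(msg, "openProb must lie in (0, 1]")
    if (!.posScalar(object@unitaryAmplitude))
      msg <- c(msg, "unitaryAmplitude must be a positive number")
    if (!.nonNegScalar(object@noiseSd))
      msg <- c(msg, "noiseSd must be a non-negative number")
    if (length(msg)) msg else TRUE
  })

#' Construct ChannelModelParams
#'
#' @param nChannels number of channels N (coerced to integer).
#' @param openProb open probability p in (0, 1].
#' @param unitaryAmplitude unitary signal q (a.u.).
#' @param noiseSd additive trial noise SD (a.u.), default 0.
#' @return A \linkS4class{ChannelModelParams} object.
#' @examples
#' ChannelModelParams(20, 0.5, 1)
#' @export
ChannelModelParams <- function(nChannels, openProb, unitaryAmplitude,
                               noiseSd = 0) {
  new("ChannelModelParams", nChannels = as.integer(nChannels),
      openProb = as.numeric(openProb),
      unitaryAmplitude = as.numeric(unitaryAmplitude),
      noiseSd = as.numeric(noiseSd))
}

#' Two-condition simulation scenario for optical fluctuation analysis
#'
#' Bundles the quantal parameters of a control and a perturbed condition with
#' the design sizes (boutons per condition, trials per bouton) and the root
#' seed, i.e. everything needed to generate a reproducible
#' \linkS4class{TrialTable}.
#'
#' @slot control,perturbed \linkS4class{ChannelModelParams} per condition.
#' @slot nBoutonsControl,nBoutonsPerturbed integer(1) bouton counts (>= 1).
#' @slot nTrials integer(1), trials per bouton (>= 2; CV undefined below).
#' @slot seed integer(1) root RNG seed.
#' @exportClass SimScenario
setClass("SimScenario",
  representation(control = "ChannelModelParams",
                 perturbed = "ChannelModelParams",
                 nBoutonsControl = "integer", nBoutonsPerturbed = "integer",
                 nTrials = "integer", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@nTrials < 2L)
      msg <- c(msg, "nTrials must be >= 2 (CV undefined otherwise)")
    if (object@nBoutonsControl < 1L || object@nBoutonsPerturbed < 1L)
      msg <- c(msg, "bouton counts must be >= 1")
    if (length(object@seed) != 1L || is.na(object@seed))
      msg <- c(msg, "seed must be a single integer")
    if (length(msg)) msg else TRUE
  })

#' Construct a SimScenario
#'
#' @param control,perturbed \linkS4class{ChannelModelParams}.
#' @param nBoutonsControl,nBoutonsPerturbed boutons per condition.
#' @param nTrials trials per bouton.
#' @param seed root RNG seed.
#' @return A \linkS4class{SimScenario}.
#' @export
SimScenario <- function(control, perturbed, nBoutonsControl,
                        nBoutonsPerturbed, nTrials = 5L, seed = 1L) {
  new("SimScenario", control = control, perturbed = perturbed,
      nBoutonsControl = as.integer(nBoutonsControl),
      nBoutonsPerturbed = as.integer(nBoutonsPerturbed),
      nTrials = as.integer(nTrials), seed = as.integer(seed))
}

#' One ROI's fluorescence time series with annotated epochs
#'
#' Holds a uniformly sampled fluorescence trace together with named epoch
#' windows (in seconds). The conventional epoch names are \code{baseline},
#' \code{stimulus} and \code{plateau} (the NH4Cl-unquench or ionophore
#' steady state used for normalization).
#'
#' @slot time numeric, strictly increasing sample times (s).
#' @slot fluorescence numeric, same length as \code{time} (a.u.).
#' @slot epochs named list of numeric(2) \code{c(start, end)} windows (s),
#'   all within the time range; baseline must precede stimulus.
#' @slot roiId character(1) ROI identifier.
#' @exportClass Trace
setClass("Trace",
  representation(time = "numeric", fluorescence = "numeric",
                 epochs = "list", roiId = "character"),
  validity = function(object) {
    msg <- character()
    n <- length(object@time)
    if (n < 2L) msg <- c(msg, "trace needs at least 2 samples")
    if (length(object@fluorescence) != n)
      msg <- c(msg, "time and fluorescence lengths differ")
    if (n >= 2L && any(diff(object@time) <= 0))
      msg <- c(msg, "time must be strictly increasing")
    ep <- object@epochs
    if (length(ep)) {
      if (is.null(names(ep)) || any(!nzchar(names(ep))))
        msg <- c(msg, "epochs must be a named list")
      bad <- vapply(ep, function(w)
        !(is.numeric(w) && length(w) == 2L && w[1] <= w[2]), logical(1))
      if (any(bad)) msg <- c(msg, "each epoch must be numeric c(start, end)")
      if (!any(bad) && n >= 1L) {
        rng <- range(object@time)
        out <- vapply(ep, function(w) w[1] < rng[1] - 1e-9 ||
                        w[2] > rng[2] + 1e-9, logical(1))
        if (any(out)) msg <- c(msg, "epochs must lie within the time range")
        if (all(c("baseline", "stimulus") %in% names(ep)) &&
            ep$baseline[2] > ep$stimulus[1] + 1e-9)
          msg <- c(msg, "baseline epoch must precede stimulus epoch")
      }
    }
    if (length(object@roiId) != 1L)
      msg <- c(msg, "roiId must be a single identifier")
    if (length(msg)) msg else TRUE
  })

#' Construct a Trace
#'
#' @param time sample times (s), strictly increasing.
#' @param fluorescence fluorescence values (a.u.).
#' @param epochs named list of \code{c(start, end)} windows in seconds.
#' @param roiId ROI identifier.
#' @return A \linkS4class{Trace}.
#' @examples
#' tr <- Trace(0:10, c(rep(0, 5), 1:6),
#'             epochs = list(baseline = c(0, 4), stimulus = c(4, 10)))
#' peakAmplitude(tr)
#' @export
Trace <- function(time, fluorescence, epochs = list(), roiId = "roi1") {
  new("Trace", time = as.numeric(time),
      fluorescence = as.numeric(fluorescence),
      epochs = epochs, roiId = as.character(roiId))
}

#' Per-bouton, per-trial response amplitude table
#'
#' Long-format table of single-stimulus response amplitudes: one row per
#' (condition, bouton, trial). This is the input of optical fluctuation
#' analysis; at least two trials per bouton are required there.
#'
#' @slot data data.frame with columns \code{condition}, \code{bouton_id},
#'   \code{trial_id}, \code{amplitude}; (condition, bouton_id, trial_id)
#'   unique.
#' @exportClass TrialTable
setClass("TrialTable", representation(data = "data.frame"),
  validity = function(object) {
    d <- object@data
    need <- c("condition", "bouton_id", "trial_id", "amplitude")
    if (!all(need %in% names(d)))
      return(paste("TrialTable needs columns:", paste(need, collapse = ", ")))
    if (!is.numeric(d$amplitude)) return("amplitude must be numeric")
    key <- paste(d$condition, d$bouton_id, d$trial_id, sep = "\r")
    if (anyDuplicated(key))
      return("(condition, bouton_id, trial_id) must be unique")
    TRUE
  })

#' Construct a TrialTable
#'
#' @param data data.frame with columns \code{condition}, \code{bouton_id},
#'   \code{trial_id}, \code{amplitude}.
#' @return A \linkS4class{TrialTable}.
#' @export
TrialTable <- function(data) new("TrialTable", data = as.data.frame(data))

#' Parameters of the synthetic pHluorin stimulus-train trace
#'
#' Describes a trace with a flat baseline, a linear fluorescence rise during
#' the stimulus (exocytosis outpacing reacidification), a partial
#' post-stimulus recovery, and a terminal NH4Cl unquench plateau revealing
#' the total reporter pool.
#'
#' @slot baselineLevel,peakDelta,nh4clPlateau,baselineSd numeric(1), a.u.
#' @slot samplingRate numeric(1), Hz.
#' @slot stimStart,stimEnd,plateauStart,plateauEnd numeric(1), s; ordered,
#'   plateau at least 5 s long, plateau level above baseline.
#' @exportClass PhluorinSimParams
setClass("PhluorinSimParams",
  representation(baselineLevel = "numeric", peakDelta = "numeric",
                 nh4clPlateau = "numeric", baselineSd = "numeric",
                 samplingRate = "numeric", stimStart = "numeric",
                 stimEnd = "numeric", plateauStart = "numeric",
                 plateauEnd = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@nh4clPlateau <= object@baselineLevel)
      msg <- c(msg, "nh4clPlateau must exceed baselineLevel")
    if (object@plateauEnd - object@plateauStart < 5)
      msg <- c(msg, "plateau window must be at least 5 s long")
    if (!(0 <= object@stimStart && object@stimStart < object@stimEnd &&
          object@stimEnd <= object@plateauStart &&
          object@plateauStart < object@plateauEnd))
      msg <- c(msg, "windows must be ordered: 0 <= stimStart < stimEnd <= plateauStart < plateauEnd")
    if (!.posScalar(object@samplingRate))
      msg <- c(msg, "samplingRate must be positive")
    if (!.nonNegScalar(object@baselineSd))
      msg <- c(msg, "baselineSd must be non-negative")
    if (length(msg)) msg else TRUE
  })

#' Construct PhluorinSimParams
#'
#' @param baselineLevel resting fluorescence (a.u.).
#' @param peakDelta fluorescence rise over the stimulus (a.u.).
#' @param nh4clPlateau unquench plateau level (a.u.), must exceed baseline.
#' @param baselineSd per-sample noise SD (a.u.).
#' @param samplingRate sampling rate (Hz).
#' @param stimStart,stimEnd stimulus window (s).
#' @param plateauStart,plateauEnd NH4Cl plateau window (s), >= 5 s long.
#' @return A \linkS4class{PhluorinSimParams}.
#' @export
PhluorinSimParams <- function(baselineLevel = 0, peakDelta = 50,
                              nh4clPlateau = 200, baselineSd = 0,
                              samplingRate = 1, stimStart = 10,
                              stimEnd = 20, plateauStart = 40,
                              plateauEnd = 50) {
  new("PhluorinSimParams", baselineLevel = as.numeric(baselineLevel),
      peakDelta = as.numeric(peakDelta),
      nh4clPlateau = as.numeric(nh4clPlateau),
      baselineSd = as.numeric(baselineSd),
      samplingRate = as.numeric(samplingRate),
      stimStart = as.numeric(stimStart), stimEnd = as.numeric(stimEnd),
      plateauStart = as.numeric(plateauStart),
      plateauEnd = as.numeric(plateauEnd))
}

#' Hill-equation calibration constants for a Ca2+ indicator
#'
#' The equilibrium fluorescence of a single-wavelength indicator follows
#' \deqn{F([Ca]) = F_{min} + (F_{max}-F_{min}) \frac{[Ca]^{n}}{[Ca]^{n}+K_d^{n}}}
#' with \eqn{F_{min} = F_{max}/R_f}. The constants are indicator-specific and
#' must come from a published calibration; no scientific defaults are
#' provided (see \code{exampleCalibration} for illustrative GCaMP5-like
#' values).
#'
#' @slot kd numeric(1), half-saturation constant (nM).
#' @slot nHill numeric(1), Hill coefficient.
#' @slot dynamicRange numeric(1), Rf = Fmax/Fmin (> 1).
#' @exportClass CalibrationParams
setClass("CalibrationParams",
  representation(kd = "numeric", nHill = "numeric", dynamicRange = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!.posScalar(object@kd)) msg <- c(msg, "kd must be positive")
    if (!.posScalar(object@nHill)) msg <- c(msg, "nHill must be positive")
    if (!(is.numeric(object@dynamicRange) && length(object@dynamicRange) == 1L
          && is.finite(object@dynamicRange) && object@dynamicRange > 1))
      msg <- c(msg, "dynamicRange must be > 1")
    if (length(msg)) msg else TRUE
  })

#' Construct CalibrationParams
#'
#' @param kd half-saturation constant (nM).
#' @param nHill Hill coefficient.
#' @param dynamicRange Fmax/Fmin ratio (> 1).
#' @return A \linkS4class{CalibrationParams}.
#' @export
CalibrationParams <- function(kd, nHill, dynamicRange) {
  new("CalibrationParams", kd = as.numeric(kd), nHill = as.numeric(nHill),
      dynamicRange = as.numeric(dynamicRange))
}

#' Parameters for the resting-calcium reporter generator
#'
#' @slot restingCa numeric(1), true resting free [Ca2+] (nM, > 0).
#' @slot calib \linkS4class{CalibrationParams} of the indicator.
#' @slot noiseSd numeric(1), additive noise SD on the basal signal (a.u.).
#' @slot noiseCv numeric(1), multiplicative noise CV on the basal signal
#'   (dimensionless, >= 0).
#' @slot fMax numeric(1), nominal ionophore-saturated signal (a.u.).
#' @slot expressionSd numeric(1), log-SD of the per-ROI lognormal expression
#'   factor scaling both basal and maximal signals (>= 0).
#' @exportClass GcampSimParams
setClass("GcampSimParams",
  representation(restingCa = "numeric", calib = "CalibrationParams",
                 noiseSd = "numeric", noiseCv = "numeric", fMax = "numeric",
                 expressionSd = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!.posScalar(object@restingCa))
      msg <- c(msg, "restingCa must be positive")
    if (!.nonNegScalar(object@noiseSd)) msg <- c(msg, "noiseSd must be >= 0")
    if (!.nonNegScalar(object@noiseCv)) msg <- c(msg, "noiseCv must be >= 0")
    if (!.posScalar(object@fMax)) msg <- c(msg, "fMax must be positive")
    if (!.nonNegScalar(object@expressionSd))
      msg <- c(msg, "expressionSd must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' Construct GcampSimParams
#'
#' @param restingCa resting [Ca2+] (nM).
#' @param calib \linkS4class{CalibrationParams}.
#' @param noiseSd additive basal-signal noise SD (a.u.), default 0.
#' @param noiseCv multiplicative basal-signal noise CV, default 0.
#' @param fMax nominal saturated signal (a.u.), default 1000.
#' @param expressionSd log-SD of per-ROI expression spread, default 0.
#' @return A \linkS4class{GcampSimParams}.
#' @export
GcampSimParams <- function(restingCa, calib, noiseSd = 0, noiseCv = 0,
                           fMax = 1000, expressionSd = 0) {
  new("GcampSimParams", restingCa = as.numeric(restingCa), calib = calib,
      noiseSd = as.numeric(noiseSd), noiseCv = as.numeric(noiseCv),
      fMax = as.numeric(fMax), expressionSd = as.numeric(expressionSd))
}

#' Parameters for the FM-dye unloading generator
#'
#' Per-punctum unloading half-lives are drawn from a Gaussian truncated at
#' zero; each trace is \eqn{F_0 e^{-kt}} plus additive noise, sampled every
#' \code{frameInterval} seconds (imaging stacks every 15 s by default).
#'
#' @slot tHalfMean,tHalfSd numeric(1), half-life distribution (s).
#' @slot initialF numeric(1), initial fluorescence (a.u.).
#' @slot noiseSd numeric(1), additive per-frame noise SD (a.u.).
#' @slot frameInterval numeric(1), s between frames (default 15).
#' @slot duration numeric(1), total imaging time (s), at least two frames.
#' @exportClass UnloadingSimParams
setClass("UnloadingSimParams",
  representation(tHalfMean = "numeric", tHalfSd = "numeric",
                 initialF = "numeric", noiseSd = "numeric",
                 frameInterval = "numeric", duration = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!.posScalar(object@tHalfMean)) msg <- c(msg, "tHalfMean must be > 0")
    if (!.nonNegScalar(object@tHalfSd)) msg <- c(msg, "tHalfSd must be >= 0")
    if (!.posScalar(object@initialF)) msg <- c(msg, "initialF must be > 0")
    if (!.nonNegScalar(object@noiseSd)) msg <- c(msg, "noiseSd must be >= 0")
    if (!.posScalar(object@frameInterval))
      msg <- c(msg, "frameInterval must be > 0")
    if (!(is.numeric(object@duration) && length(object@duration) == 1L &&
          is.finite(object@duration) &&
          object@duration >= 2 * object@frameInterval))
      msg <- c(msg, "duration must be at least 2 x frameInterval")
    if (length(msg)) msg else TRUE
  })

#' Construct UnloadingSimParams
#'
#' @param tHalfMean,tHalfSd mean and SD of per-punctum half-lives (s).
#' @param initialF initial fluorescence (a.u.), default 100.
#' @param noiseSd per-frame noise SD (a.u.), default 0.
#' @param frameInterval frame spacing (s), default 15.
#' @param duration imaging duration (s), default 300.
#' @return An \linkS4class{UnloadingSimParams}.
#' @export
UnloadingSimParams <- function(tHalfMean = 20, tHalfSd = 4, initialF = 100,
                               noiseSd = 0, frameInterval = 15,
                               duration = 300) {
  new("UnloadingSimParams", tHalfMean = as.numeric(tHalfMean),
      tHalfSd = as.numeric(tHalfSd), initialF = as.numeric(initialF),
      noiseSd = as.numeric(noiseSd),
      frameInterval = as.numeric(frameInterval),
      duration = as.numeric(duration))
}

#' Result of BIC model selection among N, p and q hypotheses
#'
#' @slot bic named numeric(3), BIC per hypothesis ("N", "p", "q").
#' @slot deltaBic 3 x 3 matrix, \code{deltaBic[a, b] = bic[a] - bic[b]}.
#' @slot winner character(1), hypothesis with minimal BIC.
#' @slot strongEvidence logical(1), TRUE when the winner's BIC is lower than
#'   both alternatives by at least 10 (the conventional strong-evidence
#'   threshold).
#' @slot nEstControl numeric(1), control-condition channel-number estimate
#'   from aggregate CV^-2 and the assumed p0.
#' @slot p0 numeric(1), assumed control open probability.
#' @slot meanRatio numeric(1), perturbed/control mean amplitude ratio.
#' @slot details list of fit internals (per-hypothesis parameter estimates,
#'   likelihoods, control fit, likelihood flavour, notes).
#' @exportClass ModelSelectionResult
setClass("ModelSelectionResult",
  representation(bic = "numeric", deltaBic = "matrix", winner = "character",
                 strongEvidence = "logical", nEstControl = "numeric",
                 p0 = "numeric", meanRatio = "numeric", details = "list"),
  validity = function(object) {
    msg <- character()
    if (!identical(sort(names(object@bic)), c("N", "p", "q")))
      msg <- c(msg, "bic must be named for hypotheses N, p, q")
    if (length(object@winner) != 1L ||
        !object@winner %in% names(object@bic))
      msg <- c(msg, "winner must be one of the hypotheses")
    if (length(msg) == 0L &&
        object@bic[object@winner] > min(object@bic) + 1e-9)
      msg <- c(msg, "winner must have minimal BIC")
    if (length(msg) == 0L && !(is.finite(object@nEstControl) &&
                               object@nEstControl > 0))
      msg <- c(msg, "nEstControl must be positive")
    if (length(msg)) msg else TRUE
  })

#' Per-punctum first-order unloading fit
#'
#' @slot punctumId character(1).
#' @slot f0 numeric(1), fitted initial fluorescence (a.u.).
#' @slot rateK numeric(1), decay rate (1/s); positive for converged fits.
#' @slot tHalf numeric(1), \code{log(2)/rateK} (s).
#' @slot rSquared numeric(1) in [0, 1].
#' @slot converged logical(1).
#' @exportClass UnloadingFit
setClass("UnloadingFit",
  representation(punctumId = "character", f0 = "numeric", rateK = "numeric",
                 tHalf = "numeric", rSquared = "numeric",
                 converged = "logical"),
  validity = function(object) {
    msg <- character()
    if (isTRUE(object@converged)) {
      if (!(is.finite(object@rateK) && object@rateK > 0))
        msg <- c(msg, "converged fit must have rateK > 0")
      else if (abs(object@tHalf - log(2) / object@rateK) >
               1e-8 * object@tHalf)
        msg <- c(msg, "tHalf must equal log(2)/rateK")
      if (is.finite(object@rSquared) &&
          (object@rSquared < -1e-9 || object@rSquared > 1 + 1e-9))
        msg <- c(msg, "rSquared must lie in [0, 1]")
    }
    if (length(msg)) msg else TRUE
  })

#' Distribution of unloading half-lives for one group
#'
#' @slot group character(1) group label.
#' @slot tHalfValues numeric, per-punctum half-lives (s, > 0).
#' @slot gaussMu,gaussSigma numeric(1), Gaussian ML estimates (s).
#' @slot binWidth numeric(1), histogram bin width for reporting (s).
#' @exportClass THalfDistribution
setClass("THalfDistribution",
  representation(group = "character", tHalfValues = "numeric",
                 gaussMu = "numeric", gaussSigma = "numeric",
                 binWidth = "numeric"),
  validity = function(object) {
    msg <- character()
    if (any(object@tHalfValues <= 0)) msg <- c(msg, "t1/2 values must be > 0")
    if (!(is.finite(object@gaussSigma) && object@gaussSigma > 0))
      msg <- c(msg, "gaussSigma must be > 0")
    if (!.posScalar(object@binWidth)) msg <- c(msg, "binWidth must be > 0")
    if (length(msg)) msg else TRUE
  })
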