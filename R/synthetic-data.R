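# Seeded generators for every input the pipeline consumes. Defaults mirror
# the study conditions the analyses assume (five-trial averages, ~500
# boutons per condition, 15-s FM imaging frames); noise magnitudes are
# documented assumptions, not measured values.

#' Simulate per-bouton single-stimulus amplitudes under the binomial
#' channel model
#'
#' For every bouton and trial the number of open channels is drawn
#' \eqn{K \sim Bin(N, p)} and the response amplitude is \eqn{Kq +
#' \epsilon}, \eqn{\epsilon \sim Normal(0, noiseSd)}. Amplitudes are not
#' truncated at zero, preserving the moment identities mean = \eqn{Npq} and
#' variance = \eqn{Np(1-p)q^2 + noiseSd^2} that the closed-form oracles
#' rely on. The control and perturbed conditions are generated from
#' independent child streams of the scenario seed.
#'
#' @param scenario a \linkS4class{SimScenario}.
#' @param heterogeneityCv optional lognormal CV of a per-bouton
#'   multiplicative factor on q (default 0 = homogeneous boutons; the
#'   fluctuation-analysis math assumes within-condition homogeneity).
#' @return A \linkS4class{TrialTable} with conditions \code{"control"} and
#'   \code{"perturbed"}.
#' @examples
#' sc <- SimScenario(ChannelModelParams(20, 0.5, 1),
#'                   ChannelModelParams(20, 0.5, 1.1),
#'                   nBoutonsControl = 10, nBoutonsPerturbed = 10,
#'                   nTrials = 5, seed = 42)
#' simulateChannelTrials(sc)
#' @export
simulateChannelTrials <- function(scenario, heterogeneityCv = 0) {
  stopifnot(is(scenario, "SimScenario"))
  validObject(scenario)
  seeds <- deriveSeeds(scenario@seed, 2L)
  one <- function(params, nBoutons, nTrials, condition, seed) {
    .withSeed(seed, {
      qb <- rep(params@unitaryAmplitude, nBoutons)
      if (heterogeneityCv > 0) {
        sl <- sqrt(log(1 + heterogeneityCv^2))
        qb <- qb * exp(rnorm(nBoutons, -sl^2 / 2, sl))
      }
      k <- rbinom(nBoutons * nTrials, params@nChannels, params@openProb)
      amp <- k * rep(qb, each = nTrials)
      if (params@noiseSd > 0)
        amp <- amp + rnorm(length(amp), 0, params@noiseSd)
      data.frame(condition = condition,
                 bouton_id = rep(sprintf("%s_b%04d", condition,
                                         seq_len(nBoutons)),
                                 each = nTrials),
                 trial_id = rep(seq_len(nTrials), nBoutons),
                 amplitude = amp, stringsAsFactors = FALSE)
    })
  }
  TrialTable(rbind(
    one(scenario@control, scenario@nBoutonsControl, scenario@nTrials,
        "control", seeds[1]),
    one(scenario@perturbed, scenario@nBoutonsPerturbed, scenario@nTrials,
        "perturbed", seeds[2])))
}

#' Simulate a pHluorin stimulus-train trace with an NH4Cl plateau
#'
#' The trace sits at \code{baselineLevel}, rises linearly by
#' \code{peakDelta} over the stimulus window (so the peak falls at the end
#' of stimulation), relaxes exponentially toward baseline afterwards, and
#' jumps to the \code{nh4clPlateau} unquench level for the plateau window.
#' Gaussian noise of SD \code{baselineSd} is added to every sample.
#'
#' @param params a \linkS4class{PhluorinSimParams}.
#' @param seed integer seed.
#' @param roiId ROI identifier for the returned trace.
#' @return A \linkS4class{Trace} with epochs \code{baseline},
#'   \code{stimulus} and \code{plateau}.
#' @examples
#' tr <- simulatePhluorinTrace(PhluorinSimParams(), seed = 1)
#' peakAmplitude(normalizeToPlateau(tr))
#' @export
simulatePhluorinTrace <- function(params, seed = 1L, roiId = "roi1") {
  stopifnot(is(params, "PhluorinSimParams"))
  validObject(params)
  dt <- 1 / params@samplingRate
  time <- seq(0, params@plateauEnd, by = dt)
  f <- rep(params@baselineLevel, length(time))
  inStim <- time > params@stimStart & time <= params@stimEnd
  f[inStim] <- params@baselineLevel + params@peakDelta *
    (time[inStim] - params@stimStart) / (params@stimEnd - params@stimStart)
  post <- time > params@stimEnd & time < params@plateauStart
  tauRec <- max((params@plateauStart - params@stimEnd) / 3, dt)
  f[post] <- params@baselineLevel + params@peakDelta *
    exp(-(time[post] - params@stimEnd) / tauRec)
  f[time >= params@plateauStart] <- params@nh4clPlateau
  f <- .withSeed(seed, f + rnorm(length(f), 0, params@baselineSd))
  Trace(time, f, roiId = roiId,
        epochs = list(baseline = c(0, params@stimStart),
                      stimulus = c(params@stimStart, params@stimEnd),
                      plateau = c(params@plateauStart, params@plateauEnd)))
}

#' Simulate basal and ionophore-saturated reporter signals
#'
#' Generates per-ROI pairs (F_basal, F_max): the maximal signal is the
#' nominal \code{fMax} scaled by a per-ROI lognormal expression factor (the
#' saturating ionophore application controls for expression differences,
#' which is why downstream calibration uses the ratio), and the basal
#' signal follows the Hill saturation curve of the indicator at the true
#' resting [Ca2+], optionally corrupted by additive and/or multiplicative
#' noise.
#'
#' @param params a \linkS4class{GcampSimParams}.
#' @param nRois number of ROIs to generate.
#' @param seed integer seed.
#' @return data.frame with columns \code{roi_id}, \code{f_basal},
#'   \code{f_max}.
#' @examples
#' calib <- CalibrationParams(kd = 460, nHill = 2.5, dynamicRange = 32.7)
#' simulateGcampResting(GcampSimParams(100, calib), nRois = 3, seed = 1)
#' @export
simulateGcampResting <- function(params, nRois = 1L, seed = 1L) {
  stopifnot(is(params, "GcampSimParams"))
  validObject(params)
  if (nRois < 1L) .stopParam("nRois must be >= 1")
  calib <- params@calib
  theta <- params@restingCa^calib@nHill /
    (params@restingCa^calib@nHill + calib@kd^calib@nHill)
  .withSeed(seed, {
    fmax <- params@fMax *
      if (params@expressionSd > 0)
        exp(rnorm(nRois, -params@expressionSd^2 / 2, params@expressionSd))
      else rep(1, nRois)
    fmin <- fmax / calib@dynamicRange
    fb <- fmin + (fmax - fmin) * theta
    if (params@noiseCv > 0) fb <- fb * (1 + rnorm(nRois, 0, params@noiseCv))
    if (params@noiseSd > 0) fb <- fb + rnorm(nRois, 0, params@noiseSd)
    data.frame(roi_id = sprintf("roi%04d", seq_len(nRois)),
               f_basal = fb, f_max = fmax, stringsAsFactors = FALSE)
  })
}

#' Simulate FM-dye unloading traces
#'
#' Each punctum gets a half-life drawn from Normal(\code{tHalfMean},
#' \code{tHalfSd}) truncated at zero (redrawn until positive), and a trace
#' \eqn{F(t) = F_0 e^{-t \ln 2 / t_{1/2}}} sampled every
#' \code{frameInterval} seconds with additive Gaussian noise.
#'
#' @param params an \linkS4class{UnloadingSimParams}.
#' @param nPuncta number of puncta (>= 1).
#' @param seed integer seed.
#' @return list of \linkS4class{Trace} objects (epoch-free), one per
#'   punctum; the true half-lives are attached as attribute
#'   \code{"trueTHalf"}.
#' @examples
#' trs <- simulateFmUnloading(UnloadingSimParams(), nPuncta = 2, seed = 1)
#' fitUnloading(trs[[1]])
#' @export
simulateFmUnloading <- function(params, nPuncta, seed = 1L) {
  stopifnot(is(params, "UnloadingSimParams"))
  validObject(params)
  if (nPuncta < 1L) .stopParam("nPuncta must be >= 1")
  time <- seq(0, params@duration, by = params@frameInterval)
  .withSeed(seed, {
    th <- rnorm(nPuncta, params@tHalfMean, params@tHalfSd)
    while (any(th <= 0))
      th[th <= 0] <- rnorm(sum(th <= 0), params@tHalfMean, params@tHalfSd)
    traces <- lapply(seq_len(nPuncta), function(i) {
      f <- params@initialF * exp(-time * log(2) / th[i])
      if (params@noiseSd > 0) f <- f + rnorm(length(f), 0, params@noiseSd)
      Trace(time, f, roiId = sprintf("punctum%04d", i))
    })
    attr(traces, "trueTHalf") <- th
    traces
  })
}
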