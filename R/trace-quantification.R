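# Trace-processing rules: background adjustment, NH4Cl-plateau
# normalization, peak-at-stimulus-end extraction, 2-SD inclusion filtering,
# trial averaging, fEPSP rising slope, PPR, percent inhibition and
# control-mean normalization.

.epochIdx <- function(trace, name) {
  w <- epochs(trace)[[name]]
  if (is.null(w)) .stopParam("trace has no '", name, "' epoch")
  idx <- which(traceTime(trace) >= w[1] - 1e-9 &
               traceTime(trace) <= w[2] + 1e-9)
  if (!length(idx)) .stopParam("epoch '", name, "' contains no samples")
  idx
}

#' Subtract a constant background level from a trace
#'
#' Camera offset / ambient background is removed as a supplied constant per
#' trace (measured from a cell-free region); epoch annotations are
#' preserved. Applying twice with b1 then b2 equals applying once with
#' b1 + b2.
#'
#' @param trace a \linkS4class{Trace}.
#' @param backgroundLevel finite background level (a.u.).
#' @return The background-adjusted \linkS4class{Trace}.
#' @export
backgroundAdjust <- function(trace, backgroundLevel) {
  stopifnot(is(trace, "Trace"))
  if (!is.numeric(backgroundLevel) || length(backgroundLevel) != 1L ||
      !is.finite(backgroundLevel))
    .stopParam("backgroundLevel must be a single finite number")
  initialize(trace, fluorescence = traceFluorescence(trace) - backgroundLevel)
}

#' Normalize a trace to its NH4Cl (or ionophore) plateau
#'
#' Divides the whole trace by the mean fluorescence over the final 5 s of
#' the plateau epoch -- the steady-state unquench level that reports total
#' reporter expression -- so that the plateau mean becomes exactly 1 and
#' responses are comparable across boutons with different expression.
#'
#' @param trace a \linkS4class{Trace} with a \code{plateau} epoch at least
#'   5 s long.
#' @param window length of the terminal plateau window used for the
#'   normalization mean (s, default 5).
#' @return The normalized \linkS4class{Trace}.
#' @export
normalizeToPlateau <- function(trace, window = 5) {
  stopifnot(is(trace, "Trace"))
  w <- epochs(trace)$plateau
  if (is.null(w)) .stopParam("trace has no 'plateau' epoch")
  if (w[2] - w[1] < window - 1e-9)
    .stopParam("plateau epoch shorter than the ", window, " s window")
  idx <- which(traceTime(trace) >= w[2] - window - 1e-9 &
               traceTime(trace) <= w[2] + 1e-9)
  m <- mean(traceFluorescence(trace)[idx])
  if (!is.finite(m) || m <= 0)
    .stopParam("plateau mean must be positive, got ", format(m))
  initialize(trace, fluorescence = traceFluorescence(trace) / m)
}

#' Mean fluorescence over the terminal plateau window
#'
#' Companion query to \code{normalizeToPlateau}; on a normalized trace it
#' returns exactly 1.
#'
#' @inheritParams normalizeToPlateau
#' @return numeric(1), the plateau mean (a.u.).
#' @export
plateauMean <- function(trace, window = 5) {
  stopifnot(is(trace, "Trace"))
  w <- epochs(trace)$plateau
  if (is.null(w)) .stopParam("trace has no 'plateau' epoch")
  idx <- which(traceTime(trace) >= w[2] - window - 1e-9 &
               traceTime(trace) <= w[2] + 1e-9)
  mean(traceFluorescence(trace)[idx])
}

#' Peak amplitude at the end of the stimulation period
#'
#' Peak fluorescence is taken at the end of the stimulus epoch (responses
#' keep building during stimulation, so the terminal sample is the peak of
#' the evoked component; any later overshoot is ignored). A terminal
#' averaging window of more than one sample may be requested.
#'
#' @param trace a \linkS4class{Trace} with a \code{stimulus} epoch.
#' @param terminalSamples number of terminal in-stimulus samples to
#'   average (default 1).
#' @return numeric(1), the peak amplitude (a.u.).
#' @export
peakAmplitude <- function(trace, terminalSamples = 1L) {
  stopifnot(is(trace, "Trace"))
  idx <- .epochIdx(trace, "stimulus")
  take <- tail(idx, terminalSamples)
  mean(traceFluorescence(trace)[take])
}

#' Baseline noise SD of a trace
#'
#' Sample SD of fluorescence over the annotated baseline epoch; the scale
#' against which the 2-SD inclusion rule is applied.
#'
#' @param trace a \linkS4class{Trace} with a \code{baseline} epoch.
#' @return numeric(1), baseline SD (a.u.).
#' @export
baselineSd <- function(trace) {
  stopifnot(is(trace, "Trace"))
  sd(traceFluorescence(trace)[.epochIdx(trace, "baseline")])
}

#' ROI inclusion filter: signal-to-noise and ionophore-response criteria
#'
#' An ROI is included iff its mean peak response is at least \code{kSd}
#' baseline SDs (ROIs responding at less than 2 SD of baseline noise are
#' excluded by default) and, when \code{requireIonomycin} is set, it showed
#' a positive response to ionophore application. The mask is a
#' deterministic function of its inputs and invariant under any common
#' positive rescaling of amplitudes and SDs.
#'
#' @param meanAmplitude named numeric, per-ROI mean peak amplitude.
#' @param baselineSd named numeric, per-ROI baseline noise SD; names must
#'   match \code{meanAmplitude}.
#' @param kSd inclusion threshold in baseline SDs (default 2).
#' @param requireIonomycin flag; when TRUE, \code{ionomycinResponse} must
#'   be supplied and positive for inclusion.
#' @param ionomycinResponse named numeric per-ROI ionophore response.
#' @return named logical inclusion mask, aligned with
#'   \code{meanAmplitude}.
#' @examples
#' applyInclusionFilter(c(a = 5, b = 1.9), c(a = 1, b = 1))
#' @export
applyInclusionFilter <- function(meanAmplitude, baselineSd, kSd = 2,
                                 requireIonomycin = FALSE,
                                 ionomycinResponse = NULL) {
  if (is.null(names(meanAmplitude)) || is.null(names(baselineSd)))
    .stopParam("meanAmplitude and baselineSd must be named by ROI")
  if (!setequal(names(meanAmplitude), names(baselineSd)))
    .stopParam("ROI sets of meanAmplitude and baselineSd differ")
  baselineSd <- baselineSd[names(meanAmplitude)]
  mask <- meanAmplitude >= kSd * baselineSd
  if (requireIonomycin) {
    if (is.null(ionomycinResponse))
      .stopParam("requireIonomycin = TRUE needs ionomycinResponse")
    if (!setequal(names(meanAmplitude), names(ionomycinResponse)))
      .stopParam("ROI sets of meanAmplitude and ionomycinResponse differ")
    mask <- mask & ionomycinResponse[names(meanAmplitude)] > 0
  }
  mask
}

#' Pointwise average of traces on a common time grid
#'
#' @param traces list of \linkS4class{Trace} objects with identical time
#'   grids.
#' @param roiId identifier for the averaged trace (default: first trace's).
#' @return The mean \linkS4class{Trace}; epoch annotations are copied from
#'   the first trace.
#' @export
trialAverage <- function(traces, roiId = NULL) {
  if (!length(traces) || !all(vapply(traces, is, logical(1), "Trace")))
    .stopParam("traces must be a non-empty list of Trace objects")
  t0 <- traceTime(traces[[1]])
  same <- vapply(traces, function(tr)
    length(traceTime(tr)) == length(t0) &&
      all(abs(traceTime(tr) - t0) < 1e-9), logical(1))
  if (!all(same)) .stopParam("traces are not on a common time grid")
  f <- rowMeans(vapply(traces, traceFluorescence,
                       numeric(length(t0))))
  Trace(t0, f, epochs = epochs(traces[[1]]),
        roiId = if (is.null(roiId)) roiId(traces[[1]]) else roiId)
}

#' Rising slope of a field potential or fluorescence rise
#'
#' The magnitude of an fEPSP is taken as the gradient of its rising phase
#' (avoiding population-spike contamination near the peak). The rise is
#' defined from the pre-event level to the extremum; a least-squares line
#' is fitted to the samples whose amplitude lies within the stated
#' fractional range of that rise (20--80% by default).
#'
#' @param trace a \linkS4class{Trace}; if a \code{baseline} epoch is
#'   annotated the pre-event level is its mean, otherwise the first
#'   sample.
#' @param fitWindow numeric(2) fractional range of the rise (default
#'   \code{c(0.2, 0.8)}).
#' @param negative set TRUE for downward events (e.g. negative-going field
#'   potentials); the returned slope keeps its sign.
#' @return numeric(1), slope in fluorescence (or mV) per time unit.
#' @export
risingSlope <- function(trace, fitWindow = c(0.2, 0.8), negative = FALSE) {
  stopifnot(is(trace, "Trace"))
  if (length(fitWindow) != 2L || fitWindow[1] < 0 || fitWindow[2] > 1 ||
      fitWindow[1] >= fitWindow[2])
    .stopParam("fitWindow must be an increasing pair within [0, 1]")
  f <- traceFluorescence(trace)
  if (negative) f <- -f
  t <- traceTime(trace)
  base <- if (!is.null(epochs(trace)$baseline))
    mean(f[.epochIdx(trace, "baseline")]) else f[1]
  ipk <- which.max(f)
  rise <- f[ipk] - base
  if (rise <= 0) .stopParam("no rising segment found")
  lo <- base + fitWindow[1] * rise
  hi <- base + fitWindow[2] * rise
  # contiguous rising limb: walk back from the extremum
  idx <- seq_len(ipk)
  sel <- idx[f[idx] >= lo & f[idx] <= hi]
  if (length(sel) < 3L)
    .stopParam("fewer than 3 samples in the slope-fit window")
  s <- unname(coef(lm(f[sel] ~ t[sel]))[2])
  if (negative) -s else s
}

#' Paired-pulse ratio from fEPSP rising slopes
#'
#' PPR is expressed as fEPSP2/fEPSP1 (second over first rising slope); an
#' inverse correlate of release probability.
#'
#' @param fepsp1Slope,fepsp2Slope rising slopes of the first and second
#'   responses (mV/ms); vectors are paired elementwise.
#' @return numeric, the ratio(s).
#' @examples
#' pairedPulseRatio(1.0, 1.5)
#' @export
pairedPulseRatio <- function(fepsp1Slope, fepsp2Slope) {
  if (any(fepsp1Slope == 0)) .stopParam("fEPSP1 slope must be non-zero")
  fepsp2Slope / fepsp1Slope
}

#' Percent inhibition of a response relative to a reference
#'
#' Returns \code{100 * (1 - treated/reference)}; negative values indicate
#' potentiation and are not clipped. Used e.g. for the EGTA assay in which
#' the fractional reduction of exocytosis under a slow chelator reports
#' channel--sensor coupling distance.
#'
#' @param responseTreated treated-condition response(s).
#' @param responseReference reference response(s), > 0.
#' @return numeric, percent inhibition.
#' @examples
#' percentInhibition(0.5, 1.0)   # 50
#' percentInhibition(1.2, 1.0)   # -20 (potentiation)
#' @export
percentInhibition <- function(responseTreated, responseReference) {
  if (any(responseReference <= 0))
    .stopParam("reference response must be positive")
  100 * (1 - responseTreated / responseReference)
}

#' Normalize values to the control-group mean
#'
#' Divides each value by \code{mean(controlValues)} so that the normalized
#' control group averages exactly 1 (the convention for immunoblot ratios
#' and similar cross-batch comparisons).
#'
#' @param values numeric values to normalize.
#' @param controlValues non-empty control group with non-zero mean.
#' @return numeric, normalized values.
#' @export
normalizeToControlMean <- function(values, controlValues) {
  if (!length(controlValues)) .stopParam("control group is empty")
  m <- mean(controlValues)
  if (!is.finite(m) || m == 0) .stopParam("control mean must be non-zero")
  values / m
}
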