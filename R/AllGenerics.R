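# Accessor generics and show methods. Accessors are provided for the slots
# users need downstream; internal code also uses them rather than @.

#' Trace accessors
#'
#' @param x a \linkS4class{Trace}.
#' @return \code{traceTime} and \code{traceFluorescence} return numeric
#'   vectors; \code{epochs} the named list of windows; \code{roiId} the ROI
#'   identifier.
#' @aliases traceTime traceFluorescence epochs roiId
#' @name trace-accessors
NULL

#' @rdname trace-accessors
#' @export
setGeneric("traceTime", function(x) standardGeneric("traceTime"))
#' @rdname trace-accessors
#' @export
setGeneric("traceFluorescence",
           function(x) standardGeneric("traceFluorescence"))
#' @rdname trace-accessors
#' @export
setGeneric("epochs", function(x) standardGeneric("epochs"))
#' @rdname trace-accessors
#' @export
setGeneric("roiId", function(x) standardGeneric("roiId"))

#' @rdname trace-accessors
setMethod("traceTime", "Trace", function(x) x@time)
#' @rdname trace-accessors
setMethod("traceFluorescence", "Trace", function(x) x@fluorescence)
#' @rdname trace-accessors
setMethod("epochs", "Trace", function(x) x@epochs)
#' @rdname trace-accessors
setMethod("roiId", "Trace", function(x) x@roiId)

#' Extract the underlying data.frame of a TrialTable
#'
#' @param x a \linkS4class{TrialTable}.
#' @return data.frame with columns condition, bouton_id, trial_id, amplitude.
#' @export
setGeneric("trialData", function(x) standardGeneric("trialData"))
#' @rdname trialData
setMethod("trialData", "TrialTable", function(x) x@data)

#' ModelSelectionResult accessors
#'
#' @param x a \linkS4class{ModelSelectionResult}.
#' @return \code{bicTable} returns the named BIC vector, \code{deltaBic} the
#'   matrix of ordered-pair BIC differences, \code{winner} the selected
#'   hypothesis, \code{strongEvidence} whether the winner clears the
#'   conventional threshold of 10 over both alternatives, \code{nEstControl}
#'   the control channel-number estimate and \code{meanRatio} the
#'   perturbed/control mean amplitude ratio.
#' @aliases bicTable deltaBic winner strongEvidence nEstControl meanRatio
#' @name selection-accessors
NULL

#' @rdname selection-accessors
#' @export
setGeneric("bicTable", function(x) standardGeneric("bicTable"))
#' @rdname selection-accessors
#' @export
setGeneric("deltaBic", function(x) standardGeneric("deltaBic"))
#' @rdname selection-accessors
#' @export
setGeneric("winner", function(x) standardGeneric("winner"))
#' @rdname selection-accessors
#' @export
setGeneric("strongEvidence", function(x) standardGeneric("strongEvidence"))
#' @rdname selection-accessors
#' @export
setGeneric("nEstControl", function(x) standardGeneric("nEstControl"))
#' @rdname selection-accessors
#' @export
setGeneric("meanRatio", function(x) standardGeneric("meanRatio"))

#' @rdname selection-accessors
setMethod("bicTable", "ModelSelectionResult", function(x) x@bic)
#' @rdname selection-accessors
setMethod("deltaBic", "ModelSelectionResult", function(x) x@deltaBic)
#' @rdname selection-accessors
setMethod("winner", "ModelSelectionResult", function(x) x@winner)
#' @rdname selection-accessors
setMethod("strongEvidence", "ModelSelectionResult",
          function(x) x@strongEvidence)
#' @rdname selection-accessors
setMethod("nEstControl", "ModelSelectionResult", function(x) x@nEstControl)
#' @rdname selection-accessors
setMethod("meanRatio", "ModelSelectionResult", function(x) x@meanRatio)

#' UnloadingFit accessors
#'
#' @param x an \linkS4class{UnloadingFit}.
#' @return \code{tHalf} the half-life (s), \code{rateK} the decay rate
#'   (1/s), \code{rSquared} the coefficient of determination,
#'   \code{converged} the convergence flag.
#' @aliases tHalf rateK rSquared converged
#' @name unloading-accessors
NULL

#' @rdname unloading-accessors
#' @export
setGeneric("tHalf", function(x) standardGeneric("tHalf"))
#' @rdname unloading-accessors
#' @export
setGeneric("rateK", function(x) standardGeneric("rateK"))
#' @rdname unloading-accessors
#' @export
setGeneric("rSquared", function(x) standardGeneric("rSquared"))
#' @rdname unloading-accessors
#' @export
setGeneric("converged", function(x) standardGeneric("converged"))

#' @rdname unloading-accessors
setMethod("tHalf", "UnloadingFit", function(x) x@tHalf)
#' @rdname unloading-accessors
setMethod("rateK", "UnloadingFit", function(x) x@rateK)
#' @rdname unloading-accessors
setMethod("rSquared", "UnloadingFit", function(x) x@rSquared)
#' @rdname unloading-accessors
setMethod("converged", "UnloadingFit", function(x) x@converged)

setMethod("show", "ChannelModelParams", function(object) {
  cat("ChannelModelParams: N =", object@nChannels,
      " p =", object@openProb, " q =", object@unitaryAmplitude,
      " noiseSd =", object@noiseSd, "\n")
  cat("  E[amplitude] = Npq =",
      object@nChannels * object@openProb * object@unitaryAmplitude,
      "   CV^-2 (noise-free) = Np/(1-p) =",
      if (object@openProb < 1)
        object@nChannels * object@openProb / (1 - object@openProb)
      else Inf, "\n")
})

setMethod("show", "Trace", function(object) {
  cat("Trace", object@roiId, ":", length(object@time), "samples,",
      sprintf("t = [%g, %g] s", min(object@time), max(object@time)), "\n")
  if (length(object@epochs))
    cat("  epochs:", paste(sprintf("%s=[%g,%g]", names(object@epochs),
        vapply(object@epochs, `[`, numeric(1), 1L),
        vapply(object@epochs, `[`, numeric(1), 2L)), collapse = " "), "\n")
})

setMethod("show", "TrialTable", function(object) {
  d <- object@data
  cat("TrialTable:", nrow(d), "trials,",
      length(unique(paste(d$condition, d$bouton_id))), "boutons,",
      "conditions:", paste(unique(d$condition), collapse = ", "), "\n")
})

setMethod("show", "ModelSelectionResult", function(object) {
  cat("Optical fluctuation analysis - BIC model selection\n")
  cat("  winner:", object@winner,
      if (object@strongEvidence) "(strong evidence, all dBIC >= 10)"
      else "(not strong evidence)", "\n")
  cat("  BIC:", paste(sprintf("%s=%.2f", names(object@bic), object@bic),
                      collapse = "  "), "\n")
  cat(sprintf("  mean ratio (perturbed/control): %.4f\n", object@meanRatio))
  cat(sprintf("  control N estimate (p0 = %g): %.2f\n", object@p0,
              object@nEstControl))
})

setMethod("show", "UnloadingFit", function(object) {
  if (object@converged)
    cat(sprintf("UnloadingFit %s: t1/2 = %.2f s (k = %.4f 1/s, R2 = %.3f)\n",
                object@punctumId, object@tHalf, object@rateK,
                object@rSquared))
  else cat("UnloadingFit", object@punctumId, ": not converged\n")
})

setMethod("show", "THalfDistribution", function(object) {
  cat(sprintf(
    "THalfDistribution '%s': n = %d, Gaussian mu = %.2f s, sigma = %.2f s\n",
    object@group, length(object@tHalfValues), object@gaussMu,
    object@gaussSigma))
})
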