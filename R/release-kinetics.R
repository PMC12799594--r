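# FM-dye unloading kinetics: per-punctum first-order decay fits, t1/2,
# Gaussian fits to t1/2 distributions, and group comparisons.

#' Fit a first-order exponential decay to an unloading trace
#'
#' Nonlinear least squares (Levenberg-Marquardt) of
#' \eqn{F(t) = F_0 e^{-kt}} (plus a constant offset when
#' \code{baselineOffset = TRUE}), with starting values from a log-linear
#' regression. The half-life is \eqn{t_{1/2} = \ln 2 / k}. Traces without
#' a decaying signal (terminal >= initial fluorescence, or zero variance)
#' yield \code{converged = FALSE} and should be excluded downstream.
#'
#' @param trace a \linkS4class{Trace} with at least 4 samples.
#' @param baselineOffset include a constant offset term (off by default:
#'   plain first-order decay).
#' @return An \linkS4class{UnloadingFit}.
#' @examples
#' tm <- seq(0, 300, by = 15)
#' tr <- Trace(tm, 100 * exp(-tm * log(2) / 20), roiId = "p1")
#' tHalf(fitUnloading(tr))   # 20
#' @export
fitUnloading <- function(trace, baselineOffset = FALSE) {
  stopifnot(is(trace, "Trace"))
  t <- traceTime(trace); f <- traceFluorescence(trace)
  if (length(t) < 4L) .stopParam("need at least 4 samples to fit a decay")
  failed <- new("UnloadingFit", punctumId = roiId(trace), f0 = NA_real_,
                rateK = NA_real_, tHalf = NA_real_, rSquared = NA_real_,
                converged = FALSE)
  if (var(f) == 0 || f[1] <= f[length(f)]) return(failed)
  # log-linear start (positive samples only)
  pos <- f > 0
  kStart <- if (sum(pos) >= 2)
    max(-unname(coef(lm(log(f[pos]) ~ t[pos]))[2]), 1e-6) else
      log(2) / (max(t) / 2)
  fit <- tryCatch({
    if (baselineOffset)
      minpack.lm::nlsLM(f ~ f0 * exp(-k * t) + c,
                        start = list(f0 = max(f) - min(f), k = kStart,
                                     c = min(f)),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    else
      minpack.lm::nlsLM(f ~ f0 * exp(-k * t),
                        start = list(f0 = max(f), k = kStart),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
  }, error = function(e) NULL)
  if (is.null(fit)) return(failed)
  cf <- coef(fit)
  if (!is.finite(cf[["k"]]) || cf[["k"]] <= 0) return(failed)
  r2 <- 1 - sum(resid(fit)^2) / sum((f - mean(f))^2)
  new("UnloadingFit", punctumId = roiId(trace), f0 = unname(cf[["f0"]]),
      rateK = unname(cf[["k"]]), tHalf = log(2) / unname(cf[["k"]]),
      rSquared = min(max(r2, 0), 1), converged = TRUE)
}

#' Fit unloading decays to a list of traces
#'
#' Convenience wrapper over \code{fitUnloading}; non-converged fits and
#' fits below the goodness threshold are dropped with a message stating
#' the count (exclusions must stay auditable).
#'
#' @param traces list of \linkS4class{Trace} objects.
#' @param baselineOffset passed to \code{fitUnloading}.
#' @param minRSquared exclude converged fits below this R^2 (default 0.5).
#' @return list of converged \linkS4class{UnloadingFit} objects.
#' @export
fitUnloadingAll <- function(traces, baselineOffset = FALSE,
                            minRSquared = 0.5) {
  fits <- lapply(traces, fitUnloading, baselineOffset = baselineOffset)
  keep <- vapply(fits, function(f)
    converged(f) && rSquared(f) >= minRSquared, logical(1))
  if (any(!keep))
    message(sum(!keep), " of ", length(fits),
            " puncta excluded (non-converged or R^2 < ", minRSquared, ")")
  fits[keep]
}

#' Gaussian fit to a half-life distribution
#'
#' Maximum-likelihood Gaussian (mu = mean, sigma = ML standard deviation
#' with denominator n) fitted to the raw half-life values; the histogram
#' implied by \code{binWidth} is presentational only. Bin width defaults
#' to the Freedman-Diaconis rule.
#'
#' @param values numeric vector of half-lives (s), at least 10 values.
#' @param group group label.
#' @param binWidth histogram bin width (s); default Freedman-Diaconis.
#' @return A \linkS4class{THalfDistribution}.
#' @export
fitThalfGaussian <- function(values, group = "group", binWidth = NULL) {
  if (length(values) < 10L)
    .stopParam("need at least 10 half-life values, got ", length(values))
  if (any(!is.finite(values) | values <= 0))
    .stopParam("half-life values must be positive and finite")
  n <- length(values)
  mu <- mean(values)
  sigma <- sqrt(mean((values - mu)^2))
  if (sigma == 0)
    .stopParam("degenerate distribution: all half-lives identical")
  if (is.null(binWidth)) {
    binWidth <- 2 * IQR(values) / n^(1 / 3)
    if (binWidth <= 0) binWidth <- diff(range(values)) / ceiling(sqrt(n))
  }
  new("THalfDistribution", group = as.character(group),
      tHalfValues = as.numeric(values), gaussMu = mu, gaussSigma = sigma,
      binWidth = as.numeric(binWidth))
}

#' Histogram of a half-life distribution
#'
#' @param dist a \linkS4class{THalfDistribution}.
#' @return data.frame with columns \code{mid}, \code{count},
#'   \code{rel_freq} at the distribution's bin width.
#' @export
tHalfHistogram <- function(dist) {
  stopifnot(is(dist, "THalfDistribution"))
  v <- dist@tHalfValues
  breaks <- seq(floor(min(v) / dist@binWidth) * dist@binWidth,
                max(v) + dist@binWidth, by = dist@binWidth)
  counts <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE),
                     nbins = length(breaks) - 1L)
  data.frame(mid = breaks[-length(breaks)] + dist@binWidth / 2,
             count = counts, rel_freq = counts / length(v))
}

#' Compare half-life distributions across groups
#'
#' @param distributions list of \linkS4class{THalfDistribution} objects.
#' @param reference label of the reference group (default: first).
#' @return data.frame with per-group \code{group}, \code{n},
#'   \code{mean_t_half}, \code{gauss_mu}, \code{gauss_sigma} and
#'   \code{delta_vs_ref} (difference of mean t1/2 versus the reference;
#'   negative = faster unloading).
#' @export
compareUnloadingGroups <- function(distributions, reference = NULL) {
  if (length(distributions) < 2L) .stopParam("need at least 2 groups")
  labs <- vapply(distributions, function(d) d@group, character(1))
  if (is.null(reference)) reference <- labs[1]
  if (!reference %in% labs) .stopParam("unknown reference group: ", reference)
  means <- vapply(distributions, function(d) mean(d@tHalfValues),
                  numeric(1))
  data.frame(group = labs,
             n = vapply(distributions, function(d)
               length(d@tHalfValues), integer(1)),
             mean_t_half = means,
             gauss_mu = vapply(distributions, function(d) d@gaussMu,
                               numeric(1)),
             gauss_sigma = vapply(distributions, function(d) d@gaussSigma,
                                  numeric(1)),
             delta_vs_ref = means - means[labs == reference][1],
             stringsAsFactors = FALSE)
}
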