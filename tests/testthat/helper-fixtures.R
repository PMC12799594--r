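# Shared fixture builders. All synthetic, built in code at test time.

channelScenario <- function(qPerturbed = 1.1, nPerturbed = 20L,
                            pPerturbed = 0.5, nBoutons = 100L,
                            nTrials = 5L, noiseSd = 0.2, seed = 1L) {
  SimScenario(ChannelModelParams(20L, 0.5, 1, noiseSd),
              ChannelModelParams(nPerturbed, pPerturbed, qPerturbed,
                                 noiseSd),
              nBoutonsControl = nBoutons, nBoutonsPerturbed = nBoutons,
              nTrials = nTrials, seed = seed)
}

rampTrace <- function(slope = 2, n = 50L, dt = 0.1, offset = 0) {
  tm <- seq(0, by = dt, length.out = n)
  Trace(tm, offset + slope * tm,
        epochs = list(baseline = c(0, 0), stimulus = c(0, max(tm))))
}

# alpha-function synthetic fEPSP: A * (t/tau) * exp(1 - t/tau)
alphaTrace <- function(amp = 1, tau = 2, dt = 0.05, tmax = 10) {
  tm <- seq(0, tmax, by = dt)
  Trace(tm, amp * (tm / tau) * exp(1 - tm / tau))
}

expDecayTrace <- function(tHalf = 20, f0 = 100, dt = 15, duration = 300,
                          noiseSd = 0, seed = NULL, id = "p1") {
  tm <- seq(0, duration, by = dt)
  f <- f0 * exp(-tm * log(2) / tHalf)
  if (noiseSd > 0) {
    if (!is.null(seed)) set.seed(seed)
    f <- f + rnorm(length(f), 0, noiseSd)
  }
  Trace(tm, f, roiId = id)
}
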