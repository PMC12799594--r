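test_that("degenerate binomial (p = 1, no noise) yields constant amplitudes", {
  sc <- SimScenario(ChannelModelParams(10, 1, 2, 0),
                    ChannelModelParams(10, 1, 2, 0), 3, 3, 5, seed = 11)
  amp <- trialData(simulateChannelTrials(sc))$amplitude
  expect_true(all(amp == 20))
})

test_that("trial moments match the binomial model at large n", {
  # mean -> Npq, variance -> Np(1-p)q^2, CV^-2 -> Np/(1-p)
  sc <- SimScenario(ChannelModelParams(20, 0.5, 1, 0),
                    ChannelModelParams(20, 0.5, 1, 0),
                    1, 1, 1e5, seed = 101)
  amp <- with(trialData(simulateChannelTrials(sc)),
              amplitude[condition == "control"])
  expect_equal(mean(amp), 10, tolerance = 0.02)
  expect_equal(var(amp), 5, tolerance = 0.02)
  expect_equal(mean(amp)^2 / var(amp), 20, tolerance = 0.02)
})

test_that("scaling q rescales the mean but leaves CV^-2 unchanged", {
  base <- channelScenario(qPerturbed = 1, seed = 5)
  scaled <- channelScenario(qPerturbed = 1.1, seed = 5)
  a0 <- trialData(simulateChannelTrials(base))
  a1 <- trialData(simulateChannelTrials(scaled))
  x0 <- a0$amplitude[a0$condition == "perturbed"]
  x1 <- a1$amplitude[a1$condition == "perturbed"]
  # common seed: identical channel-count draws, so the q = 0 noise part
  # scales exactly (generated with noiseSd = 0 here)
  sc0 <- channelScenario(qPerturbed = 1, noiseSd = 0, seed = 5)
  sc1 <- channelScenario(qPerturbed = 1.1, noiseSd = 0, seed = 5)
  y0 <- trialData(simulateChannelTrials(sc0))
  y1 <- trialData(simulateChannelTrials(sc1))
  pert <- y0$condition == "perturbed"
  expect_equal(y1$amplitude[pert], 1.1 * y0$amplitude[pert])
  s0 <- summarizeBoutons(simulateChannelTrials(sc0))
  s1 <- summarizeBoutons(simulateChannelTrials(sc1))
  expect_equal(s1$cv2inv, s0$cv2inv)          # exact q-invariance
  expect_equal(mean(x1) / mean(x0), 1.1, tolerance = 0.02)
})

test_that("channel-trial generation is reproducible and validates inputs", {
  sc <- channelScenario(seed = 99)
  expect_identical(simulateChannelTrials(sc), simulateChannelTrials(sc))
  expect_error(SimScenario(ChannelModelParams(20, 0.5, 1),
                           ChannelModelParams(20, 0.5, 1), 5, 5,
                           nTrials = 1), "nTrials")
  expect_error(ChannelModelParams(20, 1.5, 1), "openProb")
  expect_error(ChannelModelParams(0, 0.5, 1), "nChannels")
  expect_error(ChannelModelParams(20, 0.5, -1), "unitaryAmplitude")
})

test_that("pHluorin traces carry the designed epochs and plateau", {
  p <- PhluorinSimParams(baselineLevel = 0, peakDelta = 50,
                         nh4clPlateau = 200, baselineSd = 0)
  tr <- simulatePhluorinTrace(p, seed = 3)
  expect_setequal(names(epochs(tr)), c("baseline", "stimulus", "plateau"))
  expect_equal(plateauMean(tr), 200)
  norm <- normalizeToPlateau(tr)
  expect_equal(peakAmplitude(norm), 0.25)
  # determinism
  expect_identical(simulatePhluorinTrace(p, seed = 3),
                   simulatePhluorinTrace(p, seed = 3))
})

test_that("a weak pHluorin response is caught by the 2-SD filter", {
  p <- PhluorinSimParams(baselineLevel = 0, peakDelta = 1,
                         nh4clPlateau = 200, baselineSd = 1)
  tr <- simulatePhluorinTrace(p, seed = 21)
  amp <- setNames(peakAmplitude(tr), roiId(tr))
  bsd <- setNames(baselineSd(tr), roiId(tr))
  expect_false(applyInclusionFilter(amp, bsd, kSd = 2)[[1]])
})

test_that("invalid pHluorin windows are rejected", {
  expect_error(PhluorinSimParams(stimStart = 30, stimEnd = 20), "ordered")
  expect_error(PhluorinSimParams(plateauStart = 40, plateauEnd = 43),
               "5 s")
  expect_error(PhluorinSimParams(nh4clPlateau = 0, baselineLevel = 1),
               "exceed")
})

test_that("basal GCaMP signal sits at the Hill midpoint when Ca = Kd", {
  # near-infinite dynamic range, Hill slope 1, no noise
  calib <- CalibrationParams(kd = 300, nHill = 1, dynamicRange = 1e9)
  sim <- simulateGcampResting(GcampSimParams(300, calib), nRois = 4,
                              seed = 2)
  expect_equal(sim$f_basal / sim$f_max, rep(0.5, 4), tolerance = 1e-6)
})

test_that("noise-free GCaMP signals invert to the exact resting [Ca2+]", {
  calib <- exampleCalibration()
  for (ca in c(50, 100, 160, 400)) {
    sim <- simulateGcampResting(GcampSimParams(ca, calib, expressionSd = 0.2),
                                nRois = 10, seed = 7)
    expect_equal(restingCalcium(sim$f_basal, sim$f_max, calib),
                 rep(ca, 10), tolerance = 1e-9)
  }
  expect_error(GcampSimParams(-5, calib), "restingCa")
})

test_that("FM unloading traces follow the designed first-order decay", {
  p <- UnloadingSimParams(tHalfMean = 20, tHalfSd = 0, noiseSd = 0)
  trs <- simulateFmUnloading(p, nPuncta = 3, seed = 4)
  tr <- trs[[1]]
  expect_equal(traceFluorescence(tr),
               100 * 2^(-traceTime(tr) / 20), tolerance = 1e-12)
  # F at one half-life is half of F at time 0 by construction
  expect_equal(100 * exp(-20 * log(2) / 20) / 100, 0.5)
  fits <- lapply(trs, fitUnloading)
  th <- vapply(fits, tHalf, numeric(1))
  expect_equal(th, rep(20, 3), tolerance = 1e-6)  # degenerate t1/2 spread
  expect_error(UnloadingSimParams(frameInterval = 15, duration = 20),
               "duration")
  expect_error(simulateFmUnloading(p, nPuncta = 0), "nPuncta")
})

test_that("per-punctum half-lives are positive and seed-stable", {
  p <- UnloadingSimParams(tHalfMean = 10, tHalfSd = 8, noiseSd = 1)
  trs <- simulateFmUnloading(p, nPuncta = 50, seed = 8)
  expect_true(all(attr(trs, "trueTHalf") > 0))
  trs2 <- simulateFmUnloading(p, nPuncta = 50, seed = 8)
  expect_identical(lapply(trs, traceFluorescence),
                   lapply(trs2, traceFluorescence))
})

test_that("generators leave the global RNG state untouched", {
  set.seed(123); before <- .Random.seed
  invisible(simulateChannelTrials(channelScenario(seed = 1)))
  invisible(simulateFmUnloading(UnloadingSimParams(), 2, seed = 1))
  expect_identical(.Random.seed, before)
})
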