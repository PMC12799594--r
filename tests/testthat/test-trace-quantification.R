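test_that("background adjustment is a shift that composes additively", {
  tr <- Trace(0:9, rep(10, 10))
  expect_equal(traceFluorescence(backgroundAdjust(tr, 10)), rep(0, 10))
  expect_equal(backgroundAdjust(tr, 0), tr)
  expect_equal(backgroundAdjust(backgroundAdjust(tr, 3), 4),
               backgroundAdjust(tr, 7))
})

test_that("plateau normalization divides by the terminal 5-s plateau mean", {
  tm <- seq(0, 50, by = 1)
  f <- ifelse(tm < 40, ifelse(tm >= 10 & tm <= 20, 50 * (tm - 10) / 10, 0),
              200)
  tr <- Trace(tm, f, epochs = list(baseline = c(0, 10),
                                   stimulus = c(10, 20),
                                   plateau = c(40, 50)))
  norm <- normalizeToPlateau(tr)
  expect_equal(peakAmplitude(norm), 0.25)
  expect_equal(plateauMean(norm), 1.0)
  # idempotence: renormalizing a normalized trace changes nothing
  expect_equal(normalizeToPlateau(norm), norm)
  # guards
  zero <- Trace(tm, 0 * f, epochs = epochs(tr))
  expect_error(normalizeToPlateau(zero), "positive")
  noPlateau <- Trace(tm, f, epochs = list(baseline = c(0, 10),
                                          stimulus = c(10, 20)))
  expect_error(normalizeToPlateau(noPlateau), "plateau")
  short <- Trace(tm, f, epochs = list(plateau = c(40, 43)))
  expect_error(normalizeToPlateau(short), "shorter")
})

test_that("peak is read at the end of the stimulation period", {
  tm <- seq(0, 10, by = 1)
  # rising ramp to 0.4 at stimulus end, overshoot afterwards
  f <- c(0, 0, 0.1, 0.2, 0.3, 0.4, 0.9, 0.8, 0.2, 0.1, 0)
  tr <- Trace(tm, f, epochs = list(baseline = c(0, 1), stimulus = c(1, 5)))
  expect_equal(peakAmplitude(tr), 0.4)
  # terminal averaging window of 3 samples
  tr2 <- Trace(tm, c(0, 0, 0.1, 0.3, 0.4, 0.5, 0.9, 0, 0, 0, 0),
               epochs = list(baseline = c(0, 1), stimulus = c(1, 5)))
  expect_equal(peakAmplitude(tr2, terminalSamples = 3), 0.4)
  expect_error(peakAmplitude(Trace(tm, f)), "stimulus")
})

test_that("inclusion filter applies the k-SD rule with boundary included", {
  expect_true(applyInclusionFilter(c(r = 5), c(r = 1))[[1]])
  expect_false(applyInclusionFilter(c(r = 1.9), c(r = 1))[[1]])
  expect_true(applyInclusionFilter(c(r = 2), c(r = 1))[[1]])  # mean == 2 SD
  expect_error(applyInclusionFilter(c(a = 1), c(b = 1)), "ROI sets")
})

test_that("packaged fixture yields exactly 7 of 10 included ROIs", {
  fx <- read.csv(system.file("extdata", "inclusion_fixture_synthetic.csv",
                             package = "presynquant"))
  mask <- applyInclusionFilter(
    setNames(fx$mean_amplitude, fx$roi_id),
    setNames(fx$baseline_sd, fx$roi_id), kSd = 2,
    requireIonomycin = TRUE,
    ionomycinResponse = setNames(fx$ionomycin_response, fx$roi_id))
  expect_identical(sum(mask), 7L)
  # bit-stable on repetition
  expect_identical(mask, applyInclusionFilter(
    setNames(fx$mean_amplitude, fx$roi_id),
    setNames(fx$baseline_sd, fx$roi_id), kSd = 2,
    requireIonomycin = TRUE,
    ionomycinResponse = setNames(fx$ionomycin_response, fx$roi_id)))
})

test_that("inclusion mask is invariant under common positive rescaling", {
  set.seed(42)
  amp <- setNames(runif(20, 0, 6), paste0("r", 1:20))
  bsd <- setNames(runif(20, 0.5, 2), paste0("r", 1:20))
  m0 <- applyInclusionFilter(amp, bsd)
  for (s in c(0.01, 0.5, 3, 1000))
    expect_identical(applyInclusionFilter(s * amp, s * bsd), m0)
})

test_that("ionomycin non-responders are excluded when required", {
  amp <- c(a = 5, b = 5); bsd <- c(a = 1, b = 1)
  iono <- c(a = 3, b = 0)
  m <- applyInclusionFilter(amp, bsd, requireIonomycin = TRUE,
                            ionomycinResponse = iono)
  expect_identical(unname(m), c(TRUE, FALSE))
  expect_error(applyInclusionFilter(amp, bsd, requireIonomycin = TRUE),
               "ionomycinResponse")
})

test_that("trial averaging is the pointwise mean and reduces noise", {
  tm <- seq(0, 5, by = 0.5)
  a <- Trace(tm, sin(tm), epochs = list(baseline = c(0, 1)))
  expect_equal(trialAverage(list(a, a)), a)
  b <- Trace(tm, -sin(tm), epochs = list(baseline = c(0, 1)))
  expect_equal(traceFluorescence(trialAverage(list(a, b))),
               rep(0, length(tm)))
  # residual SD of a 10-trial average of sd-1 noise ~ 1/sqrt(10)
  set.seed(9)
  tmLong <- seq(0, 100, by = 0.1)
  noisy <- lapply(1:10, function(i) Trace(tmLong, rnorm(length(tmLong))))
  resid <- sd(traceFluorescence(trialAverage(noisy)))
  expect_equal(resid, 1 / sqrt(10), tolerance = 0.1)
  expect_error(trialAverage(list(a, Trace(tm + 0.1, sin(tm)))),
               "common time grid")
})

test_that("trial averaging commutes with background adjustment", {
  tm <- seq(0, 5, by = 0.5)
  trs <- lapply(1:4, function(i) Trace(tm, i * cos(tm)))
  expect_equal(
    backgroundAdjust(trialAverage(trs), 2.5),
    trialAverage(lapply(trs, backgroundAdjust, backgroundLevel = 2.5)))
})

test_that("rising slope recovers a ramp gradient, shift-invariantly", {
  expect_equal(risingSlope(rampTrace(slope = 2)), 2, tolerance = 1e-9)
  expect_equal(risingSlope(rampTrace(slope = 2, offset = 7)), 2,
               tolerance = 1e-9)
  flat <- Trace(0:10, rep(1, 11))
  expect_error(risingSlope(flat), "rising")
})

test_that("rising slope of an alpha-function matches a dense-grid fit", {
  coarse <- alphaTrace(amp = 1.5, tau = 2, dt = 0.05)
  dense <- alphaTrace(amp = 1.5, tau = 2, dt = 0.0005)
  expect_equal(risingSlope(coarse), risingSlope(dense), tolerance = 0.05)
})

test_that("paired-pulse ratio is fEPSP2/fEPSP1", {
  expect_equal(pairedPulseRatio(1.0, 1.5), 1.5)
  expect_equal(pairedPulseRatio(2.0, 2.0), 1.0)
  expect_equal(pairedPulseRatio(2.0, 1.0), 0.5)
  expect_error(pairedPulseRatio(0, 1), "non-zero")
})

test_that("percent inhibition keeps sign for potentiation", {
  expect_equal(percentInhibition(0.5, 1.0), 50)
  expect_equal(percentInhibition(1.0, 1.0), 0)
  expect_equal(percentInhibition(1.2, 1.0), -20)
  expect_error(percentInhibition(1, 0), "positive")
})

test_that("control-mean normalization sets the control average to 1", {
  expect_equal(normalizeToControlMean(2, c(1, 1, 1)), 2)
  ctrl <- c(2, 4)
  expect_equal(mean(normalizeToControlMean(ctrl, ctrl)), 1)
  expect_equal(normalizeToControlMean(c(3, 6), ctrl), c(1, 2))
  expect_error(normalizeToControlMean(1, numeric(0)), "empty")
  expect_error(normalizeToControlMean(1, c(-1, 1)), "non-zero")
})

test_that("trace and trial-table CSV round trips preserve the data", {
  dir <- withr::local_tempdir()
  tr <- simulatePhluorinTrace(PhluorinSimParams(baselineSd = 0.5), seed = 6)
  p <- file.path(dir, "traces.csv")
  writeTraceCsv(tr, p)
  back <- readTraceCsv(p)[[1]]
  expect_equal(traceFluorescence(back), traceFluorescence(tr))
  expect_equal(epochs(back), lapply(epochs(tr), as.numeric))
  tt <- simulateChannelTrials(channelScenario(nBoutons = 5, seed = 2))
  p2 <- file.path(dir, "trials.csv")
  writeTrialTable(tt, p2)
  expect_equal(trialData(readTrialTable(p2)), trialData(tt))
  expect_error(readTrialTable(file.path(dir, "nope.csv")), "not found")
})
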