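test_that("bouton summaries match hand-computed statistics", {
  tt <- TrialTable(data.frame(condition = "c", bouton_id = "b1",
                              trial_id = 1:5,
                              amplitude = c(10, 10, 10, 10, 12)))
  s <- summarizeBoutons(tt)
  expect_equal(s$mean_amp, 10.4)
  expect_equal(s$sd_amp, sqrt(0.8))           # 0.8944...
  expect_equal(s$cv2inv, 10.4^2 / 0.8)        # 135.2
  expect_equal(s$n_trials, 5L)
})

test_that("zero-variance boutons are excluded with a warning", {
  tt <- TrialTable(data.frame(
    condition = "c", bouton_id = rep(c("b1", "b2"), each = 3),
    trial_id = rep(1:3, 2), amplitude = c(5, 5, 5, 4, 5, 6)))
  expect_warning(s <- summarizeBoutons(tt), "zero trial variance")
  expect_identical(s$bouton_id, "b2")
})

test_that("noise correction subtracts the known noise variance", {
  tt <- TrialTable(data.frame(condition = "c", bouton_id = "b1",
                              trial_id = 1:4, amplitude = c(8, 10, 10, 12)))
  plain <- summarizeBoutons(tt)
  corr <- summarizeBoutons(tt, noiseSd = 1)
  expect_equal(corr$cv2inv,
               plain$mean_amp^2 / (plain$sd_amp^2 - 1))
})

test_that("empirical CV^-2 approaches Np/(1-p) and the pooled aggregate is
          unbiased at few trials", {
  sc <- channelScenario(qPerturbed = 1, nBoutons = 500, noiseSd = 0,
                        seed = 31)
  st <- summarizeBoutons(simulateChannelTrials(sc))
  agg <- aggregateCv2inv(st)[["control"]]
  expect_equal(agg, 20, tolerance = 0.1)
  # the per-bouton mean CV^-2 is strongly upward-biased at 5 trials
  # (E[1/chi^2_4] inflation ~ factor 2); the pooled estimator is not
  cs <- conditionSummary(st)
  expect_gt(cs$mean_cv2inv[cs$condition == "control"], 1.5 * agg)
})

test_that("channel-number estimation inverts CV^-2 = Np/(1-p)", {
  expect_equal(estimateN(19.5, 0.5), 19.5)   # p/(1-p) = 1 fixed point
  expect_equal(estimateN(10, 0.2), 40)
  expect_error(estimateN(10, 0), "p0")
  expect_error(estimateN(10, 1), "p0")
  expect_error(estimateN(-1, 0.5), "positive")
})

test_that("predicted CV^-2 follows each single-parameter hypothesis", {
  expect_equal(predictCv2inv("N", 19.5, 1.10), 21.45)
  expect_equal(predictCv2inv("p", 19.5, 1.10, p0 = 0.5),
               19.5 * (0.55 / 0.45))          # 23.8333...
  # q hypothesis: exactly constant over any grid of mean ratios
  for (r in seq(0.5, 1.9, by = 0.1))
    expect_identical(predictCv2inv("q", 19.5, r), 19.5)
  # identity ratio returns the baseline for every hypothesis
  expect_equal(predictCv2inv("N", 19.5, 1), 19.5)
  expect_equal(predictCv2inv("p", 19.5, 1, p0 = 0.5), 19.5)
})

test_that("p-hypothesis prediction is increasing and convex, and errors
          when infeasible", {
  r <- seq(1, 1.9, by = 0.05)
  pred <- vapply(r, function(x) predictCv2inv("p", 19.5, x, p0 = 0.5),
                 numeric(1))
  expect_true(all(diff(pred) > 0))
  expect_true(all(diff(diff(pred)) > 0))
  predN <- vapply(r, function(x) predictCv2inv("N", 19.5, x), numeric(1))
  expect_true(all(diff(predN) > 0))
  expect_error(predictCv2inv("p", 19.5, 2.1, p0 = 0.5), "infeasible")
  expect_error(predictCv2inv("p", 19.5, 1.1), "p0")
})

test_that("a q-only enhancement is attributed to q", {
  tt <- simulateChannelTrials(channelScenario(qPerturbed = 1.1, seed = 7))
  res <- selectModel(tt, p0 = 0.5)
  expect_identical(winner(res), "q")
  expect_true(strongEvidence(res))
  expect_equal(meanRatio(res), 1.1, tolerance = 0.05)
  # delta-BIC bookkeeping
  d <- deltaBic(res)
  expect_equal(d["N", "q"], bicTable(res)[["N"]] - bicTable(res)[["q"]])
  expect_true(all(diag(d) == 0))
})

test_that("a strong N-only enhancement is attributed to N", {
  tt <- simulateChannelTrials(channelScenario(nPerturbed = 30, seed = 13))
  res <- selectModel(tt, p0 = 0.5)
  expect_identical(winner(res), "N")
})

test_that("identical conditions give no strong evidence for any model", {
  tt <- simulateChannelTrials(channelScenario(qPerturbed = 1, seed = 17))
  res <- selectModel(tt, p0 = 0.5)
  off <- deltaBic(res)[upper.tri(deltaBic(res)) |
                       lower.tri(deltaBic(res))]
  expect_true(all(abs(off) < 10))
  expect_false(strongEvidence(res))
  # analytic predictions coincide at mean ratio exactly 1
  expect_equal(predictCv2inv("N", 20, 1), predictCv2inv("q", 20, 1))
  expect_equal(predictCv2inv("p", 20, 1, 0.5), predictCv2inv("q", 20, 1))
})

test_that("swapping condition labels inverts the mean ratio", {
  tt <- simulateChannelTrials(channelScenario(qPerturbed = 1.1, seed = 23))
  a <- selectModel(tt, p0 = 0.5, control = "control")
  b <- selectModel(tt, p0 = 0.5, control = "perturbed")
  expect_equal(meanRatio(a), 1 / meanRatio(b), tolerance = 1e-12)
})

test_that("an infeasible p hypothesis gets +Inf BIC with a note", {
  tt <- simulateChannelTrials(channelScenario(qPerturbed = 1.6, seed = 3))
  expect_message(res <- selectModel(tt, p0 = 0.8), "infeasible")
  expect_identical(bicTable(res)[["p"]], Inf)
  expect_identical(winner(res), "q")
})

test_that("the CV^-2 summary likelihood variant runs and reports
          predictions", {
  tt <- simulateChannelTrials(channelScenario(qPerturbed = 1.1, seed = 29))
  res <- selectModel(tt, p0 = 0.5, likelihood = "cv2gaussian")
  expect_s4_class(res, "ModelSelectionResult")
  expect_true(all(is.finite(bicTable(res))))
  expect_true(winner(res) %in% c("N", "p", "q"))
  pred <- res@details$predictedCv2inv
  expect_equal(pred[["N"]],
               res@details$baselineCv2inv * meanRatio(res))
  expect_equal(pred[["q"]], res@details$baselineCv2inv)
})

test_that("selectModel validates its inputs", {
  tt <- simulateChannelTrials(channelScenario(seed = 1, nBoutons = 5))
  expect_error(selectModel(tt), "p0")
  expect_error(selectModel(tt, p0 = 1.2), "p0")
  one <- TrialTable(subset(trialData(tt), condition == "control"))
  expect_error(selectModel(one, p0 = 0.5), "two conditions")
  expect_error(selectModel(tt, p0 = 0.5, control = "nope"), "unknown")
})

test_that("prediction curves cover the three hypotheses on a ratio grid", {
  st <- summarizeBoutons(
    simulateChannelTrials(channelScenario(seed = 19, nBoutons = 30)))
  pc <- predictionCurves(st, p0 = 0.5)
  expect_setequal(unique(pc$curves$hypothesis), c("N", "p", "q"))
  qc <- subset(pc$curves, hypothesis == "q")
  expect_equal(var(qc$predicted_cv2inv), 0)   # flat line
  expect_identical(nrow(pc$observed), 2L)
})
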