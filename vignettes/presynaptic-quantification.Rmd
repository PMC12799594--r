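---
title: "Quantifying presynaptic function: fluctuation analysis, calibration and release kinetics"
author: "presynquant authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying presynaptic function}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(presynquant)
```

## What this package computes

presynquant implements the quantitative core of a presynaptic imaging and
electrophysiology workflow:

* **Trace quantification** for pHluorin exocytosis reporters and
  presynaptic Ca^2+^ indicators: constant-background adjustment,
  normalization to the NH~4~Cl unquench plateau, peak extraction at the end
  of the stimulation period, trial averaging, and the 2-SD / ionophore
  inclusion filters.
* **Optical fluctuation analysis (OFA)** of single-stimulus Ca^2+^
  transients under a binomial model of voltage-gated Ca^2+^-channel (VGCC)
  gating, with BIC selection among channel-number (N), open-probability
  (p) and unitary-signal (q) explanations of a mean change.
* **Resting-[Ca^2+^] calibration** from basal and ionomycin-saturated
  indicator signals by Hill-equation inversion.
* **FM-dye unloading kinetics**: per-punctum first-order decay fits,
  half-lives, Gaussian fits to half-life distributions, group comparisons.
* **Field-potential summaries**: rising-slope estimation and paired-pulse
  ratios (PPR = fEPSP2/fEPSP1), plus percent inhibition and control-mean
  normalization.

A seeded synthetic-data module generates every input the pipeline consumes
with the statistical structure these analyses assume, so each estimator is
validated by parameter recovery end to end.

## The binomial channel model and CV^-2^

A bouton's single-stimulus Ca^2+^ transient amplitude is modelled as

$$A = qK + \varepsilon,\qquad K \sim \mathrm{Bin}(N, p),\qquad
\varepsilon \sim \mathcal N(0, \sigma^2),$$

where $N$ is the number of functional VGCCs at the terminal, $p$ their
open probability per action potential, $q$ the fluorescence contribution
of one open channel, and $\sigma$ additive measurement noise. Hence

$$\mathbb E[A] = Npq, \qquad \mathrm{Var}[A] = Np(1-p)q^2 + \sigma^2,$$

and with negligible noise the inverse squared coefficient of variation is

$$\mathrm{CV}^{-2} = \frac{\mathbb E[A]^2}{\mathrm{Var}[A]} =
\frac{Np}{1-p}.$$

The key structure exploited by OFA: CV^-2^ is proportional to $N$,
increasing in $p$, and **independent of $q$**. A change in mean influx
that leaves CV^-2^ untouched therefore points at the unitary current,
while N- or p-mediated changes move CV^-2^ in hypothesis-specific ways
(`predictCv2inv()` encodes the three predictions; for the p hypothesis the
implied perturbed open probability is $p' = p_0 r$ for mean ratio $r$,
which is infeasible when $p_0 r \ge 1$ and is then reported as such).

```{r cv2-predictions}
predictCv2inv("N", 19.5, 1.10)        # CV^-2 scales with N
predictCv2inv("p", 19.5, 1.10, 0.5)   # p' = 0.55 raises CV^-2 further
predictCv2inv("q", 19.5, 1.10)        # q leaves CV^-2 unchanged
```

The open probability cannot be measured optically; `estimateN()` and
`selectModel()` therefore require an explicit, literature-sourced `p0` and
refuse to default it.

## Model selection: likelihood choice

The analysis framework states only that hypotheses are compared by BIC
($k\ln n - 2\ln\hat L$, differences of 10+ treated as strong evidence);
the likelihood is a design choice, and it matters.

**Default (`likelihood = "quantal"`).** We use the generative model
itself: trial amplitudes follow the binomial--Gaussian mixture
$\sum_k \mathrm{Bin}(k; N, p)\,\mathcal N(kq, \sigma^2)$. Control
parameters ($N$ integer, $q$, $\sigma$; $p = p_0$ fixed) are estimated by
maximum likelihood first; the perturbed condition is then refitted three
times, freeing exactly one quantal parameter plus $\sigma$, so every
hypothesis spends $k = 2$ parameters and BIC differences reflect fit
alone. The mixture surface has a narrow ridge when the unitary spacing
$q$ is resolvable against the noise; the optimiser therefore combines a
profiled integer-$N$ grid, lattice-residual-based $\sigma$ starting
values, multi-start Nelder--Mead, and a numerical floor of $10^{-3} q$ on
$\sigma$ (degenerate $\sigma \to 0$ likelihoods are unbounded on lattice
data).

**Alternative (`likelihood = "cv2gaussian"`).** A Gaussian likelihood on
the per-bouton CV^-2^ values of the perturbed condition around each
hypothesis's analytic prediction, residual variance at its ML estimate
(again $k = 2$). This summary-level construction is natural on the
CV^-2^-versus-mean plane, but at few trials per bouton it has very little
power: with $m$ trials the per-bouton CV^-2^ estimator contains a
$1/\chi^2_{m-1}$ factor, which at $m = 5$ has *infinite variance* and a
~2x upward bias. In recovery simulations at a five-trial, ~500-bouton
design and a 10% effect it identifies the generating hypothesis in fewer
than 10% of replicates, which is why it is not the default.

An information-theoretic note: at that design, effect-size 10%, the
N-only and p-only data-generating distributions (same amplitude lattice,
nearly matched means) are separated by an exact Kullback--Leibler
divergence corresponding to an expected $\Delta\mathrm{BIC}$ of only
$\approx 15$ with SD $\approx 7$. Even the oracle likelihood with known
parameters therefore clears the strong-evidence threshold of 10 in only
~76% of replicates for those pairs; the implemented quantal likelihood
performs at that ceiling (and identifies the correct *winner* in
97--100%). Only much larger effects, more trials, or more boutons can
make N-vs-p strong evidence routine. The q hypothesis, by contrast, is
essentially always resolved with overwhelming evidence when the unitary
spacing is resolvable.

```{r ofa-demo}
sc <- SimScenario(ChannelModelParams(20, 0.5, 1.0, noiseSd = 0.2),
                  ChannelModelParams(20, 0.5, 1.1, noiseSd = 0.2),
                  nBoutonsControl = 100, nBoutonsPerturbed = 100,
                  nTrials = 5, seed = 7)
trials <- simulateChannelTrials(sc)
selectModel(trials, p0 = 0.5)
```

### Estimating N: which CV^-2^ to invert

`summarizeBoutons()` reports per-bouton CV^-2^ (the quantity plotted on
the CV^-2^-versus-mean plane via `conditionSummary()` and
`predictionCurves()`), but for inverting $\mathrm{CV}^{-2} = Np/(1-p)$
into a channel count the package uses `aggregateCv2inv()`: the pooled
ratio (grand mean of bouton means)^2^ / (mean of per-bouton variances).
The mean of per-bouton ratios is biased upward by the $1/\chi^2$ factor
described above (about 2x at five trials) and would roughly double the N
estimate; the pooled ratio-of-means estimator is unbiased to $O(1/n)$ and
recovers the generating N within a few percent at a 500-bouton,
five-trial design.

## Trace-processing conventions

Several rules in the imaging literature leave room for interpretation;
the package fixes them as follows, each configurable where noted:

* **Baseline noise for the 2-SD filter** is the SD over the annotated
  baseline epoch of the (trial-averaged) trace, matching the convention of
  filtering on the averaged response. The threshold multiple `kSd`
  defaults to 2; the boundary case (mean exactly k SD) is included.
* **Plateau normalization** divides by the mean over the *final* 5 s of
  the plateau epoch -- the steady state -- since only the window length is
  conventionally specified. After normalization the plateau mean is
  exactly 1.
* **Peak = value at the end of the stimulation period** (the evoked
  response accumulates during the train); a terminal averaging window of
  more than one sample is available.
* **fEPSP rising slope** is fitted over the 20--80% fractional range of
  the rise by default -- the standard convention that avoids
  population-spike contamination near the peak -- and is configurable.
* **Background adjustment** subtracts a supplied constant per trace;
  frame-wise blank-ROI subtraction can be emulated upstream by passing an
  adjusted trace.

## Resting-calcium calibration

With indicator constants $K_d$, Hill coefficient $n$ and dynamic range
$R_f = F_{max}/F_{min}$, and a per-ROI ionomycin-saturated maximum
$F_{max}$,

$$[\mathrm{Ca}^{2+}]_{rest} = K_d\left(
\frac{F_{basal} - F_{min}}{F_{max} - F_{basal}}\right)^{1/n},
\qquad F_{min} = F_{max}/R_f.$$

$F_{min}$ is inferred from the dynamic range rather than measured,
because the protocol records only basal and saturated signals. The
computation is scale-invariant (expression level cancels) and strictly
increasing in $F_{basal}$; basal signals outside $[F_{min}, F_{max}]$ are
rejected rather than clipped. Calibration constants are **required
configuration**: published values differ across indicator variants and
conditions, so the package ships only a clearly marked example set
(GCaMP5-like: $K_d$ 460 nM, $n$ 2.5, $R_f$ 32.7) in
`inst/extdata/gcamp5_calibration_example.yaml`.

```{r calcium}
calib <- exampleCalibration()
gA <- simulateGcampResting(GcampSimParams(100, calib, noiseCv = 0.05),
                           nRois = 100, seed = 1)
gB <- simulateGcampResting(GcampSimParams(160, calib, noiseCv = 0.05),
                           nRois = 100, seed = 2)
groupDeltaCalcium(restingCalcium(gA$f_basal, gA$f_max, calib),
                  restingCalcium(gB$f_basal, gB$f_max, calib))
```

## FM-dye unloading kinetics

Per-punctum destaining is fitted as plain first-order decay
$F(t) = F_0 e^{-kt}$ (a constant-offset variant is available but off by
default, keeping to the first-order form), with $t_{1/2} = \ln 2 / k$
exactly. Fits are by Levenberg--Marquardt nonlinear least squares with
log-linear starting values; non-converged fits and fits with
$R^2 < 0.5$ (threshold configurable) are excluded with a logged count so
group n's remain auditable. The Gaussian describing a group's half-life
distribution is fitted by closed-form maximum likelihood on the **raw**
half-lives, not on binned counts -- the histogram (Freedman--Diaconis bin
width by default) is presentational.

## What the generators emulate -- and what they do not

The synthetic module reproduces the statistical skeleton each analysis
assumes: binomially gated trial amplitudes with additive Gaussian noise
(negative amplitudes possible, preserving moment identities; an optional
lognormal per-bouton heterogeneity factor on q exists but defaults off
because the OFA math assumes within-condition homogeneity); pHluorin
traces with baseline/stimulus/plateau epochs; Hill-model basal/maximal
indicator pairs with lognormal expression spread; truncated-Gaussian
half-life cohorts sampled at 15-s frames. Defaults mirror the designed
study conditions: five-trial averages, ~500 boutons per condition for
OFA-scale simulations, two-group calcium cohorts of 100 ROIs at 100 and
160 nM (a 60 nM difference), and 400-puncta FM cohorts with half-lives
Normal(20 s, 4 s).

They do **not** emulate pixel-level image formation, bleaching or drift,
action-potential waveform variability, vesicle-pool depletion during
trains, or bouton-to-bouton parameter covariance. Passing recovery tests
therefore validates the estimators under the stated model, not the
upstream imaging steps. Measurement-noise magnitudes are assumptions
(e.g. trial noise SD 0.2 a.u. against a unitary amplitude of 1, chosen so
per-bouton CV stays within ~1% of the binomial prediction), not measured
values.

## Numerical choices and degenerate inputs

* Boutons with zero trial variance are excluded from CV^-2^ summaries
  with a warning (the statistic is undefined there).
* The optional noise-corrected CV^-2^ replaces $s^2$ by
  $\max(s^2 - \sigma_{noise}^2, \epsilon)$ with machine-epsilon floor; it
  is off by default since imaging-noise subtraction is not part of the
  standard recipe.
* An infeasible p hypothesis gets BIC $+\infty$ and a note rather than
  silent exclusion, preserving three-way comparison semantics.
* Sample SDs use the $n-1$ denominator (trial counts of 5--10); the
  Gaussian fit to half-life cohorts uses the ML ($n$) denominator, as
  stated, where cohorts are hundreds of puncta.
* All generators use one root seed with derived per-stage child streams
  (`deriveSeeds()`), restore the global RNG state, and are bit-reproducible
  given (parameters, seed).

Problem sizes used by the validation suite -- $10^5$ trials for
closed-form moment checks, 100 replicates per scenario for recovery
rates, 500 boutons x 5 trials for N recovery, 400 puncta for FM recovery
-- were chosen as the package's own validation design, matching the
designed study scales above.

## End-to-end runs

`runPipeline()` executes configured stages (simulate where inputs are not
provided, quantify, OFA, calcium, FM) from a YAML config, writes CSV/JSON
outputs, and embeds seed, package version, config hash and per-stage
record and exclusion counts in its report:

```{r pipeline, eval = FALSE}
report <- runPipeline(system.file("extdata", "demo_config.yaml",
                                  package = "presynquant"))
report$stages$ofa$winner
```

A thin command-line wrapper over these functions is installed at
`system.file("scripts", "presynquant.R", package = "presynquant")`.

## Known limitations

* OFA assumes a single homogeneous (N, p, q) per condition; real boutons
  are heterogeneous, which inflates apparent variance and biases CV^-2^
  downward relative to the homogeneous model.
* The quantal likelihood's power to separate N from p rests entirely on
  the variance channel once means are matched; at small effects this is
  information-limited regardless of method (see above).
* The calibration module is single-wavelength and equilibrium-only; no
  ratiometric or kinetic correction.
* `fitUnloading` models mono-exponential unloading; strongly bi-phasic
  destaining will be flagged only through low $R^2$.
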