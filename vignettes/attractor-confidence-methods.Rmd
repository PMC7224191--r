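---
title: "Modelling decisions, confidence and sequential effects with a two-pool attractor network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling decisions, confidence and sequential effects with a two-pool attractor network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynconf)
```

## The model

`dynconf` simulates two-alternative perceptual decisions (clockwise vs
counter-clockwise, `C` / `AC`) with a reduced attractor network of two
competing units, each standing for an excitatory pool selective for one
category. The state of each pool is its NMDA synaptic gating variable
$S_i \in [0, 1]$:

$$\frac{dS_i}{dt} = -\frac{S_i}{\tau_S} + (1 - S_i)\,\gamma\, f(I_{i,\mathrm{tot}}),$$

where $f$ is the effective input–output relation
$f(I) = (aI - b)\,/\,(1 - e^{-d(aI - b)})$, continuous at $aI = b$ with value
$1/d$. The total current to pool $i$ sums self-excitation $J_{\mathrm{self}}
S_i$, mutual inhibition $-J_{\mathrm{cross}} S_j$, a stimulus-selective drive
$J_{\mathrm{ext}}(1 \pm c_\theta)$ (positive sign for the favored pool), an
Ornstein–Uhlenbeck noise current with mean $I_0$, time constant
$\tau_{\mathrm{noise}}$ and amplitude $\sigma_{\mathrm{noise}}$, and — after a
decision — a corollary-discharge current
$-I_{CD,\max} e^{-(t - t_D)/\tau_{CD}}$ injected into both pools.

A decision is made when either firing rate $r_i = f(I_{i,\mathrm{tot}})$
first crosses a threshold $z$; the balance of neural evidence
$\Delta r = |r_C - r_{AC}|$ at that instant is the substrate of confidence.
The corollary discharge then pushes the network away from the reached
attractor, but relaxation is generally incomplete at the next stimulus onset,
so successive decisions interact purely through the carried-over state —
no parameter changes between trials.

The stimulus strength is tied to the Gabor orientation $\theta$ (degrees) by
$c_\theta = \alpha_1 |\theta| + \alpha_2 \theta^2$, with $\alpha_1, \alpha_2$
and $z$ participant-specific.

## Parameters and defaults

The fixed network constants are the published values of this reduced-model
family: $a = 270$ Hz/nA, $b = 108$ Hz, $d = 0.154$ s, $\gamma = 0.641$,
$\tau_S = 100$ ms, $\sigma_{\mathrm{noise}} = 0.02$ nA,
$\tau_{\mathrm{noise}} = 2$ ms, $I_0 = 0.3255$ nA,
$J_{\mathrm{self}} = 0.2609$ nA, $J_{\mathrm{cross}} = 0.0497$ nA, with
shared corollary-discharge values $I_{CD,\max} = 0.033$ nA and
$\tau_{CD} = 150$ ms.

Two defaults deserve explicit justification:

* **Stimulus coupling.** We use $J_{\mathrm{ext}} = 0.0182$ nA, the product
  of the canonical external synaptic coupling $5.2\times10^{-4}$ nA·Hz$^{-1}$
  and an input rate of 35 Hz. A tenfold larger coupling is sometimes quoted
  for this model family, but with the transfer function above it drives both
  pools to $\sim$35 Hz instantaneously at stimulus onset and makes the
  symmetric high-activity state stable, so every threshold in the plausible
  range is crossed within a few milliseconds and decision times carry no
  information. At 0.0182 nA the network operates as a winner-take-all
  circuit with decision times of 200–350 ms, a spread of $\approx$ 75 ms and
  skewness $\approx$ 0.35 — the regime the behavioral literature describes.
* **Free-parameter defaults.** $z = 15$ Hz (the classic crossing threshold
  of this reduced model) and $\alpha_1 = 0.1$/deg, $\alpha_2 = 0$, chosen
  once so that the protocol orientations $0.2°$–$1.6°$ span accuracies of
  roughly 0.58–0.94 with chronometric differences of tens of milliseconds,
  matching the qualitative shape of human psychometric data on this task.
  These stand in for per-participant fitted values, which are what the
  calibration module estimates from data.

Integration advances the gating variables by Euler steps at `dt = 0.5` ms;
the noise current uses the exact Ornstein–Uhlenbeck transition by default,
so its stationary standard deviation is $\sigma_{\mathrm{noise}}/\sqrt{2}$
at every integration step — important because calibration simulates at a
coarser step than the generator, and the Euler-discretized noise (available
via `exact_ou = FALSE`, stationary sd
$\sigma_{\mathrm{noise}}/\sqrt{2 - dt/\tau_{\mathrm{noise}}}$) would
otherwise inject step-dependent noise levels and bias the fitted stimulus
strengths. The test suite verifies both formulas against simulation.
Gating variables are clamped to $[0,1]$
after each step because discretization can overshoot the interval that the
continuous dynamics preserves. Decisions default to a 1500 ms deadline
(`t_max`), after which a trial is a flagged timeout, excluded from summary
statistics; ties at threshold (a measure-zero event) go to the larger rate,
with an exact tie resolved by the trial's own random stream so replays are
deterministic.

## Protocol emulation

`protocol_spec()` encodes the three block types. Pure blocks draw from eight
orientations $\pm\{0.2, 0.5, 0.8, 1.6\}°$ with weights
$(0.05, 0.1, 0.15, 0.2, 0.2, 0.15, 0.1, 0.05)$; feedback and confidence
blocks use $\pm\{0.2, 0.8, 1.6\}°$ with weights
$(0.12, 0.18, 0.2, 0.2, 0.18, 0.12)$. Decision-to-next-onset gaps follow the
protocol timing: 500 ms in pure blocks (300 ms wait + 200 ms fixation),
700 ms in feedback blocks, and $700 + t_{\mathrm{report}}$ ms in confidence
blocks. The report duration is not part of the recorded protocol; we default
to 2000 ms, a typical slider-response latency. Sessions start from
$S = (0,0)$ settled under background input for 1000 ms; noise remains active
between trials (nothing in the dynamics switches it off). Since the model has
no reward pathway, feedback blocks are simulated identically to pure blocks.

`generate_cohort()` is the synthetic-data generator used throughout the
tests: participants draw $z \sim U(13.5, 16.5)$ Hz and
$\alpha_1 \sim U(0.08, 0.13)$ — the band of the winner-take-all regime in
which accuracies span roughly 0.55–0.95 over the protocol orientations, as
in the human data (thresholds much above $\approx 18$ Hz leave the
post-decision attractor able to outlast the corollary discharge, collapsing
accuracy to chance) — and non-decision times are ex-Gaussian with
$\mu \sim U(250, 350)$ ms, $\sigma_g \sim U(30, 50)$ ms,
$\tau_e \sim U(50, 100)$ ms (saccadic-to-motor latencies), and reported
confidence is the participant's own $\Delta r$ passed through a
histogram-matching map against a uniform 10-level target. What this generator
emulates is the *statistical structure* the analysis assumes — protocol
weights, state carry-over, RT = DT + NDT, confidence as discretized
$\Delta r$; what it does not emulate are lapses, drift in attention or
criterion, feedback-driven learning, or motor-process variability in the
confidence report, so green tests certify the pipeline's correctness on its
own assumptions, not those aspects of real data.

## Confidence mapping

Reported confidence (0–9) is modelled as a discretization of $\Delta r$.
`histogram_match()` places the nine cut-points at the order statistics of the
simulated $\Delta r$ sample at the cumulative proportions of the empirical
confidence histogram, so the mapped histogram reproduces the empirical one
exactly when the counts divide the sample size. A $\Delta r$ equal to a
cut-point maps to the upper level (right-continuous convention), empty
empirical levels give zero-width bins, and the map is built per participant
from confidence-block trials, pooling all simulated repetitions. The induced
map from $\Delta r$ to cumulative probability is summarized by a logistic
sigmoid $1/(1 + e^{-\beta(\Delta r - \kappa)})$ fitted by least squares to
the CDF points at the cut-points.

## Calibration

For each participant and block the observed quantities are the per-orientation
mean response times (centered by the grand mean over orientations, which
removes the orientation-independent mean non-decision time) and accuracies,
pooling $\pm\theta$. The displayed fitting cost is

$$\lambda\,\frac{1}{m}\sum_\theta \Delta RT(\theta)^2 +
  \frac{1}{n}\sum_\theta \Delta acc(\theta)^2, \qquad \lambda = 2,$$

with $m$ and $n$ the maxima over $\theta$ of the respective squared
differences, and a $0/0 \to 0$ convention. Used verbatim as an iterative
objective this expression is degenerate: both terms are renormalized by the
current maximum, so the cost is bounded by $(\lambda + 1)K$ for $K$
orientations regardless of how poor the fit is, and it rewards concentrating
the entire mismatch on a single orientation. `fit_participant()` therefore
freezes the normalizers at their first-iterate values — the frozen cost
coincides with the displayed one at the starting point and retains the
magnitude of the mismatch thereafter.

The optimizer couples a Metropolis chain with a derivative-free simplex
refinement (Nelder–Mead; for the one-parameter threshold fit, Brent's method
on the chain's support). The chain targets $e^{-\mathrm{cost}_{\mathrm{lik}}}$,
where $\mathrm{cost}_{\mathrm{lik}}$ is the same sum of squared differences
but each divided by twice its sampling variance (binomial for accuracy,
$\mathrm{sd}^2/n$ for mean RTs, data and simulation contributions added) —
i.e. a genuine Gaussian negative log-likelihood. The deterministic parts of
the fit — a coarse pre-scan over the threshold and a common strength scale
that chooses the chain's starting point, and the final simplex refinement —
evaluate the cost with a fixed simulator seed (common random numbers), so
the optimized surface is deterministic and the whole fit reproducible. The
chain itself refreshes the simulator seed at every iteration: with a frozen
noise realization the sampled posterior would ignore the Monte-Carlo shift
of the surface's minimum and undercover, whereas the refreshed-noise chain
(in the spirit of Monte-Carlo-within-Metropolis samplers) spreads over that
evaluation noise as well, which the coverage experiment below shows brings
the intervals close to nominal. Proposals are Gaussian at 5% of each
parameter range, adapted toward 30% acceptance during the burn-in third and
frozen afterwards; a quarter of the proposals jointly rescale
$(z, c_\theta)$ (with the appropriate Hastings correction) to traverse the
threshold–strength ridge of the cost surface.
Cost evaluations integrate at `dt = 1` ms (the generator uses 0.5 ms; the
induced shift in mean decision times is under 2%) with 1200 simulated trials
per evaluation by default. The spec of the 70% confidence intervals follows
from the chain being a posterior sample: central 70% quantile ranges of the
post-burn-in marginals, which for an exactly quadratic cost reproduce the
closed-form Gaussian interval.

Fitted per-orientation strengths are then regressed on
$\alpha_1\theta$ versus $\alpha_1\theta + \alpha_2\theta^2$ (no intercept)
and the form with lower $AIC = 2k + n\log(RSS/n)$ is kept. The shared
corollary-discharge parameters $(I_{CD,\max}, \tau_{CD})$ are fitted by grid
search with all participants refitted at each grid point, the default grid
centered on (0.033 nA, 150 ms). We fit per block and report both blocks'
strength laws rather than constraining them equal across blocks.

Identifiability caveat: with only centered mean RTs and accuracies, a higher
threshold can be traded against uniformly stronger stimulus strengths with
little change in either observable. At desk-scale budgets the point estimates
land within roughly 10% (threshold) and 20–30% (strengths) of generating
values on typical seeds; the interval-coverage experiment therefore fixes the
strength law and assesses the threshold's 70% interval, where the chain mixes
fully and empirical coverage is close to nominal.

## Non-decision time

Observed RT is modelled as decision time plus an independent ex-Gaussian
non-decision time. Because the calibrated network's decision times are
near-Gaussian (the test suite asserts $|$skewness$| < 0.5$ under the default
regime), the RT is itself ex-Gaussian and the deconvolution is closed-form in
moments: fit an ex-Gaussian to RT by maximum likelihood, then set
$\mu = \hat\mu - \overline{DT}$,
$\sigma_g = \sqrt{\max(\hat\sigma^2 - \mathrm{var}(DT), \epsilon)}$,
$\tau_e = \hat\tau$. The variance subtraction is floored (and flagged) when
the simulated decision-time variance exceeds the fitted RT variance, and fits
with $P(NDT < 0) \ge 0.01$ are flagged as unphysical. The full RT density is
reconstructed by numerical convolution of a Gaussian at the decision-time
sample moments with the fitted ex-Gaussian. On the question of what the
cohort-level "minimum non-decision time" should mean, we report both the 1st
percentile of each fitted distribution and the cohort minimum of the fitted
$\mu$; the two are computable from the fit report.

## Sequential analyses

`preprocess_trials()` produces the covariates of the mixed model
$\ln RT_n = a_{0,p} + a_{1,p}|\theta| + a_2 x_{\mathrm{rep}} +
a_{3,p}\ln RT_{n-1} + a_4\,\mathrm{Conf}_{n-1}$: per-participant z-scored
RTs, lagged log RT (broken at block boundaries), previous-trial confidence
dichotomized at the participant's median (at-median counts as low), and the
repetition indicator — by default, whether the current correct category
repeats the previous *response* (the previous correct category is available
via `repetition = "category"`). Trials after a missing confidence report drop
out of the regression through their missing lag. The model is fitted with
`lmerTest` using uncorrelated random slopes on the intercept, $|\theta|$ and
the lagged log RT; singular fits are refitted with progressively simpler
random structures and flagged. Model comparison against reductions uses
maximum-likelihood AIC/BIC on identical rows.

`post_confidence_contrasts()` bins trials by repetition and orientation
strength (default low $= \{0.2°, 0.8°\}$, high $= 1.6°$, configurable) and
runs Welch t-tests (hence fractional degrees of freedom) of post-low vs
post-high confidence z-scored RTs. `phase_plane_report()` gives the
mechanistic account: mean network states at stimulus onset per bin (oriented
as previous-winner/previous-loser), their distance to the basin boundary of
the between-trial flow (by bisection along the segment to the mirrored
state), and 200 ms thresholdless continuations of the noiseless flow. After
high-confidence decisions the state sits deeper in the previous winner's
basin, so repeated low-strength stimuli are answered faster; at high strength
the stimulus drive dominates and the difference dissolves.

## The race-model contrast

The extended independent race model accumulates two uncoupled diffusions
$dx_i = I_0(1 \pm c)\,dt + \sigma\,dW_i$ from 0 to a single positive
threshold $z$ per race (the standard race convention for the under-specified
two-sided variant), reads confidence from the balance of evidence
$|z - x_{\mathrm{losing}}|$, and relaxes both activities exponentially toward
baseline between trials with the diffusion noise active. Its drift and noise
defaults were grid-tuned so accuracy and mean decision time match the
attractor defaults within about 10% across the protocol strengths. The
relaxation constant defaults to 500 ms rather than mirroring
$\tau_{CD} = 150$ ms: with 150 ms the carryover at a 700 ms protocol gap is
under 1% of threshold and the race model trivially predicts *no* sequential
effect at any feasible sample size, whereas the model's characteristic
prediction — post-low-confidence speeding when the choice alternates,
nothing when it repeats — presupposes visibly incomplete relaxation. This is
the mirror image of the attractor network's pattern (post-high speeding on
repeats), and `compare_model_contrasts()` reproduces the opposite signs on
matched single-strength protocols; an optional linearly collapsing bound
leaves the ordering intact. In the attractor network the memory of the
previous trial is stabilized by the attractor structure itself, while a
leaky race forgets exponentially — which is why the two architectures are
distinguishable from sequential behavior alone.

## Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale, chosen as the
smallest sizes at which every assertion is statistically stable: 2000–4000
trials per condition for behavioral contrasts, 1200–2000 simulated trials
per calibration cost evaluation with 300-iteration chains, 25–50 repetitions
for coverage experiments, and 5000 samples for the deconvolution checks.
Bootstrap intervals use 500 resamples. All randomness flows from explicit
seeds; compiled simulators take an integer seed drawn from R's RNG so
`set.seed()` governs everything.

## Known limitations

* The network's residual asymmetry after a decision decays with a time
  constant of roughly one second, so at the full confidence-block gap
  (`report_ms = 2000`, i.e. ~2.7 s decision-to-onset) the carried-over state
  is nearly neutral and the pooled previous-confidence coefficient of the
  mixed model sits near zero on synthetic cohorts; the post-confidence
  speedup is demonstrated by the binned contrasts at the shorter matched
  gap, where it is concentrated in the repeated bin.
* The calibration ridge discussed above limits joint point recovery of
  threshold and strengths from means alone; richer summaries (RT variances,
  quantiles) would identify the scale but are outside the fitting contract.
* The model produces no correlation between successive response times
  (and the test suite checks independence at long gaps); the RT
  autocorrelation seen in human data is deliberately not modelled.
* Feedback effects on behavior are not modelled; feedback blocks differ from
  pure blocks only by their inter-trial timing.
* The collapsing-bound race variant is a simple linear stand-in, not a
  calibrated reconstruction of any published variant.
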