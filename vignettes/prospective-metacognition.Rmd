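---
title: "Simulating and analyzing prospective metacognitive judgments"
author: "prospectmeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analyzing prospective metacognitive judgments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prospectmeta)
```

## The task and what the package computes

`prospectmeta` is a generative simulator plus analysis pipeline for a
two-stage perceptual decision task built around *prospective metacognition*:
judging, before attempting a perceptual decision, how likely one is to get
it right.

On every trial two random-dot-kinematogram (RDK) options are offered
simultaneously:

* the **internal probability option**: a full field of dots whose motion
  coherence `c` is drawn from {0, 0.03, 0.06, 0.12, 0.25, 0.37, 0.50,
  0.75}. A correct left/right motion discrimination is *always* rewarded,
  so the probability of reward is the decision maker's own probability of
  being correct — something they must estimate prospectively;
* the **external probability option**: fully coherent motion (trivially
  discriminable), rewarded with a displayed probability `p` from {0.1, 0.3,
  0.5, 0.6, 0.7, 0.8, 0.9, 1.0}.

The observer first chooses which task to attempt (the metacognitive
judgment), then performs the chosen discrimination on the same stimulus
rotated by 90 degrees, and finally receives a probabilistic reward. A
session crosses all 8 x 8 offer combinations in balanced, shuffled
repetitions over 195 trials. A *follow-up* session contains only internal
perceptual trials and yields, per coherence, the empirical accuracy used as
that participant's internal-probability baseline (`followup_table()`).

Every analysis the package implements operates on plain tab-separated trial
logs (`read_session_log()` / `write_session_log()`), so real data in the
documented column layout can be analyzed with the same code paths as
simulated data.

## The simulated observer

`agent_params()` defines a signed-evidence observer. With drift
$\mu(c) = (c/\alpha)^{s}$, the trial's evidence is

$$z = \mu(c) + \varepsilon_{\text{share}} + \varepsilon_{\text{resp}},
\qquad \varepsilon_{\text{share}} \sim N(0, \sigma_e/\alpha),\quad
\varepsilon_{\text{resp}} \sim N(0, \textstyle\sqrt{1 - (\sigma_e/\alpha)^2}),$$

and the perceptual response is the sign of $z$ (with lapse rate
$\lambda$). Accuracy at coherence $c$ is therefore exactly

$$\Pr(\text{correct} \mid c) = \tfrac{\lambda}{2} +
(1-\lambda)\,\Phi\!\big((c/\alpha)^{s}\big),$$

which is chance-anchored at $c = 0$ and saturates near 1 at the highest
coherence. A cumulative-Gaussian (probit) accuracy curve was chosen over a
Weibull form because only an explicit evidence variable lets the same trial
evidence drive both stages — the point of the whole design. The *shared*
component $\varepsilon_{\text{share}}$ is a property of the stimulus
instance (e.g. the particular dot draw) and survives from the metacognitive
stage into the perceptual stage; the response component is fresh noise.

At the metacognitive stage the observer reads out
$\hat z = \mu(c) + \varepsilon_{\text{share}} + \xi$ with readout noise
$\xi \sim N(0, \sigma_m/\alpha)$, forecasts its accuracy
$\hat p = \lambda/2 + (1-\lambda)\Phi(\hat z)$, distorts both probabilities
through the prospect-theory weighting function

$$w_\gamma(p) = \frac{p^{\gamma}}{\big(p^{\gamma}+(1-p)^{\gamma}\big)^{1/\gamma}},$$

and chooses the internal option with probability
$\mathrm{logit}^{-1}\!\big(\beta\,[w_{\gamma_{int}}(\hat p) -
w_{\gamma_{ext}}(p)]\big)$. When the external option is chosen, the
discrimination succeeds with probability 0.979 (the near-ceiling rate for
fully coherent stimuli) and reward then falls with probability `p`.

Because the shared evidence links the two stages, the observer accepts
internal options selectively on trials it can actually win. This single
channel produces, downstream, (i) above-chance type II sensitivity, (ii)
the positive external-probability coefficient in the internal-performance
regression, and (iii) the challenge-trial benefit — without any of those
statistics being targeted directly.

### Default parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.22 | psychometric width (coherence units) |
| `slope` | 1.6 | psychometric exponent |
| `lapse` | 0.02 | lapse rate |
| `evidence_sd` | 0.176 | sd of the shared (stimulus-instance) evidence |
| `meta_noise` | 0.12 | sd of the extra metacognitive readout noise |
| `choice_beta` | 8 | inverse temperature of the metacognitive choice |
| `gamma_internal`, `gamma_external` | 0.8 | probability-weighting exponents |
| `external_accuracy` | 0.979 | perceptual ceiling on external trials |

The width and exponent place the follow-up accuracies at the two moderate
coherences near 0.55 (c = 0.06) and 0.65 (c = 0.12) — midway between
adjacent external-probability grid values. This matters: if a true accuracy
sits almost exactly on a grid probability, whole offer cells flip between
the challenge and inevitable classes on follow-up sampling noise and the
near-tie cell (which carries strong selection) dominates the contrast, a
degeneracy of the synthetic design rather than of the method. The remaining
defaults were set so that reward rates for the two options land, roughly
matched, in the seventies of percent and the type II ROC area in the low
0.7s, the regime the task was designed to probe. The simulated type I area
(about 0.92–0.96) runs above what human cohorts show (~0.84), because the
simulated observer has no attentional drift beyond its 2% lapse rate; none
of the package's checks depend on matching that value.

The "stimulation" manipulation (`tms_condition = "alpfc"`) multiplies
`meta_noise` by a factor (default 3), degrading the metacognitive readout
while leaving stimulus processing untouched; `"vertex"` is a genuine no-op
that consumes the random stream identically, so at equal seeds it is
byte-identical to no stimulation. Every trial draws the same set of random
variates in a fixed order whichever option is chosen, which makes paired
condition comparisons exact.

## Signal-detection statistics

`classify_optimality()` labels each trial at the four intermediate
coherences (0.03–0.25) internal- or external-optimal by comparing the
follow-up accuracy (times the internal option's certain reward
contingency) with the external probability. Ties favor internal — the
internal option's contingency is certain, so tie trials carry no regret —
and the rule is configurable. The extreme coherences are excluded because
the optimal action there is unambiguous for every observer.

`type_two_aroc()` plots, per eligible coherence, the hit rate (internal
chosen when internal-optimal) against the false-alarm rate (internal chosen
when external-optimal), augments the points with the (0,0) and (1,1)
anchors, and integrates by trapezoids. Anchors and trapezoids are the
conventional completion of a finite ROC point set; both are options.
`type_one_aroc()` scores left/right discrimination on chosen-internal
trials through $A = \Phi\big((z(\text{hit}) - z(\text{FA}))/\sqrt 2\big)$,
with the log-linear edge correction $(k + 0.5)/(n + 1)$ applied so empty
cells stay finite, and coherence-0 trials excluded by default (no
objectively correct direction exists there; the simulator still defines one
so that scoring is total when the exclusion is turned off).

`m_ratio()` converts both areas through the equal-variance identity
$d' = \sqrt 2\, z(A)$ and reports meta-d'/d' $= z(A_{II})/z(A_I)$. The
$\sqrt 2$ placement is fixed by the sanity anchor $m(A, A) = 1$, which the
tests assert across the whole range of areas.

## Choice models

`build_lagged_design()` constructs, per trial, the linearized internal
probability (`coherence_transform()`: rank index of the roughly geometric
coherence ladder rescaled to [0, 1]; a log transform is the documented
alternative — the two differ only in spacing, and all predictors are
z-scored within session anyway), the external probability, and for each of
the past three *encounters* of each task type its outcome, its offered
probability, and their product. Encounters — not raw trial offsets — define
the lags: the k-th previous internal encounter is the k-th most recent
trial on which the internal option was actually performed. Histories never
cross session boundaries. Rows with incomplete histories are dropped and
counted rather than zero-imputed, since an imputed zero after z-scoring
would silently mean "average history". Z-scoring happens after row
selection, within session.

`fit_logistic()` is a self-contained IRLS maximum-likelihood fitter with a
monotone log-likelihood (step-halving), convergence at coefficient changes
below 1e-8, and an explicit perfect-separation error naming the culprit
columns (diverging linear predictor together with error-free in-sample
classification). The test suite checks it against `glm()` to 1e-6.
`fit_lagged_model()` fits per session and averages coefficients (the
per-participant pattern of the field), dropping — with a warning — the
occasional session where 20 predictors on ~170 rows achieve in-sample
separation; a pooled fit is available and is what the parameter-recovery
study uses, since the generating model there has a single common
coefficient vector and per-session maximum likelihood at that size is
biased away from zero. `fit_dv_model()` is the one-predictor variant on the
decision variable (follow-up-based internal reward probability minus
external probability).

## Probability weighting and its identifiability

`empirical_choice_curve()` bins trials by option level and pairs the
proportion of trials on which the option *should* have been chosen by an
optimal observer (x) with the proportion on which it *was* chosen (y);
`fit_gamma()` fits $w_\gamma$ by least squares with a log-spaced grid scan
before golden-section refinement, because the SSE profile in $\gamma$ is
not unimodal (an S-shaped point set has competing minima on both sides of
1).

One property of this construction deserves emphasis. If a simulated
observer distorts *both* options' probabilities through the same
$w_\gamma$ and chooses by comparing them, the distortion cancels: a strictly
monotone transform applied to both sides of a comparison leaves the
comparison unchanged, so in the sharp-choice limit the generating
$\gamma$ has *no* effect on behavior, and at realistic noise levels its
effect is swamped by the flattening that choice stochasticity itself
produces (which reads out as an inverse-S with $\hat\gamma \approx$
0.6–0.8 regardless of the generating value — of some interest in itself,
since empirical curves of this kind are produced by exactly such
stochastic choosers). One-sided distortion does not help: it shifts the
curve bodily, which the one-parameter family absorbs as an extreme
exponent. The parameter-recovery study in `recover()` therefore validates
the *estimator*: per-level choice proportions are drawn binomially from
$w_\gamma(p)$ at the task's own optimal-proportion levels and trial counts
(20 sessions' worth) and refitted, recovering $\gamma \in \{0.4, 0.7, 1.0,
1.5\}$ to within a few hundredths. The full agent-loop sweep is reported
alongside (`gamma_agent`) for transparency about the identifiability limit.

`risk_metrics()` summarizes each option's reward stream by its mean and
the implied Bernoulli variance $r(1-r)$.

## Challenge and inevitable trials

`classify_challenge()` labels a trial *challenge* when the external offer
exceeded the expected internal reward (per-participant follow-up baseline,
matching the optimality construction) and *inevitable* when it fell short;
exact ties are excluded. `challenge_contrast()` compares perceptual
accuracy between the classes among chosen-internal trials at the moderate
coherences {0.06, 0.12}, *stratified by coherence* (per-level accuracies,
equal-weight average of per-level differences): the two classes have
different coherence compositions — challenge trials skew toward the harder
coherence — so a pooled difference would be confounded. A positive
difference means the observer performs better precisely when it rejected
the on-average better offer: trial-level prospective metacognition.
`tms_contrast()` assembles the dissociation report (type II drop, type I
spared, challenge benefit reduced). At the default noise multiplier of 3
the benefit shrinks by roughly half rather than collapsing to zero; full
abolition would require the perturbation to dominate the shared-evidence
channel entirely.

## ROI beta-timecourse slope

`simulate_roi_timecourse()` builds a synthetic region-of-interest signal:
per trial, a gamma-variate impulse response with unit peak, scaled by the
trial's parametric regressor value (chosen- or unchosen-internal
probability, mutually exclusive per trial), plus Gaussian noise, sampled at
a 1.23 s repetition interval. The two conditions differ in time-to-peak
(defaults 4 s vs 7 s) but share the peak amplitude — accumulation speed
differs, peak signal does not. This is a synthetic stand-in for a
preprocessed BOLD timecourse; no hemodynamic pipeline is modeled, only the
downstream statistics.

`beta_timecourse()` normalizes the signal, oversamples it 20-fold by
linear interpolation (the factor is conventional; the interpolant is the
package's choice), epochs 0–11 s after each onset, and regresses the
across-trial signal values at every post-onset time on the z-scored
regressor (ordinary least squares with intercept — an intercept is
included since the regressor is centered, not exhaustive). `slope_stat()`
then takes the minimum beta strictly inside 0–4 s (within which the next
trial phase cannot yet have started), the maximum strictly after it and
before 11 s, ties to the earliest time, and reports
$(\beta_{max}-\beta_{min})/(t_{max}-t_{min})$ and the magnitude
$\beta_{max}-\beta_{min}$. `chosen_unchosen_slope_contrast()` averages
per-session slopes and peaks within condition before contrasting, as
session statistics are averaged within a participant.

The generator's default signal-to-noise (noise sd 0.15 against unit peak
responses, ~195 events per session) was set so that the ramp-rate ordering
is recovered in at least 95% of single sessions; at substantially lower
SNR the extremum-based statistic is dominated by the noise excursions of
the epoched regression and the contrast washes out. The event schedule
spaces onsets by one nominal trial length plus a Poisson-distributed
(mean 3 s) jitter clipped to 2.5–8.5 s.

## Numerical and design notes

* Trial logs are UTF-8 TSV, booleans as 0/1, probabilities with at most six
  significant digits, `\n` endings — byte-stable for identical input.
* Sessions of any length are scheduled as whole-grid repetitions plus a
  random remainder subset; sessions shorter than one grid warn.
* `fit_gamma()` searches $\gamma \in [0.05, 20]$, tolerance 1e-6,
  unweighted SSE by default with bin-count weights as an option.
* All simulators draw every random variate for every trial in a fixed
  order, so conditions differing only in a parameter multiplier are exactly
  paired at equal seeds.
* Degenerate inputs fail loudly: one-class ROC sets, single-direction
  type I inputs, chance-level type I in the M-ratio, constant design
  columns, constant ROI regressors, empty challenge classes.

## What the synthetic data do and do not show

The generator reproduces the statistical structure the analyses assume:
a chance-anchored psychometric curve, matched reward rates, trial-level
coupling between metacognitive choice and perceptual outcome, inverse-S
empirical weighting curves, a selective metacognitive impairment under
readout-noise perturbation, and ramp-speed differences with matched peaks.
Passing tests therefore show that the *computations* are correct and that
the *directions* of the headline effects follow from the assumed
mechanisms. They do not show that human observers share those mechanisms:
the shared-evidence channel is one concrete choice among several that
produce trial-level metacognitive sensitivity; sequential dependencies
(learning, fatigue) are absent, so lag coefficients in simulated data are
near zero; and the cohort-level inferential statistics of a real study
(group t-tests across participants) are out of scope. The simulated type I
area and internal reward rate run somewhat above human values, as noted
above.
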