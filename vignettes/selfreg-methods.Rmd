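---
title: "Models and methods behind selfreg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind selfreg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

selfreg models the behavioural side of a paired self-regulation
experiment. Participants complete two tasks in one session: an emotion
task in which they view or cognitively reappraise affective pictures and
rate their feeling on the 9-point SAM valence scale, and a food-choice
task in which they accept or refuse to eat single food items — rated
beforehand for taste and healthiness — under a 3-second response deadline,
with one choice implemented for real. The scientific question the package
supports is whether regulation ability transfers across domains: does a
person who is good at blunting their emotional reactions also choose
healthier foods when taste and health conflict?

This vignette explains the models the package implements, the parameters
that matter, what the synthetic-data generator does and does not emulate,
and the numerical and design choices a maintainer would want recorded.

## Trial design: the neutral zone and challenge types

Foods are rated on a visual-analogue scale from $-5$ to $+5$ on each of
taste and healthiness. The middle of the scale carries a *neutral* band
spanning 5% of the total 10-unit length on each side of zero, so a rating
$r$ is neutral when $|r| \le 0.5$. We treat the band as closed (boundary
values are neutral): the rule exists to exclude ambiguous items from
choice sets, and the closed version is the conservative reading.

Items non-neutral on both attributes fall into four quadrants. The two
*challenge* types are those where the attributes conflict: high-taste /
low-health (HTLH, tempting junk) and low-taste / high-health (LTHH,
unappealing health food). The aligned quadrants (HTHH, LTLH) pose no
self-control problem. Each participant's 100-trial choice set is built
from their own ratings with a target of 75 challenges; the HTLH:LTHH mix
is proportional to availability in the profile rather than fixed, because
empirically participants supply far more tasty-unhealthy than
unpalatable-healthy items (the package default rating model reproduces
this skew). Profiles that cannot supply `min_challenge` (default 50)
challenge items error out of design, mirroring the participant exclusion
applied in practice; the default is a stipulation — the experiment's own
cutoff is not published — chosen to keep the challenge majority while
tolerating sparse profiles, and it is configurable.

## Trial and participant scores

**Taste/health weights.** Per participant, a maximum-likelihood logistic
regression of the yes/eat indicator on mean-centered taste and health
ratings, $\mathrm{logit}\,P(\text{yes}) = \beta_0 + \beta_1
\mathrm{tr}_c + \beta_2 \mathrm{hr}_c$, fitted by IRLS (`stats::glm`).
Centering is within participant over the presented foods: the fit is per
participant, and this keeps the intercept interpretable. (A group-level
variant of the same model standardizes ratings across participants; the
two conventions differ and we document ours rather than silently mix
them.) Quasi-complete separation — for instance a participant who never
chooses to eat — is detected through runaway coefficients or exploded
standard errors and handled by refitting with a small quadratic penalty
(ridge 0.05) plus a `separation_flag` that downstream stages treat as an
exclusion.

**Subjective food value.** $sv = \beta_1 \mathrm{tr}_c + \beta_2
\mathrm{hr}_c$ — the weighted evidence for eating, excluding the
intercept, in log-odds units.

**Decision conflict.** $-|sv|$: maximal (zero) when the weighted evidence
balances exactly, increasingly negative on one-sided trials.

**Self-control stakes.** $|\mathrm{tr}| + |\mathrm{hr}|$ on challenge
trials and **zero by definition** on aligned trials, where no
self-control is required. Stakes use raw, uncentered ratings: they
measure distance from the scale's neutral point, not from the
participant's mean.

**Orthogonalized stakes.** For modulator-style analyses both stakes and
conflict are mean-centered over the responded challenge trials, and
stakes are residualized on conflict by least squares, leaving only the
variance unique to the self-control need. The residual is invariant to
adding any affine function of conflict to the raw stakes vector, which
the test suite checks directly against a normal-equations oracle.
Behavioural regressions use raw stakes; only the modulator path uses the
orthogonalized version.

**Self-control success.** A responded challenge trial is a success when
the healthier option was taken: refusing HTLH or accepting LTHH. Missed
trials are excluded from numerator and denominator — the success
definition refers to choices made, and what happens on a missed trial is
task logistics, not a decision. The participant's success level is the
proportion of responded challenge trials resolved for health, reported
overall and per challenge type.

**Reappraisal success.** Each reappraised picture is rated twice: once
in-scan while regulating, once post-scan while simply viewing. The
per-stimulus success score is the rating difference signed so that larger
means more successful regulation (reappraise $-$ view for negative
stimuli, view $-$ reappraise for positive), averaged within valence and
then across the two valences. We difference per stimulus rather than
subtracting condition means: both coincide with complete data, but the
per-stimulus form degrades gracefully when post-scan ratings are missing.
The per-trial success/failure classification used for event sorting
requires a strict move toward neutral; ties count as failures, a
stipulation we flag because a tie is not evidence of regulation.

## The drift-diffusion choice model

Choices and response times are modelled as a Wiener diffusion with unit
diffusion coefficient between two absorbing boundaries: the upper at
separation $a$ means "yes/eat", the lower at 0 means "no/refuse". The
process starts at $z_{\mathrm{rel}} \cdot a$ and drifts at
$v = \delta \cdot sv$ with a single drift-scaling parameter $\delta$, so
tasty-and-healthy items drift up and aversive items drift down. A
starting point $z_{\mathrm{rel}} < 1/2$ expresses a prior bias toward
refusal; the package default is $z_{\mathrm{rel}} = 1/3$, the bias these
tasks elicit when three quarters of the trials are challenges. Responses
landing after the 3-s deadline are *missed*.

Drift is taken proportional to the combined subjective value rather than
carrying separate taste and health drift weights; the separate-weights
variant is expressible by adjusting the inputs but is deliberately not a
fitted option, keeping the parameter count at four.

The first-passage-time density is evaluated by the two classical series
expansions — the small-time sum over reflected Gaussian images and the
large-time Fourier sine series — switching per time point to whichever
needs fewer terms for truncation error below $10^{-7}$. The zero-drift
absorption probability at the upper boundary equals $z_{\mathrm{rel}}$
exactly, and the general closed form is implemented with care at
$v \to 0$ and at large $|v|$ (log-space rescaling) so it is continuous
and overflow-free; both facts are tested against quadrature of the
density.

Estimation maximizes the censored likelihood: responded trials contribute
the density at their boundary, missed trials the survival mass beyond the
deadline (computed by 48-node Gauss-Legendre quadrature of the two
densities). Optimization is bounded L-BFGS-B over
$(a, z_{\mathrm{rel}}, t_0, \delta)$ from three deterministic starting
points, with $t_0$ bounded above by the fastest observed response. Fits
with fewer than 40 responded trials, or with all responses at one
boundary (which pins the starting point), are flagged unconverged.

Simulation uses Euler-Maruyama with a 1-ms default step (0.1 ms in the
oracle tests); the simulator is compiled (Rcpp) and draws from R's RNG so
`set.seed()` governs reproducibility end to end.

## The synthetic cohort generator

The generator is the package's test bed: every downstream stage must be
exercisable with known ground truth and no downloads. Its defaults are
the study conditions, not tuning knobs:

* **Cohort**: 38 participants, 180 foods rated each, 100 choice trials
  with a 75-challenge target.
* **Ratings**: a quadrant-mixture sampler with masses
  (HTLH 0.42, LTHH 0.13, HTHH 0.30, LTLH 0.15), values uniform within the
  non-neutral part of each quadrant, and a 5% neutral-band fraction. The
  masses reproduce the empirical skew — a median of roughly 52 HTLH but
  only ~15 LTHH challenges per hundred choices — without claiming the
  true food-rating distribution, which is not published; this is a
  stipulated default, recorded as such.
* **Choice behaviour**: population means for the attribute weights of
  1.47 (taste) and 1.46 (health) — the group-level coefficients these
  tasks produce — with SD 0.45, and diffusion defaults
  $a = 1.5$, $z_{\mathrm{rel}} = 1/3$, $t_0 = 0.3$ s, $\delta = 0.8$.
* **Emotion task**: 5 block types of 20 trials. In-scan ratings are
  discretized truncated Gaussians (SD 1.2 on the latent scale, a value
  chosen to give within-condition spreads resembling ordinal SAM data)
  around view means of 2.69 / 5.26 / 7.09 for negative / neutral /
  positive blocks. Reappraise blocks shift the view mean toward the
  midpoint 5 by the participant's efficacy, `delta_neg` (population mean
  1.56) or `delta_pos` (mean 1.88) — the shifts implied by the condition
  means such tasks report. Post-scan re-ratings of reappraised stimuli
  are drawn from the *unregulated* view distribution, treating post-scan
  viewing as the unregulated baseline.
* **Coupling**: `coupling_rho` induces a latent correlation between mean
  regulation efficacy $(\delta_{neg}+\delta_{pos})/2$ and the health
  weight through a shared Gaussian factor; the construction is exact
  before the (rare, $\approx 2.6$ SD) truncation of the efficacies at
  zero. The default is 0: no cross-task association, matching the null
  association the behavioural literature reports.
* **Covariates**: hunger, BMI, restraint and gender are generated but
  carry no effect (coefficients zero) in the generative model — they
  exist so covariate-style group fits are exercisable and should come out
  null.
* **Reproducibility**: one RNG stream per participant derived from
  (cohort seed, participant index), so cohorts are bit-identical under
  regeneration and participants independent of each other.

What the generator does *not* emulate: real food-rating distributions
(ratings are uniform within quadrant), sequential effects and fatigue,
the logit-vs-diffusion scale correspondence of the weights (see below),
arousal, stimulus-specific emotion content, or any neural data. Passing
tests on synthetic cohorts therefore demonstrate that the pipeline's
estimators recover the parameters of *this* generative family — not that
the substantive findings would replicate in new human data.

One scale subtlety deserves emphasis: choices are generated by the
diffusion, but the weight-fitting stage is logistic. At
$z_{\mathrm{rel}} = 1/2$ the diffusion's choice rule is exactly logistic
with slope $a\delta$ per unit $sv$; away from $1/2$ it is only
approximately so. Recovered logistic weights are therefore proportional
to, not equal to, the generating diffusion-scale weights. The
parameter-recovery report consequently scores the *ratio*
$w_{taste}/w_{health}$, which is scale-free, rather than the raw weights.

## Group-level inference

The trial-level regressions (rating-by-condition, choice, challenge
success, log-RT) are approximated by the two-stage summary-statistics
approach: stage 1 fits each participant separately (logistic for binary
responses, linear for ratings and log RT), stage 2 averages coefficients
across participants with a $t$-based 95% interval. Full hierarchical
MCMC estimation is a non-goal: the two-stage approximation is testable at
desk scale, consistent for the group means as participants and trials
grow (which the suite checks under a null generator), and transparent
about its degenerate cases (identical participants are flagged).
Between-subject covariates cannot be stage-1 regressors; where needed
they enter stage 2 as regressions of stage-1 coefficients.

Correlations between per-participant scores use Spearman (rank) or
Pearson (linear) point estimates with a BCa bootstrap 95% interval and
`pp_positive`, the bootstrap fraction of positive correlations — a
deliberate substitution for MCMC-based Bayesian correlation intervals,
with the same point estimate and comparable interval semantics but no
sampler dependency. Exact interval endpoints will differ from any
specific prior choice; only point-estimate agreement should be expected
when comparing against externally computed Bayesian intervals.
Cross-task association joins the two tasks' score tables on participant
id with exclusions applied per task, so a participant can contribute to
one task only.

## Numerical choices and problem sizes

* Series truncation for the Wiener density: error bound $10^{-7}$,
  per-element small/large-time switching.
* Survival (censoring) mass: 48-node Gauss-Legendre quadrature on the
  deadline interval.
* Separation detection: $|\hat\beta| > 12$ or coefficient SE $> 25$ or a
  non-converged IRLS; ridge penalty 0.05 on the fallback.
* DDM optimization bounds: $a \in [0.3, 5]$,
  $z_{\mathrm{rel}} \in [0.03, 0.97]$, $t_0 \in [0, \min \mathrm{RT})$,
  $\delta \in [-6, 6]$; three fixed starting points; 500 iterations.
* Tie-breaks: rating-scale neutral band closed; reappraisal ties are
  failures.
* The test suite's simulation sizes are chosen to make Monte-Carlo error
  small relative to each tolerance while keeping the default run
  desk-sized: $10^5$ Euler-Maruyama paths at 0.1-ms steps for the
  density-vs-histogram oracle, 38 participants × 1000 trials for
  starting-point recovery, 500 null cohorts (with 40-trial choice sets,
  which only widens score noise and does not bias coverage) for the
  bootstrap-coverage check, and 2000 profiles for coupling recovery.

## Known limitations

* No inter-trial variability parameters (drift, starting point or
  non-decision-time variability) in the diffusion model; the basic
  four-parameter model is the deliberate scope.
* The logistic weight stage recovers diffusion-generated weights only up
  to scale (see above); analyses should use the ratio or within-scale
  comparisons.
* BCa intervals are approximate at $n \approx 38$; coverage is verified
  by simulation to be near-nominal, not exact.
* The generator's rating and emotion-noise distributions are stipulated
  families, adequate for estimator validation but not fitted to any
  empirical rating corpus.
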