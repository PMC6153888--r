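---
title: "Modelling anisotropy of traveled-distance estimation: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling anisotropy of traveled-distance estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathaniso)
```

## The scientific question

When people estimate how far they have been passively translated — a
distance-reproduction task driven by inertial (vestibular and somatosensory)
cues — is the accuracy of that estimate the same in every direction of the
sagittal plane? `pathaniso` implements the full analysis chain for this
question: the motion stimuli, a generative model of the cohort, the
exclusion rules, five competing error models compared by small-sample
corrected AIC, a reference-frame test that dissociates body- from
earth-centered coding, and an audit of whether simulator noise could
masquerade as an anisotropy.

The experimental design the package assumes is a within-subject factorial:
12 translation directions on a 30° grid in the sagittal plane (0° =
forward, 90° = up), 6 target distances from 0.5 to 1.5 m, and two trunk
orientations (upright, and pitched 30° backward so that body- and
earth-centered directions dissociate), 144 test trials per participant.
Responses are reproduced distances: the participant presses a button during
a standardized test translation when they feel they have covered the target
distance again.

## Motion profiles

The target translation uses a raised-cosine velocity profile over a fixed
3 s, $v(t) = \tfrac{D}{T}\left(1 - \cos\tfrac{2\pi t}{T}\right)$, whose
acceleration is a full sinusoid with peak $2\pi D/T^2$ (0.35 m/s² at 0.5 m
up to 1.05 m/s² at 1.5 m). The test translation is identical in every
trial: a half-sinusoid acceleration phase with peak $A$ and duration $t_1$,
followed by a constant deceleration $d$ until rest at time $T$ and distance
$S$. Rest-to-rest closure ties the parameters together,

$$ v_1 = \frac{2At_1}{\pi} = d\,(T - t_1), \qquad
   S = \frac{A t_1^2}{\pi} + \frac{v_1 (T - t_1)}{2}. $$

Substituting the first relation into the second collapses the distance
constraint to $S = A t_1 T/\pi$, so `solve_test_profile()` is closed-form:
$t_1 = \pi S/(AT)$ given the distance, or $t_1 = dT/(2A/\pi + d)$ given the
deceleration. With $A = 1.55$ m/s², $T = 5$ s and $S = 2.5$ m this yields
$d \approx 0.251$ m/s² — the configuration all analyses use. Profiles are
sampled at 1000 Hz by default (configurable down to 50 Hz); velocity and
position are exact piecewise integrals, and a trapezoid-rule consistency
check in the test suite verifies the $1/\text{rate}^2$ convergence of
numerical re-integration. Comparisons against values printed to two
decimals use round-half-up (`round_half_up()`).

Direction never enters the kinematics: the same unsigned profile is used
for every direction, which only labels the unit vector of motion.

## The generative cohort model

No raw participant data accompany this design, so `simulate_cohort()`
generates cohorts with the statistical structure that the analysis assumes,
and the package's validation rests on recovery of known generative truth.

* **Error curve.** The expected absolute error for a trial at direction
  $\alpha$ follows one of the five model curves below (default: the
  horizontal–vertical model with $w_h = 0.36$, $w_v = 0.40$ m, the
  reference point estimates for this task, used as generative truth).
* **Error distribution.** Signed error is zero-mean Gaussian with
  $\sigma(\alpha) = \mu(\alpha)\sqrt{\pi/2}$, so that
  $E|\text{error}| = \mu(\alpha)$ by the folded-normal identity
  $E|N(0,\sigma^2)| = \sigma\sqrt{2/\pi}$. Only absolute error is analysed
  downstream, and no bias term is identifiable from it, so the generator
  deliberately has none. The Gaussian shape itself is an assumption: the
  design's source data do not constrain it.
* **Participant heterogeneity.** One multiplicative log-normal random
  effect per participant scales all weights,
  $w^{(i)} = w \cdot e^{\sigma_P z_i}$. The default $\sigma_P = 0.2$
  (≈20% between-participant spread) is a one-time choice of realistic
  psychophysical heterogeneity; a single shared scaling (rather than
  per-weight effects) keeps the model identifiable at ~20 participants ×
  72 trials.
* **Body-fixed anisotropy.** In the pitched orientation the curve is
  evaluated at the body-centered angle (earth direction − 30°): the
  generative anisotropy rotates with the trunk, matching the reference
  frame the downstream test is designed to detect.
* **Duration-strategy responders.** A configurable fraction of
  participants (default 4/24) press at a characteristic time (uniform on
  2–4 s per participant, Gaussian per-trial jitter of 0.15 s) converted to
  distance through the test profile's position curve — reproducing the
  real failure mode of reproducing elapsed time instead of distance, which
  the participant screen must catch.
* **Response support.** Reproduced distances are clipped to the test
  profile's physical range [0, 2.5] m. This truncation matters; see
  *Known limitations*.
* **Block structure.** 12 blocks × 12 trials (each block covers every
  direction once; distances shuffled across blocks; orientations in
  contiguous halves) is reproduced for realism but carries no generative
  effect.

Everything is deterministic given the config seed.

What the generator does *not* emulate: vestibular transduction (otolith
dynamics, detection deadbands), bias in signed error, learning or fatigue
across blocks, and any direction-dependence of response variability beyond
the proportionality $\sigma \propto \mu$. Passing recovery tests therefore
demonstrate that the pipeline's inferences are sound *when the data follow
this structure*, not that real cohorts do.

## Exclusion rules

`screen_participants()` excludes a participant when the Pearson correlation
between target and reproduced distances is not significantly positive
(two-sided $p \ge .05$ with $n-2$ df, or $r \le 0$, or undefined because
responses are constant). Requiring $r > 0$ as well as significance is a
documented choice: a significantly *negative* correlation also means the
task was not solved as intended. `remove_outlier_trials()` then drops
trials whose absolute error lies more than 2 SD from the participant's
overall mean — pooled over both orientations, applied once, never
iterated. The order (participants first, then trials) is part of the
contract; reversing it changes the result. For Gaussian signed errors the
rule removes the folded-normal mass beyond $\mu + 2\mathrm{SD} \approx
2.0\sigma$, about 4.5% of trials, consistent with the ~4% reported for this
design in practice.

## The five error models and their fitting

With $\alpha$ the direction (continuous, entering through $\cos\alpha$ and
$\sin\alpha$) and indicators written $[\cdot]$:

* isotropy: $\mu = c$;
* horizontal–vertical: $\mu = \sqrt{(w_h\cos\alpha)^2 + (w_v\sin\alpha)^2}$;
* upward–downward: vertical term split into $[\sin\alpha>0]\,w_u$ and
  $[\sin\alpha<0]\,w_d$;
* forward–backward: horizontal term split into $[\cos\alpha>0]\,w_f$ and
  $[\cos\alpha<0]\,w_b$;
* forward–backward–upward–downward: both splits, four weights.

The quadratic combination normalizes the components: equal weights predict
the same error in every direction, and each refined model collapses to the
horizontal–vertical curve when its split weights agree (asserted as a
property test on random draws). The indicator switches coincide with
vanishing sine/cosine factors, so every curve is continuous.

`fit_anisotropy()` maximizes the marginal likelihood of

$$ y_{ij} = e^{\sigma_b z_i}\,\mu(\alpha_{ij}; w) + \varepsilon_{ij},
   \qquad z_i \sim N(0,1),\ \varepsilon_{ij} \sim N(0, \sigma^2), $$

integrating the participant effect with Gauss–Hermite quadrature (15 nodes
for single fits; replicate studies use 9, ample for a one-dimensional
smooth integrand). The isotropy null is the classical linear
random-intercept model $y_{ij} = \beta_0 + b_i + \varepsilon_{ij}$ and uses
its exact closed-form Gaussian marginal likelihood — an intentional
asymmetry mirroring how the null is conventionally specified for this
analysis. All fits are maximum likelihood (never REML), so AICc values are
comparable across fixed-effect structures.

Numerical choices: weights and variance components are kept positive by a
log reparameterization; optimization runs ≥5 deterministically jittered
`nlminb` starts (relative tolerance 1e-12) with ties broken by best
likelihood; convergence is declared from the Dennis–Schnabel scaled
gradient at the selected solution (threshold 1e-4 — finite-difference
gradients on a log-likelihood of magnitude ~10³ cannot certify much
tighter), because quasi-Newton termination messages such as "singular
convergence" on the flat ridge of an over-parameterized variant do not
distinguish failure from a legitimate stationary point. A constant-response
table (zero variance) is handled analytically: the likelihood is unbounded
there, and the fit reports the ML limit (all weights equal to the constant,
variances at the 1e-8 floor) flagged as degenerate. Gaussian residuals on
a non-negative response are a known support mismatch, accepted to match
standard nonlinear mixed-effects practice for this analysis.

Model comparison uses $\mathrm{AICc} = -2\ell + 2k + 2k(k+1)/(n-k-1)$ with
$k$ = fixed weights + 2 variance components, and flags models within
$\Delta\mathrm{AICc} < 4$ of the best as indistinguishable (the
conventional selection guideline). Fits are performed separately per
orientation condition (upright; pitched earth-coded; pitched body-coded);
`compare_models()` refuses fits on differing observation sets.

## Reference-frame test

`to_body_frame()` maps earth directions to body directions by subtracting
the pitch and wrapping into (−180°, 180°] with −180° relabelled 180°, so
the 12-bin grid maps onto itself (a bijection for pitch multiples of 30°).
The wrap convention is stated explicitly because −180°/180° aliasing would
otherwise silently mispair one bin. `compare_frames()` correlates the
participant-averaged upright error pattern with the pitched pattern coded
both ways; the two codings use identical data and differ only by
relabeling, which the tests assert by recomputing one from the other.
The two-sided $p$ uses $n_\text{pairs} - 2$ df. Patterns are averaged
before correlating (12 pairs), mirroring the reference analysis' degrees
of freedom; a per-participant variant is deliberately not the default.

## Stimulus-noise audit

`preprocess_imu()` applies a 4th-order Butterworth low-pass at 80 Hz
forward–backward (zero phase; only the cutoff is externally specified —
order and realization are this package's documented choice) and removes
gravity as the per-axis mean over the whole recording. Means are subtracted
*before* filtering and the result re-centered: a large DC component
produces forward–backward edge transients, and mean subtraction commutes
with a linear filter away from the edges.

`snr()` implements the squared ratio of the rms commanded-vector norm to
the rms commanded-minus-recorded difference norm. For iid per-axis Gaussian
noise of sd $\sigma$ the closed form $(\mathrm{rms}|\mathbf{cmd}|/(\sigma\sqrt3))^2$
serves as an oracle. Noise-free recordings return an `Inf` sentinel
(flagged), an all-zero command returns 0.

`differential_threshold()` encodes the Weber-type functions
$\Delta I = 0.05 I + 0.03$ (horizontal), $0.19\,I^{0.60}$ (up) and
$0.17\,I^{0.42}$ (down), combined quadratically at oblique angles with the
opposite vertical term zeroed. Pure-axis angles route through the axis
formulas directly, treating intensity as unsigned — the physically coherent
reading, since the literal combined formula neither reduces at ±90° (the
0.03 offset persists inside the root) nor behaves at 180° (where
$\cos\alpha = -1$ flips the sign of the Weber term). The literal evaluation
remains available behind `strict = TRUE` and its non-reduction at ±90° is
asserted in the tests as implemented-as-printed behavior.

`noise_vs_threshold()` averages SNR over the five repeats per condition on
the SNR (not dB) scale, takes the absolute target-minus-test difference of
noise rms, and compares it against the lowest differential threshold across
the condition's stimuli with the *target* motion's noise rms as the
stimulus intensity. The hardware recordings behind the original audit are
not available; `synthesize_imu()` provides seeded synthetic recordings
(per-axis Gaussian noise, default sd 0.03 m/s² — small realistic actuator
noise, a one-time choice), so this module reproduces the *procedure* and is
validated on constructions, not on the original figures' magnitudes.

## Problem sizes used in validation

The replicate studies in the test suite use 100 seeded cohorts of 20
participants × 72 upright trials for parameter recovery and
model-selection power (both truths), 100 full cohorts for frame
discrimination, and 10⁴-sample recordings for the SNR closed form; the
narrative scripts under `analysis/` run 25-replicate versions of the same
studies. These sizes were chosen to keep each study's Monte-Carlo error
well below the effects being asserted.

## Known limitations

* **Response truncation biases realized error.** Clipping reproduced
  distances to [0, 2.5] m truncates the error distribution, most strongly
  where $\sigma(\alpha) \approx 0.50$ m meets the 0.5 m smallest target:
  the realized mean absolute error falls ≈0.006 below the nominal
  $w_h = 0.36$ and ≈0.012 below $w_v = 0.40$. Fitted weights estimate the
  realized curve, so paper-scale recovery is biased low by exactly this
  truncation (the test suite documents this: recovery is unbiased for
  small-weight truths whose responses stay away from the bounds, and the
  ordering $w_h < w_v$ is recovered in 97% of paper-scale replicates even
  though the means sit below the nominal truth).
* **Selection power is modest at the design's effect size.** With
  $|w_v - w_h| = 0.04$ against residual sd ≈ 0.3, the generative
  horizontal–vertical model attains the lowest AICc in just under half the
  replicates (more than any other single variant); the isotropy null wins
  most of the remainder. This mirrors the small ΔAICc margins typical of
  this design.
* **Gaussian residuals on absolute error** misstate the support and
  skewness of the response; parameter recovery shows the mean structure is
  nonetheless estimated consistently.
* **The noise audit is synthetic.** Conclusions about any real simulator
  require its actual IMU recordings; the module's CSV interfaces accept
  them.
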