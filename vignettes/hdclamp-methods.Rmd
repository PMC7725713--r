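---
title: "Models and methods behind hdclamp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hdclamp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdclamp)
```

## What the package models

The human dynamic clamp (HDC) is a human--machine interface in which a
person's rhythmic finger movement is coupled in real time to a *virtual
partner* (VP): a model oscillator that reads the human's position and
velocity and moves accordingly. Because the machine side is fully
parameterized, the paradigm turns social coordination into a controlled,
reproducible measurement. In its clinical use, a session of coordination
trials is summarized by five normalized scores — motor, coordination, task,
intention, humanness — spanning a gradient from sensorimotor to
sociocognitive skill, and each score is age-corrected against a control
group by Gaussian-process normative modeling before any case--control
statistics are computed.

The clinical recordings behind that analysis are private. `hdclamp`
therefore pairs the complete analysis pipeline with a *synthetic cohort
generator*: a generative model of participants, sessions and dyadic movement
with the statistical structure the downstream analyses assume (a motor
deficit in the case group, sociocognitive response accuracy improving with
age). Every analysis result obtained with this package describes that
synthetic world; the value of the package is that the pipeline is exercised
end to end, with known ground truth, at the same shapes and sample sizes as
the real study.

## Dyad dynamics

Each effector (human or VP) is a hybrid Rayleigh--van der Pol oscillator

$$\ddot x + (\alpha x^2 + \beta \dot x^2 - \gamma)\,\dot x + \omega^2 x = C,$$

self-sustained for $\gamma > 0$ with limit-cycle amplitude
$r = \sqrt{4\gamma/(\alpha + 3\beta\omega^2)}$ under the rotating-wave
approximation. The coupling force exerted by the partner's state
$(x_o, \dot x_o)$ is HKB-type with an intended-phase parameter
$\mu \in \{+1, -1\}$:

$$C = -(\dot x - \mu \dot x_o)\,\bigl[a - b\,(x - \mu x_o)^2\bigr].$$

With $\mu = +1$ the first term damps the relative velocity and attracts the
dyad to in-phase motion; with $\mu = -1$ the same mechanics act on the
mirrored partner coordinate and attract anti-phase. The sign of the $b$
term matters: written this way, averaging over the fast cycle reduces a
symmetric noise-free dyad to the HKB phase equation

$$\dot\varphi = \Delta\omega - a_\mathrm{red}\sin\varphi
  - 2 b_\mathrm{red}\sin 2\varphi,
  \qquad a_\mathrm{red} = a - \tfrac{b r^2}{2},\quad
  b_\mathrm{red} = \tfrac{b r^2}{8},$$

so anti-phase is stable exactly when $b r^2 > a$. A coupling with
$+b(x-\mu x_o)^2$ is a pure relative-velocity damping whose nonlinear part
only ever strengthens the in-phase pull: it admits no anti-phase regime at
all, which is why the package uses the sign above. The default oscillator
constants ($\gamma = 1$, $\omega = 2\pi$ rad/s, $\alpha = 0.5$,
$\beta = (\gamma-\alpha)/3\omega^2 \approx 0.0042$) calibrate $r = 2$ units,
which makes the stability boundary of the full model coincide with the
reduced equation's $b/a = 1/4$ when the same gains are read into
`hkb_fixed_points()`. Numerically integrated dyads probed on both sides of
the boundary confirm it to within $\pm 10\%$ of $1/4$ — amplitude dynamics
beyond the leading-order averaging shift it slightly, but inside that band.

Two caveats follow from the same analysis. First, strong nonlinear gains
anti-damp the dyad when it transits far from its target pattern; gains with
$b\,(2r)^2 \gtrsim \gamma$ can genuinely diverge, which the integrator
reports as an error rather than silently clipping. Session simulations
therefore default to $a = 0.5$, $b = 0.05$: the intended pattern is encoded
by $\mu$, so the session-level dynamics do not rely on $b/a$ bistability and
the nonlinear term can stay a perturbation. Second, `vp_step()` — the
single-step clamp primitive — holds the human sample *and the coupling force
computed from it* fixed across the RK4 substeps, as a per-frame real-time
loop does; the full simulator integrates the genuinely coupled system.

Integration is fixed-step RK4 at `dt = 0.01` s with Euler--Maruyama noise
injection (standard deviation `noise_sd`, units/s^2) into the human
acceleration only: the real clamp's VP is deterministic given its input.
Trials last 20 s, the first 3 s being the metronome lead-in excluded from
all kinematic scoring; trial duration is a package choice (long enough for
15+ cycles of settled coordination after the transient) since no canonical
value is fixed by the paradigm's printed description.

## Phase extraction and the five scores

Instantaneous phase comes from the analytic signal (FFT Hilbert transform)
of the mean-centered series, with the first and last 5% of samples excluded
as transform edge artifacts; relative phase is wrapped to $(-\pi, \pi]$.
Phase extraction was chosen over peak-picking because it yields a dense
estimate on every retained sample.

Per trial, on the post-metronome segment:

* **motor** $= \operatorname{clamp}\bigl(1 - |A_h - A_{vp}|/A_{vp},\,0,\,1\bigr)$,
  where $A$ is the median per-cycle peak-to-peak amplitude (cycles delimited
  by upward mean-crossings). Medians keep single distorted cycles from
  dominating.
* **coordination** $=$ the mean resultant length
  $\bigl|\langle e^{i\varphi_{rel}}\rangle\bigr|$ — the phase-locking value,
  agnostic to which phase relation is held.
* **task** $= \langle (1 + \cos(\varphi_{rel} - \varphi_{target}))/2 \rangle$
  with target 0 (in-phase instruction) or $\pi$ (anti-phase). The smooth
  cosine profile is one defensible operationalization of
  "instruction-conditional phase matching"; a tolerance-window variant would
  change absolute levels but not the comparisons the pipeline runs on it.
* **intention**: per-trial credit 1 if the rating sign matches the VP's true
  cooperative/competitive behavior, 0.5 for "unsure" (rating 0), else 0.
* **humanness**: fraction of trials judged "human".

Scores aggregate per participant globally (every trial weighted equally) and
within the four instruction-by-behavior cells; an unvisited cell is missing,
never zero.

## The synthetic cohort

Defaults reproduce the reference study's demographic frame: 113 ASD
(age $11.2 \pm 3.2$, m/f 96:18 — realized as 95:18 at $n = 113$, since the
printed counts sum to 114) and 42 controls (age $16 \pm 4.4$, m/f 25:17),
ages truncated to 5--25 years, and a 40-trial protocol of four
alternating-instruction blocks with i.i.d. fair-coin VP behavior.

Participant-level generative parameters:

| parameter | default (controls) | role |
|---|---|---|
| `motor_gain` | lognormal, median 1, sdlog 0.15 | movement amplitude factor |
| `motor_noise_sd` | lognormal, median 2 units/s^2, sdlog 0.3 | neuromotor noise |
| `compliance` | normal(1, 0.25) clipped to [0, 2] | coupling-gain multiplier |
| attribution logit | intercept $\mathcal N(-0.8, 0.4)$, slope $\mathcal N(0.12, 0.03)$/yr | intention accuracy |
| humanness logit | intercept $\mathcal N(-1.2, 0.5)$, slope $\mathcal N(0.08, 0.02)$/yr | humanness judgments |

The case group multiplies `motor_gain` by 0.8 and `motor_noise_sd` by 1.5.
The noise median is the one constant that was calibrated by hand: at
markedly higher noise the within-cycle jitter inflates the measured
peak-to-peak amplitudes enough to mask the amplitude deficit that the gain
multiplier injects, defeating the generator's purpose. At the default the
injected deficit comes through at $d \approx -0.9$ on the motor score —
larger than the clinical report's $-0.5$, which the defaults make no claim
to match; only the sign and the null behavior are treated as testable.

End-of-trial responses are the simplest monotone models that reproduce the
observed developmental structure: the intention rating is correct with
probability $\operatorname{logit}^{-1}(b_0 + b_1\,\mathrm{age})$, "unsure"
with fixed probability 0.05, and inverted otherwise; the humanness judgment
is "human" with probability
$\operatorname{logit}^{-1}(c_0 + c_1\,\mathrm{age} + 1.5\,(R - 0.5))$ where
$R$ is the trial's phase-locking (people judge stable partners more human).
Ratings are ternary $\{-1, 0, +1\}$; a graded cooperativeness scale would be
binarized by sign anyway for the intention score.

What the generator does *not* emulate: instrument scores (IQ, SRS-2,
NEPSY-II, Purdue) are plain group-shifted normals used only to exercise the
correlation machinery; there is no item-level structure, no
missing-at-random pattern, no drift within session, and no age effect on
task compliance — so the real study's positive age-task correlation is not
reproduced, and passing tests say nothing about those aspects of real data.

## Normative modeling

For each score, a Gaussian process is fitted to the control group over age:
squared-exponential kernel plus independent noise, constant mean fixed at
the training mean, hyperparameters by maximizing the log marginal likelihood
(analytic gradients, L-BFGS-B in log-parameter space, five seeded starts;
length-scale bounded to [1, 30] years, variances to [1e-6, 10]). The model
separates the smooth developmental trajectory (GP mean), population
heterogeneity plus measurement noise (noise variance) and the uncertainty
of the fit itself (posterior variance, widening outside the training ages).

A participant's deviation score is
$z = (y - \mu(\mathrm{age}))/\sigma(\mathrm{age})$ with $\sigma$ the *total*
predictive spread including the noise variance. Cases are scored against the
full control fit; controls are scored leave-one-out (the model is refitted
without the scored row, warm-started from the full fit) so that control
z-scores are not shrunk by having been in their own reference — without
this, control variance is biased low and case--control comparisons
optimistic. Held-out calibration is checked directly: on synthetic controls
the z distribution is standard normal within the tolerances the tests
state, and under null-mode cohorts the downstream Welch test on NM scores
keeps its nominal type-I error.

Percentile norms use midpoint ranks,
$100\,(n_{below} + \tfrac12 n_{equal})/n$.

## The statistical battery

All tests report the pooled-SD Cohen's $d$ with the convention *cases minus
controls* (negative = cases lower). Demographics use Welch t for continuous
variables and the Yates-corrected chi-square for 2x2 tables. Developmental
correlations are Pearson $r$ with the $t$-transform p-value. Global NM
comparisons default to Welch t. The per-cell grid defaults to a one-sided
permutation test (10,000 seeded resamples) directed by the observed $d$ —
the pattern of the reference report's per-cell $(d, p)$ pairs is most
consistent with one-sided tests, and the choice is an argument, not a
constant. The subcondition regression is OLS on the coded design
`outcome ~ diagnosis + age + behavior + task + behavior:task`: the reference analysis's
residual df (618 at 156 participants x 4 cells) implies five predictors for
four named ones, and the behavior-by-task interaction is the natural fifth;
it is switchable (`interaction = FALSE`) if a different fifth predictor is
ever established. No multiple-testing correction is applied, matching the
raw p-values the battery mirrors.

Exploratory stratification is Ward (`ward.D2`) hierarchical clustering of
standardized NM scores cut at $k = 2$, scored against diagnosis by adjusted
Rand index and Fisher's exact test; classification is logistic regression
with stratified 5-fold cross-validation, per feature and combined, reporting
AUC.

## Determinism and numerics

A single master seed determines everything: stage and unit seeds derive
through a fixed integer fold (`derive_seed`), simulation noise flows through
R's RNG inside the compiled integrator, the GP restarts are seeded, and the
permutation and cross-validation resamples are seeded. Re-running
`run_pipeline()` with the same config reproduces byte-identical score and
NM tables. Numerical guardrails: the integrator reports divergence (step
index) instead of returning clipped garbage; phase extraction refuses
near-flat series (range below `osc_floor`); the GP refuses fewer than 10
controls and handles constant targets through its noise term; rank-deficient
regression designs are refused with the collinear columns named.

Problem sizes in the shipped tests are the package's own choices: full-size
cohorts (113/42, 40 trials of 20 s) for the parameter-recovery and
null-calibration loops at 50 and 200 replicate seeds respectively, 500
held-out controls for GP calibration, and shorter 8 s trials where a test
only needs the response models, not settled kinematics.

## Known limitations

* The VP equations are a reconstruction of the coordination-dynamics family
  the paradigm belongs to, with constants isolated in
  `oscillator_params()` / `coupling_params()`; absolute score levels should
  not be compared against clinical numbers.
* Age enters the normative model as the only covariate (sex could be added
  as an additive covariate but is off by default, matching the age-based
  analyses the pipeline mirrors).
* The exact clinical score formulas, the identity of the fifth regression
  predictor, and the test behind the per-cell p-values are not public;
  each corresponding choice here is documented above and kept local to its
  function so a future alignment is a one-line change.
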