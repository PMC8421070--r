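---
title: "Models of reach planning under goal uncertainty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models of reach planning under goal uncertainty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reachplan)
```

## The scientific question

When a reaching movement must start before the final goal is known — the
"go-before-you-know" paradigm, where one of two potential targets is cued
only after movement onset — the initial movement is typically aimed
between the potential targets. Two theories explain such intermediate
movements. **Motor averaging (MA)** holds that the motor system prepares
a plan for each potential target and executes their (weighted) average.
**Performance optimization (PO)** holds that the motor system prepares a
single plan for the intermediate movement itself, chosen to maximize task
success. The two theories coincide in most tasks; `reachplan` implements
two experimental designs, and their analysis pipelines, in which they
make opposite predictions:

1. **A composite force-field environment.** Movements to the lateral
   targets (±30°) are perturbed by one viscous curl field
   (`FF_LATERAL`), movements to the center target (0°) by the opposite
   field (`FF_CENTER = -FF_LATERAL`). After adaptation, MA predicts that
   a goal-uncertain movement carries the lateral compensation (the
   average of two identical lateral plans), while PO predicts the
   center compensation, its near opposite. Planned forces are read out
   with error-clamp channels.
2. **Obstacle avoidance.** An obstacle blocks the direct path to one
   potential target. Depending on its shape it deflects single-target
   movements either toward the midline (the `expt2a` geometry: 1 × 12 cm
   rectangle at the path midpoint, protruding 2 cm toward and 10 cm away
   from the midline) or away from it (the `expt2b` geometry, with the
   away-from-midline part clipped off). MA predicts that goal-uncertain
   movements inherit a portion of the single-target deflection — toward
   the obstacle for `expt2b` — while PO predicts deflections that always
   increase the safety margin away from the obstacle.

## Models

### Force-profile predictions and the prediction index

Lateral force profiles on (partial) error-clamp trials are aligned to
the target-cue onset (the 3 cm excursion point, `T_ON`) and normalized
so +1 equals the peak of the ideal compensation for the center-target
field, `B·v(t)` with `B = 15` N·s/m. The MA prediction is the pointwise
mean of the left- and right-target adaptive responses; the PO prediction
is the center-target response. Observed 2-target profiles are located
between the predictions by the prediction index
$$\mathrm{PI} = \frac{\mu_2 - \mu_C}{\mu_D}, \qquad
  \mu_C = \frac{\mu_{PO} + \mu_{MA}}{2}, \qquad
  \mu_D = \frac{\mu_{PO} - \mu_{MA}}{2},$$
so that +1 means the data equal the PO prediction, −1 the MA
prediction, and 0 halfway. Profile means run from movement onset to
either `T_ON` or the feedback-response onset `T_RESP`, the earliest time
at which left- and right-cued 2-target profiles differ reliably across
participants (paired two-sided t-test per sample at α = 0.01, sustained
for 3 consecutive samples; the sustain requirement suppresses isolated
false positives, and the α matches the global level used elsewhere in
the pipeline). The PI is invariant under common affine rescaling of all
three profiles. Where the interval start is concerned, the go cue and
movement onset are nearly coincident in this paradigm; the
implementation starts the interval at movement onset and exposes the
choice through the profile span.

The per-trial **adaptation coefficient** is the no-intercept
least-squares slope of the baseline-subtracted measured force on the
ideal compensation. No intercept is fitted because baseline subtraction
already removes offsets. Signs are expressed in center-field units: +1
is full compensation of the center-target field, −1 of the
lateral-target field.

### Generalization and refinement

Adaptation generalizes locally across movement directions. The
generalization function is a sum of equal-width Gaussians at the trained
directions,
$$g(\theta) = -A_1 e^{-(\theta-30)^2/2\sigma^2}
 + A_2 e^{-\theta^2/2\sigma^2}
 - A_1 e^{-(\theta+30)^2/2\sigma^2} + A_0 .$$
Because the model is linear in $(A_1, A_2, A_0)$ given $\sigma$, the fit
profiles the amplitudes exactly and searches $\sigma$ on a dense grid
with local refinement; this makes the global optimum certifiable on the
grid, where a joint four-parameter descent can stall in local minima.
For constant data the amplitude family is degenerate; the fit returns
$A_1 = A_2 = 0$, $A_0$ equal to the constant, and defines $R^2 = 1$
when the residual sum of squares is numerically zero. Movement
directions scatter (SD ≈ 6° in the generator), so predictions are
refined by the factor
$\mathbb{E}[g(\theta)] / g(\theta_{\text{nominal}})$, the expectation
taken over the empirical direction sample (no kernel smoothing — the
simplest faithful estimate of expected adaptation), evaluated up to
±42.5° with out-of-span samples clipped to the boundary.

### Safety-margin models of obstacle avoidance

Per-participant summaries (mirrored onto a left-obstacle convention and
pooled across sides) feed four models of the mean 2-target direction
$\mu_2$:

* baseline MA: $\hat\mu_2 = \tfrac12\mu_{1A} + \tfrac12\mu_{1B}$;
* refined MA: $\hat\mu_2 = \alpha\,\mu_{1A} + (1-\alpha)\,\mu_{1B}$;
* baseline PO: $\hat\mu_2 = \tfrac12\cdot 0° + \tfrac12
  (\mu_{1A}\,\sigma_2/\sigma_{1A} - 15°)$, floored at 0° when the
  scaled margin does not exceed the 15° obstacle offset;
* refined PO: $\hat\mu_2 = \beta\cdot 0° + (1-\beta)
  (\mu_{1A}\,\sigma_2/\sigma_{1A} - 15°)$.

$\mu_{1A}$, $\mu_{1B}$ are single-target mean deflections, $\sigma_{1A}$
and $\sigma_2$ direction SDs (plain sample SDs; the angles involved stay
well below 45°, where circular statistics would matter), and 15° is the
angular offset of the obstacle-protrusion tip from the straight-ahead
direction. Population-level predictions use the **ratio of cohort
means** $\bar\sigma_2/\bar\sigma_{1A}$; the individuation models below
use per-participant ratios — both usages are explicit functions.
$\alpha$ and $\beta$ are constrained to [0, 1]. They are estimated as
no-intercept regression slopes — $\mu_2 - \mu_{1B}$ on
$\mu_{1A} - \mu_{1B}$ for $\alpha$; $\mu_2$ on
$\mu_{1A}\sigma_2/\sigma_{1A} - 15°$ for $\beta$, whose slope is
$1-\beta$ — with the unconstrained solution projected (clipped) onto
[0, 1]. Projection suffices for a one-dimensional problem and is
verified against dense grid search in the tests. Cross-validation fits
the weight on one cohort and evaluates its population-level prediction
on the other, reporting the percentage MSE increase over the evaluation
cohort's own fit; per-participant squared errors are always computed
against the population-level prediction, which is what yields an SEM
alongside each MSE.

**Sign conventions.** Summaries live in a mirrored left-obstacle frame
whose positive direction increases the 2-target safety margin. In that
frame $\mu_{1A} > 0$ for the `expt2a` obstacle and $\mu_{1A} < 0$ for
`expt2b`. MA, which averages movement plans, consumes frame-signed
values; PO, which scales safety margins, consumes the positive margin
magnitude obtained by `variant_margin()` (identity for `expt2a`, sign
flip for `expt2b`). Direction SDs are computed after mirroring, before
pooling.

### Individuation models

Inter-participant differences are modeled by interpolating each PO
input between its group mean and the participant's own value with
indices $k \in [0,1]$ (one shared index, or one per input), for example
$$\hat\mu_{2i} - \bar\mu_2 = \tfrac12
  \left(k\mu_{1Ai} + (1-k)\bar\mu_{1A}\right)
  \left(k\sigma_{2i} + (1-k)\bar\sigma_2\right)
  \left(\frac{k}{\sigma_{1Ai}} + \frac{1-k}{\bar\sigma_{1A}}\right)
  - K_0 .$$
Bar quantities are unweighted cohort means of the per-participant
values. $K_0$ is a free offset that keeps $R^2$ well-posed. The model
is a product of affine terms, hence nonconvex in the indices;
optimization uses a dense grid for the single index, and multi-start
bounded quasi-Newton descent plus coordinate-wise grid polish for the
three-index model, always with $K_0$ profiled out exactly. Indices are
clipped to [0, 1] by the bounded optimizer itself, and every estimate is
checked against a dense grid-search oracle in the tests. Each
variable's **partial R²** comes from refitting with that variable's
index fixed at zero:
$(SSE_{\text{red}} - SSE_{\text{full}})/SSE_{\text{red}}$, with an
F-test on $(1, n - p)$ degrees of freedom where $p$ counts indices plus
the offset (2 for the one-index model, 4 for the three-index model) —
the offset is counted as a parameter. Partial-residual datasets for
effect plots zero the *other* two indices in the fitted model, add the
full-model residuals, and mean-subtract.

## The synthetic-data generators

The package is exercised entirely on synthetic cohorts, generated at the
level each analysis stage consumes.

**Multi-field cohorts** (`simulate_ff_cohort()`) run a linear
state-space learner with Gaussian motor primitives (centers every 7.5°
over ±45°, width 15° — matching the generalization-function form the
analysis fits) through the full trial schedule: baseline familiarization
with interspersed clamps, 500 training trials at a 1:2:1
left:center:right ratio with 80% field / 20% clamp trials, and a test
epoch mixing field trials, error clamps, and 2-target partial clamps
(1305 reaches in total). The learner decays by the retention factor,
expresses the decayed state, and updates on the observed error; clamp
trials suppress the error and measure the planned force instead, on a
minimum-jerk speed profile with additive force noise (SD 0.25 N) and
per-trial direction noise (SD 6°). No rigid-body or channel dynamics
are integrated: the analysis consumes force profiles, so clamp trials
are modeled as direct measurements of the planned lateral force, and
the channel stiffness/damping constants (6000 N/m, 250 N·s/m) and the
11 cm partial-clamp release travel as metadata only. Retention (0.995)
and learning rate (0.08) are free parameters — no published values
exist for them — chosen once so that training yields similar adaptation
magnitudes (≈0.75–0.81) across the three targets with opposite center
vs. lateral signs; the 1:2:1 ratio is what balances them. The
ground-truth planning rule for 2-target trials is selectable: the
learner's output at the realized intermediate direction (PO) or the
mean of its outputs at the two target directions (MA). A cued-side
corrective force ramps in 150 ms after the cue, which is what the
feedback-response detector finds.

**Obstacle cohorts** (`simulate_obstacle_cohort()`) draw
per-participant condition means and variabilities — `expt2a`: n = 8,
margins around 28°; `expt2b`: n = 26, margins around 22° (frame value
−22°); variabilities lognormal around 4° with a common distribution for
1- and 2-target trials, so the population variability ratio is near 1 —
and then draw 50 trial directions per condition, split across left- and
right-side obstacle placements, with obstacle-free 2-target trials
assigned side labels from the seeded stream. Summaries are recovered by
the same mirroring-and-pooling code the analysis uses. The margin
distributions keep each participant's scaled margin above the 15°
offset, as observed in practice, so the baseline PO floor stays
inactive under default conditions. Under these defaults the
equal-weight PO rule yields mean 2-target deflections of ~2.5–3.5°
for `expt2b`, in the few-degree range such experiments report.
`simulate_margin_cohort()` and `simulate_individuation_cohort()`
generate summaries directly (margins uniform on [10°, 35°], variability
ratios lognormal around 1, additive direction noise on $\mu_2$) for
parameter-recovery studies where trial resampling noise would obscure
the estimand.

All generators split per-participant streams from one root seed by
counter, so cohorts are bit-reproducible and participants independent.

**What the generators do not emulate:** reaction times and go-cue timing
windows, online feedback control and obstacle-collision dynamics (trial
directions are drawn, not steered), within-participant direction-specific
variability structure, explicit strategy use, and trial-order effects
such as savings or interference beyond the learner's single state.
Passing tests therefore show that the pipeline recovers the truth its
models assume, under realistic noise — not that those models describe
any particular dataset.

## Numerical choices and edge cases

* Percentiles (movement-time thresholds) use the linear-interpolation
  definition (`quantile` type 7), isolated in one function.
* Collision detection treats the obstacle rectangle as a closed set
  (touching counts) and clips each sampled segment against it exactly.
* Movement onset is the first sample with speed above 5 cm/s or
  displacement above 3 cm, whichever is earlier; reference crossings
  (10 cm, midpoint) are located by linear interpolation.
* Trials whose trajectory never reaches the reference displacement are
  flagged `NA` and excluded from direction statistics; non-monotone
  paths are dropped from trajectory averages with a warning.
* Trial filtering keeps movement times in [225, 2000] ms and — for
  force-field-style data only — peak speeds in [0.2, 1] m/s, counting
  each rejection once under the first violated bound.
* The prediction index is undefined when the two predictions coincide;
  the fits error on degenerate regressors (below 10⁻⁸ in magnitude) and
  on cohorts with no inter-participant variance.
* Force-profile averaging restricts to the largest cue-aligned span all
  trials share.

## Problem sizes

The test suite runs the force pipeline on scaled-down cohorts (4
participants, 340-trial schedule) for its 200-replicate dissociation
checks, and the direction pipeline at the full n = 26; single runs at
the full 1305-trial, 16-participant scale behave identically and are
exercised once in the schedule tests. Recovery studies use 100
replicates at n = 26; oracle-equivalence checks use 50 random cohorts.

## Limitations

The pipeline is validated generatively: its models are fit to data
produced by the same model families plus noise. Real datasets bring
structure the generators omit (see above), and the obstacle-frame sign
conventions must be mapped carefully when importing external data
(`import_external()` expects the documented mirrored-frame schema).
The refined PO fit uses per-participant variability ratios in its
regressor; a population-ratio variant would differ slightly when ratios
vary widely across participants.
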