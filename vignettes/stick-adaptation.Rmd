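---
title: "Modelling adaptation in the bimanual stick-reaching task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling adaptation in the bimanual stick-reaching task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stickreach)
```

## The task and its redundancy

A virtual stick is held with two hands; the task is to move the stick's
right tip from a start position to a target 10 cm away in one of nine
directions (0°, ±10°, ±20°, ±30°, ±40°, counter-clockwise positive). The
hands are 15 cm apart on the stick, with lever arms of L = 40 cm (left hand
to tip) and R = 25 cm (right hand to tip); the grip is modelled as a rigid
link. Because the tip position does not determine the stick orientation, the
task has one redundant degree of freedom, summarized by two coordinates:

* **TMD** — tip-movement direction relative to horizontal, and
* **STA** — stick-tilt angle relative to the initial horizontal state.

Every simulated and analyzed movement lives on this (TMD, STA) plane, in
two frames: *physical* (what the hands do) and *visual* (what is displayed).
`plane_state()` tags the frame and all consumers reject cross-frame input.

## The baseline strategy as hand-path-cost minimization

`hand_path_cost()` computes the summed Euclidean displacement of the two
hands between movement onset and offset as a function of the target (φ, d)
and the final stick tilt θ. At θ = 0 both hands translate in parallel and
the cost is 2d for every target. Minimizing over θ (`optimal_tilt()`)
predicts the tilt a cost-optimal actor would adopt:

```{r}
predicted_relation()
```

The optimizer is a bracketed scalar search on θ ∈ [−89°, 89°] followed by a
stationary-point polish (root of the central-difference gradient); it
refuses to return if the gradient at the reported optimum exceeds
10⁻⁸ cm/deg. The domain bound keeps the search away from degenerate
geometry; physical tilts in this task are below 10°. The mapping from
target direction to optimal tilt is strictly increasing and antisymmetric —
the model-side **baseline TMD–STA relationship**. Note that the optimal tilt
at ±30° is ±6.6°, the scale at which the tilt perturbation (below) was set.

## Representing and fitting the baseline relationship

`fit_baseline_relation()` estimates the relationship g: TMD → STA from
baseline trials: trials are binned by nominal target, each bin contributes
a knot at its mean (TMD, STA), and monotonicity is enforced by weighted
pool-adjacent-violators. Between knots g is piecewise linear; beyond the
outermost knots it extrapolates with the nearest segment's slope. A
piecewise-linear form was chosen over a spline because the learner needs a
well-defined, non-negative local slope everywhere and the data constrain no
particular curvature. Per-participant relations are fitted from that
participant's own baseline trials; a population relation can be formed from
knot means.

The relationship can equally be built from the cost model
(`relation_from_optimum()`) or specified directly (`linear_relation()`),
which the simulator uses for synthetic participants.

## Perturbation regimes

`perturbation_spec()` describes the two visual manipulations:

| component | geometry | schedule | default |
|---|---|---|---|
| tip rotation | about the start position (end-effector **relevant**) | gradual: +1°/trial up to +30°; or abrupt +30° | E1-style |
| tilt rotation | about the tip (end-effector **irrelevant**) | proportional to tip displacement, ±0.6°/cm, i.e. ±6° at the 10 cm target | E2-style |

The six study arms combine them: E1A/E1B (tip only, gradual/abrupt),
E2CCW/E2CW (tilt only), E3CCW/E3CW (gradual tip + tilt of either sign);
`make_protocol()` returns the matching spec. The tilt perturbation is linear
in displacement with no cap — the movement terminates at 10 cm, where it
reaches 6°, and nothing in the protocol defines behaviour beyond that. On
the plane, the tip rotation is a horizontal shift by the scheduled ρ(trial)
and the tilt rotation a vertical shift by `tilt_sign · 0.6 · r`; at the
pose level `apply_visual_map()` implements the same maps as an isometry
about the start (exactly invertible, `invert_visual_map()`).

## The constrained-correction learner

The learner formalizes the hypothesis that the motor system corrects *any*
visual error — task-relevant or not — but that the physical correction is
constrained to the baseline relationship. Its state is the planned physical
intent x = (m, a). Each trial:

1. execution: x_exec = x + motor noise (independent Gaussians, SD
   `motor_noise_tmd`, `motor_noise_sta`);
2. observation: the visual state is the plane map of x_exec at end of
   movement, where the tilt perturbation has its full ±6° value;
3. errors: task error e_m = target − TMD_vis and tilt prediction error
   e_a = g(TMD_vis) − STA_vis;
4. update: with s = g′(m), unit tangent t = (1, s)/√(1+s²) and weighted
   error u = (η_m e_m, η_a e_a),

   x′ = b + (1 − λ)(x − b) + (u·t) t,

   where b = (target, g(target)) is the baseline point and λ the retention
   loss. The displacement (u·t) t is *parallel to the relation tangent by
   construction* — the formal statement of adaptation proceeding along the
   baseline relationship.

Two consequences carry the study's qualitative findings. For the tip
rotation alone, the steady state of the along-relation recursion (linear g
with slope s) is m\* = −30 + 30 s² η_a/η_m: with η_a = 0 compensation is
complete, with η_a > 0 the attempt to correct the perturbation-free but
*abnormal-looking* visual tilt leaves a residual error. For the tilt
perturbation alone, m\* = −s η_a δ/η_m: a perturbation that never affects
the task goal still shifts both dimensions, with the TMD shift sharing the
STA shift's sign. Combining perturbations makes the early tilt error either
assist (E3CCW) or oppose (E3CW) tip adaptation, delaying the E3CW arm.

**Parameter choices.** The learner's free parameters have no reference
values, so the defaults are set where implicit visuomotor adaptation
studies typically land: η_m = η_a = 0.3 (single-trial corrections of
10–40 % of error), λ = 0 (no decay over a 240-trial block with a
continuously present perturbation), motor noise 1° SD per dimension
(typical trial-to-trial directional variability of reaching). They were
chosen once, from that reasoning, and are the conditions under which all
population-level tests run.

**An open tension.** Under the projection rule, steeper baseline relations
produce *larger* tilt corrections (the tangent points more along STA),
whereas empirically participants with shallower relations correct a fixed
6° tilt perturbation more. An optional flag (`tilt_error_norm = TRUE`)
rescales η_a by 6/|g(30°)|, normalizing tilt-error sensitivity by the
participant's own tilt repertoire; this raises shallow participants'
corrections but does not invert the steepness dependence, because the s²
geometry of the projection dominates. The default leaves the flag off; the
discrepancy is a property of the hypothesis as formalized, documented
rather than hidden. Similarly, e_a evaluates g at the *visual* TMD — the
state the observer actually sees — rather than at the intended TMD; the two
choices differ only at second order for small perturbations.

`fit_learner()` recovers (η_m, η_a, λ) from an observed executed series by
least squares against noise-free model trajectories over a parameter grid,
vectorized across grid points. Noiseless series are recovered exactly at
grid resolution; at 1° noise and 240 trials the median recovered η_m across
20 seeds stays within ±20 % of truth (the package's parameter-recovery
test).

## Trial synthesis and analysis

`synthesize_trial()` generates within-trial kinematics: a straight
minimum-jerk tip path (quintic displacement, bell-shaped speed, closed-form
peak 1.875 d/T at τ = ½) and a stick tilt ramping linearly with
displacement to the intended STA, with hands derived sample-by-sample from
the geometry. The minimum-jerk family was chosen because observed speed
profiles are bell-shaped and the quintic has closed forms to test against;
the linear tilt ramp mirrors the within-movement tilt growth and makes the
tilt perturbation (itself displacement-proportional) commensurate. Defaults:
0.5 s duration, 1 kHz sampling — giving a 375 mm/s peak, inside the
300–450 mm/s feedback band implemented by `speed_feedback()`.

Analysis follows the standard kinematic pipeline: zero-phase fourth-order
Butterworth low-pass at 10 Hz (edge transients controlled by odd-reflection
padding and steady-state initial conditions, so DC passes untouched and
peak timings are unbiased), peak-velocity sample by global maximum of the
filtered tip speed (first index on ties), TMD as the chord angle from the
trial start to the tip at that sample (equivalent to the instantaneous
direction for straight paths and more robust to noise; the velocity
read-out is available via `method = "velocity"`), STA relative to the
trial's initial tilt. Movement offset, needed for the offset-STA read-out,
is the first sample at full displacement with speed below 5 % of peak.

Because the tilt ramp is linear and the minimum-jerk peak sits at half
displacement, the *peak-velocity* STA of a synthesized trial is exactly
half the intended offset STA. The package treats end-of-movement states as
the model's currency (the learner observes the full ±6° there) and keeps
the factor explicit wherever peak-velocity read-outs are compared to
intents; the simulator↔analysis closure test pins both the exact TMD and
the d/2 factor.

Trial segments follow the standard nine-segment scheme (1–5, 6–10, 11–15,
16–20, 21–25, 26–30, 31–120, 121–210, 211–240); the historical overlap of
the two middle segments at trial 30 is normalized to 26–30 / 31–120 so the
segments partition the phase. Trial-by-trial variability is the sample SD
over trials 121–240. Group statistics use `t.test`, `cor.test` and a
textbook Cohen's d; repeated-measures ANOVA/MANOVA inference on human data
is out of scope.

## The synthetic study

`make_population()` draws participants with baseline relation slopes from
N(0.2, 0.07²) truncated at zero. These population parameters are stand-ins,
not measured quantities: the mean is set so that reaching the ±30° targets
tilts the stick about ±6° at movement offset (the scale the tilt
perturbation was matched to, and close to the cost model's 6.6°), and the
SD produces the clearly heterogeneous but universally monotone individual
relations seen in baseline data. Baseline intents sit *on* each
participant's relation from trial 1 — synthetic participants are
"pre-optimized", consistent with the stereotyped tilt strategy being
present from the start of the task, which familiar bimanual manipulation
plausibly provides. Baseline target order is blocked pseudo-random (each
target once per nine-trial block), a conventional choice the protocol does
not pin down.

`run_experiment()` composes everything: 360 baseline trials at
relation-consistent intents plus noise, then 240 adaptation trials through
the learner under the arm's perturbation, end-to-end deterministic given
the population seed (per-participant seeds are derived from it). Runs
operate on plane states; full kinematic traces for any trial are available
through `synthesize_trial()` and the CSV dialect
(`as_trial_table()`/`read_trial_csv()`/`analyze_trials()`).

```{r}
run <- run_experiment(make_population(10, population_seed = 42),
                      make_protocol("E1A", seed = 42))
run
```

## Problem sizes, determinism and limitations

The package's tests run the study at its native scale — 240-trial
adaptation phases, ten participants per arm — with 20 seeded replicates for
the population-level sign and ordering properties and for parameter
recovery; the whole suite completes in well under a minute of compute.
All stochastic paths accept explicit seeds, restore the caller's RNG
state, and are bit-reproducible.

What passing these simulations does *not* show: the generator emulates
idealized movements (straight paths, fixed trial duration, exact
minimum-jerk speeds, linear tilt ramps, trial-level Gaussian noise) and an
idealized learner (no explicit strategy, no error-sensitivity modulation,
no within-trial feedback corrections — E1B's abrupt rotation is simulated
with the same implicit rule, justified by the near-identical human
outcome). Human data contain curved paths, within-trial corrections,
duration variability and non-stationary noise; quantitative human
statistics (specific t, R and Cohen's d values) are data-dependent and are
reproduced only at the level of signs, orderings and magnitudes on
synthetic cohorts. The grip is rigid, whereas the apparatus enforces hand
separation with a stiff spring; and all conclusions are tied to this
specific geometry (L = 40 cm, R = 25 cm, d = 10 cm).
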