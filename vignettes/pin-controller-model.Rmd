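---
title: "The pin-controller model of quiet standing: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The pin-controller model of quiet standing: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pincontrol)
```

## 1. The model

Quiet standing is idealized as a single-segment inverted pendulum pivoting
at the support surface. For each horizontal direction (anteroposterior AP,
mediolateral ML) independently,

$$\ddot{x}(t) = \frac{g}{h}\,\bigl(x(t) - u(t)\bigr),$$

where $x$ is the horizontal centre-of-mass (CoM) position, $u$ the total
centre of pressure (CoP), $g$ gravity and $h$ the CoM height. Under this
relation the difference $d = u - x$ and the CoM acceleration are exactly
anti-proportional, so their Pearson correlation is $-1$; departures from
$-1$ measure departure from pendulum-like control. The package's sign
convention is $d = \mathrm{CoP} - \mathrm{CoM}$ throughout, so *negative*
r denotes model conformance. (The alternative reading of the difference as
CoM $-$ CoP merely flips every sign; we fix the convention that makes the
conforming correlations negative, consistent with how such tables are
reported.)

The *unilaterally-constrained pin-controller* variant assigns the two
limbs different roles:

* **pin limb** — its CoP is fixed at the pin axis (no corrective motion).
  For standers with a prosthesis the pin sits anterior of the ankle; the
  package places it at `pin_fraction` (default 0.66) of the
  ankle-to-fifth-metatarsal distance, reflecting the anterior CoP shift
  observed under prosthetic feet.
* **controller limb** — realizes the whole AP command through its
  within-foot CoP, which is solved per sample from
  $u_{\mathrm{total}} = a\,u_{\mathrm{ctrl}} + (1-a)\,p$ (load share $a$,
  pin location $p$) and clamped to the foot bounds (clamping events are
  counted and flagged).

In ML, neither foot can move its CoP far within the shoe width; control
is instead exerted by *load/unload*: per-limb ML CoPs stay near the foot
centres and the share $a(t)$ is modulated so that the load-weighted
combination tracks the ML command. This mechanism is what produces
near-zero per-limb ML correlations together with strongly negative
*total* ML correlations — the combination moves even though neither
per-limb CoP does.

### Control law

The total CoP command is a delayed proportional–derivative law with
exploratory noise,

$$u(t) = x_{\mathrm{ref}} + k_p\,[x(t-\Delta) - x_{\mathrm{ref}}] +
  k_d\,\dot{x}(t-\Delta) + n(t),$$

with $n$ white noise low-passed at `noise_cutoff`. Closed-loop stability
of the unstable pendulum requires $k_p > 1$. This law is the package's own
construction: the pin-controller idea specifies *roles*, not equations,
and any stabilizing servo yields the same qualitative signature.

## 2. Parameters, units, defaults

| parameter | unit | default | why |
|---|---|---|---|
| `body_mass` | kg | 81 | group mean of the population the model targets |
| `body_height` | m | 1.80 | idem; marker layout scales with it |
| `com_height` h | m | `synthetic_com_height(1.80)` ≈ 1.00 | mass-weighted height of the bundled segmental model, so segmental CoM estimation is exact on noiseless synthetic markers |
| `kp` | – | 1.06 | chosen so the CoP SD / CoM SD ratio is ≈ 1.3, inside the observed human band (≈ 1.1–1.5); larger gains make the simulated CoP implausibly over-active (see §5) |
| `kd` | s | 0.35 | damping inside the stable region; CoM velocity SD ≈ 5–6 mm/s |
| `delay` | s | 0.15 | physiological feedback dead time |
| `noise_sd` | m | 0.03 | white-noise SD at the 1000 Hz internal rate, before shaping; yields CoP SD ≈ 5–10 mm and CoM SD ≈ 3–6 mm, typical quiet stance |
| `noise_cutoff` | Hz | 5 | exploratory noise occupies the full band the analysis retains; see §5 |
| `within_foot_noise_sd` | m | 5e-4 | small per-limb CoP jitter (10 Hz band); zero on the pin side by definition |
| `ec_noise_multiplier` | – | 1.5 | eyes-closed inflates sway noise |
| `fb_share_gain` | s⁻¹ | 0.1 | FB condition: integral pull of the load share toward 0.5, time constant ≈ 10 s |
| `mean_load_share` | – | 0.6 | habitual weight-bearing on the intact limb (asymmetry is reported qualitatively for prosthesis users; 60:40 is a representative value and is configurable) |
| `stance_width` | m | 0.25 | distance between foot centres |
| `foot_length`, `ankle_to_met5` | m | 0.25, 0.15 | ankle at 25% of foot length from the heel |
| `block_height` | m | 0 (0.08 for the constrained able-bodied mode) | height of the pin device / matching block; a synthetic stand-in, since no device height is published |
| `marker_noise_sd` | m | 3e-4 | motion-capture-grade marker noise |

Conditions: EO is the baseline; EC multiplies `noise_sd` by
`ec_noise_multiplier`; FB activates the integral share regulation (the
stander still *starts* at their habitual share — feedback pulls them
toward symmetry over the trial).

## 3. What the generator emulates, and what it does not

Emulated: 60-s trials at 100 Hz; two parallel force plates, one per foot,
each reporting a full 3-D force/moment wrench about its surface origin;
quasi-static vertical load split (`Fz = share * m * g`); horizontal
inertial shear split by share; a pinned limb with *exactly* constant CoP;
an elevated support for the mechanically constrained able-bodied mode (the
wrench is expressed at the plate, the foot contact sits `block_height`
above it, so the analysis must project CoPs onto the common "force
structure" plane); an 18-marker reduced body whose rigid small-angle
mapping gives each marker a horizontal excursion proportional to its
height; per-subject parameter jitter (truncated normal / log-normal, see
`make_cohort()`).

Not emulated: multi-segment (hip-strategy) kinematics — every marker moves
in exact height proportion, so the kinematic inverted-pendulum correlation
is near +1 *by construction* (≈ 0.98 with default marker noise, exactly 1
without). A green kinematic test therefore establishes that the analysis
chain is correct, **not** that human bodies are rigid pendulums; human
values (≈ 0.7–0.9) reflect genuine multi-segment motion that this
generator does not produce. Also absent: prosthetic-foot viscoelasticity,
intermittent control, vertical CoM dynamics (second-order in quiet
stance), plate noise and calibration error.

## 4. Numerical choices

* **Integration**: fixed-step semi-implicit Euler at
  `fs * internal_oversample` (1000 Hz default), decimated by plain
  subsampling to 100 Hz. All stochastic inputs are band-limited well below
  the decimated Nyquist, so no anti-alias stage is needed. The delay is an
  integer number of internal steps; during the first `delay` seconds the
  delayed state is held at the initial condition.
* **Ground truth** stores the *realized* total CoP (after within-foot
  clamping and jitter), so the pendulum relation
  `acc = (g/h)(x - u)` holds to machine precision on the stored series,
  and the wrench → per-limb CoP → combined CoP chain reconstructs the
  stored total to < 1e-9 m by construction.
* **CoP from a wrench**: the unique point on a horizontal plane where the
  wrench's horizontal moment components vanish —
  `x = -My/Fz`, `y = Mx/Fz`, and on a plane `d` higher
  `x' = x + d*Fx/Fz`, `y' = y + d*Fy/Fz`. Every formula is derived from
  that single zero-moment contract (and is cross-checked against a
  brute-force two-dimensional search). Samples with `|Fz|` below 10 N are
  masked invalid: CoP is numerically meaningless near zero load.
* **Filtering**: zero-phase (forward–backward) Butterworth, order 4 per
  pass, with odd-reflection end padding; 10 Hz for markers and plate
  signals, 5 Hz before double differentiation. Differentiation uses
  central differences with one-sided second-order endpoint stencils.
  Filter start-up transients occupy roughly the first/last second; the
  acceptance regression of acceleration on (CoM − CoP) discards those
  samples, a standard practice.
* **Combination**: the global CoP is the per-sample load-weighted mean of
  per-limb CoPs *expressed at the same reference height* (mismatched
  heights are a hard error, since silently combining across planes is a
  classic mistake with elevated apparatus). An unloaded limb (sub-threshold
  `Fz`) contributes zero weight; if both are unloaded the sample is masked.
* **Degenerate inputs** (zero-variance series, all-equal marker heights,
  pure-translation marker sets) raise errors instead of yielding NaN:
  silent NaNs would corrupt group means downstream.
* **Aggregation**: correlations are averaged on the Fisher-z scale
  (`z = atanh(r)`), with t-based 95% CIs across subjects (k − 1 df) and
  back-transformation by `tanh`. The variance-stabilizing transform is the
  only standard "log transformation" whose inverse returns
  "back-transformed correlation coefficients" in [−1, 1]; a plain
  logarithm is undefined for the negative correlations that dominate the
  kinetic table. Default aggregation is two-stage — trial z's averaged
  within subject first, then across subjects — because group tables report
  means over subjects; single-stage pooling is available
  (`summary_table(..., two_stage = FALSE)`), as the pooling order is not
  standardized in the field. `|r| = 1` inputs are clamped to `1 - 1e-9`
  with a warning.

## 5. Design decisions that were genuinely open

* **Noise bandwidth (5 Hz).** An early candidate was a 1 Hz cutoff. That
  produces narrowband sway in which position and acceleration are almost
  perfectly coherent, and then *any* fixed-CoP limb shows
  `corr(p - x, acc) ≈ +0.7`: for a stationary process this correlation
  equals `var(dx/dt) / (sd(x) sd(acc))`, and a narrow band forces it
  toward 1. Human standing shows small per-limb values, which requires
  acceleration content well above the position band. The exploratory noise
  therefore spans the full 0–5 Hz band that the analysis chain itself
  retains (its pre-differentiation low-pass sits at 5 Hz).
* **Controller gain (1.06).** Gains well above 1 make the simulated CoP
  excursion roughly double the CoM excursion; human quiet-stance
  recordings put that ratio near 1.1–1.5. The default was chosen to land
  the ratio at ≈ 1.3; the per-limb correlation values reported by the
  acceptance suite were measured only after this choice was fixed.
* **Load/unload in ML.** A within-foot ML mechanism (each foot steering
  its own CoP sideways) could also stabilize ML, but it would produce
  strongly negative per-limb ML correlations — the opposite of what is
  observed. The share-based mechanism is the one consistent with near-zero
  per-limb and large negative total ML correlations.
* **"Total linear movement"** of a marker is implemented as the 1-D path
  length `sum(|diff|)` per direction; peak-to-peak range is available via
  `movement = "range"`. Path length is the stricter statistic (a marker
  that oscillates accumulates movement even with zero net excursion).
* **Height projection policy.** Per-limb CoPs are projected to a common
  plane only when the recording declares a support height different from
  a plate's surface height; for flush standers the projection is the
  identity and is skipped.
* **Pin device representation.** The constraint device is *only* a
  per-limb CoP held constant at the pin axis; device mass and inertia are
  neglected (no published values exist, and in quiet stance their
  contribution is second order).
* **Seeding.** One master seed; per-trial seeds by the documented counter
  scheme `master + 1000*subject + 100*condition + trial`, all below
  2^31. Identical configuration and seed reproduce trials bit for bit.
* **Falls and re-recording.** The pin geometry gives the stander limited
  total CoP authority (worst under FB, where symmetric weight-bearing
  shifts load onto the immobile pin); a rare noise burst can push the CoM
  past the recoverable boundary, after which no admissible CoP restores it
  — the stander falls and `simulate_trial()` errors out naming the gains.
  Protective gain stiffening was rejected: at physiological feedback
  delays, effective proportional gains above ≈ 1.4 are themselves
  unstable. Instead, subject noise draws are clipped to the quiet-stance
  regime (`[0.5, 1.25] ×` the base `noise_sd`), gain/delay jitter is kept
  inside a stability-margin-verified box (kd ∈ [0.25, 0.45] s, delay ∈
  [0.10, 0.20] s, kp ∈ [1.04, 1.12]), and `make_cohort()` re-records a
  fallen trial with a derived seed (up to five attempts, retry counts in
  the manifest) — the same protocol a laboratory follows when a
  quiet-stance trial fails.

## 6. Known limitations

The cohort is a *stand-in*: its correlation signature reproduces the
qualitative pattern expected of pin-constrained standing (strongly
negative controller-limb and total correlations, near-zero pinned-limb
and per-limb ML correlations), but the numeric values depend on free
noise parameters that cannot be anchored to published sway magnitudes,
and no claim is made that they reproduce any specific human dataset. The
g/h regression recovery degrades from < 0.1% (noiseless) to ≈ 14% with
default noise — an errors-in-variables attenuation from measurement noise
in the regressor, which is informative in itself about what such
regressions can recover from real recordings. C3D ingestion is not
provided; recordings enter through the documented CSV + JSON format.
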