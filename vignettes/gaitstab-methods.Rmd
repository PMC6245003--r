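---
title: "Gait stability from treadmill perturbation experiments: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gait stability from treadmill perturbation experiments: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitstab)
```

## The problem

Gait stability — the ability to keep walking despite perturbations — is
commonly assessed on instrumented dual-belt treadmills that can translate
the walking surface sideways, accelerate or decelerate one belt, or deliver
sensory disturbances, each triggered at a specific gait event. `gaitstab`
implements the analysis chain for such experiments: marker filtering,
heel-strike detection, spatio-temporal step parameters, margins of
stability, a per-perturbation summary statistic (6S), and local dynamic
stability of unperturbed walking. Because raw motion-capture recordings of
this kind are rarely shareable, the package also contains a synthetic
treadmill-walking generator that reproduces the protocol's six perturbation
types with known ground truth, so that every formula in the pipeline can be
verified end to end.

## Kinematic conventions

All positions are lab-frame meters with X medio-lateral (positive to the
participant's right), Y anterior-posterior (positive in the progression
direction), and Z up. Sampling is 100 Hz by default. Belt speeds are
positive when the surface moves backward under the foot. These axis
conventions are internal to the package; recordings imported from other
systems must be rotated into them.

## Preprocessing

Marker data are low-pass filtered with a second-order Butterworth filter at
6 Hz applied forward and backward (`lowpass_filter()`). The bidirectional
pass makes the filter zero-phase — symmetric peaks keep their sample — and
squares the magnitude response, so the gain at the cutoff is exactly 0.5.
End transients are suppressed by odd (reflect-and-negate) extension of
`3 * ceiling(fs/fc)` samples at each end, which keeps short trials usable.

Heel strikes are the local maxima of the anterior-posterior heel-to-pelvis
excursion (`detect_heel_strikes()`): at foot contact the heel is maximally
forward relative to the body. Peak picking uses a minimum separation of
0.35 s (about 0.65 of a typical 0.55 s step time) and a minimum prominence
of 1 cm; both are engineering choices, configurable, and deliberately loose
relative to adult treadmill gait. Events from the two feet are merged into
a strictly alternating sequence, dropping the less prominent event of any
same-side pair. Events are reported at the peak sample itself; at 100 Hz
that gives ±5 ms resolution, adequate for step-level outcomes, so no
sub-sample interpolation is attempted.

## Step parameters and margins of stability

A step runs between consecutive heel strikes of opposite feet and is
labelled by the terminating side. Step time, length and width are the
elapsed time, AP distance and absolute ML distance between the two heel
markers, both evaluated at the instant of the later heel strike
(`spatiotemporal()`). The same-instant convention matters on a treadmill:
the between-event lab-frame displacement of a single heel is dominated by
belt motion and would not measure the step.

Stability is quantified by the margin of stability (MoS): the signed
distance from the extrapolated centre of mass,

\[ \mathrm{XCoM} = \mathrm{CoM} + \frac{v_\mathrm{CoM}}{\omega_0}, \qquad
   \omega_0 = \sqrt{g / l}, \]

to the border of the base of support, evaluated at each heel strike with
the striking (leading) foot defining the border: the lateral malleolus
marker laterally, the heel marker backward. The pendulum length *l* is 1.34
times the time-averaged height of the two greater-trochanter markers, and
*g* is fixed at 9.81 m/s². Signs are chosen so that negative values mean
instability: `mos_ml` is positive when the malleolus lies lateral to the
XCoM (with the lateral direction defined by the leading side), `mos_ap` is
positive when the heel lands behind the XCoM.

Two aspects of the MoS computation are genuinely open choices and are
exposed as options:

* **CoM-velocity frame.** The default adds the stance-side belt speed to
  the AP CoM velocity (`frame = "belt"`). On a treadmill the lab-frame AP
  CoM velocity averages near zero, which would make the AP MoS
  systematically negative and contradict the ~0.17 m margins typical of
  steady walking; the belt frame restores the overground interpretation.
  `frame = "lab"` is available for overground-style data.
* **Evaluation instant.** One MoS pair per step, at the leading-foot heel
  strike — the conventional instant for per-step stability series.

`filter = TRUE` (the default) applies the 6 Hz marker filter before
measurement. On noise-free data the filter is unnecessary and introduces a
small constant flattening bias (a few millimetres) at the sharp heel-strike
reversal of the heel trajectory; because the bias is identical at every
strike it cancels exactly in all baseline-relative quantities. Validation
against analytic ground truth at millimetre tolerances is therefore run
with `filter = FALSE`, while noisy data use the full default chain.

## Baseline and the 6S perturbation response

Baseline values of each gait parameter are means and SDs over 100
consecutive dominant and 100 consecutive non-dominant steps
(`baseline_summary()`), after a 5-stride warm-up skip. Perturbations are
triggered at non-dominant heel strikes; the six post-perturbation steps are
labelled 1D, 2ND, …, 6ND (the first always lands on the dominant side) and
the six preceding steps provide the PD/NPD pre-perturbation means
(`extract_peri_window()`). The total perturbation response per parameter is

\[ 6S = \sum_{i=1}^{2} \sum_{j=1}^{3}
   \left| B(i) - P\bigl(i + (j-1) \cdot 2\bigr) \right|, \]

the L1 norm of the side-matched deviations of the six post steps from their
side's baseline mean (`six_s()`). It deliberately ignores the time course:
a large deviation with fast recovery and a small deviation with slow
recovery can score alike. 6S is computed per repetition and averaged over
the last three of the four repetitions per perturbation type
(`average_repetitions()`); the first exposure is excluded as a startle.
Averaging derived 6S values rather than raw steps is a design choice; the
two orders coincide when deviations keep a consistent sign.

## Local dynamic stability

Local dynamic stability of unperturbed walking is the maximum finite-time
divergence exponent of trunk velocity (`lds()`), estimated
Rosenstein-style: the velocity series spanning 100 strides is resampled to
10,000 samples by cubic-spline interpolation of the whole segment
(total-duration normalization, which fixes the average stride to 100
samples while preserving stride-to-stride timing variability), delay-embedded
with dimension 5 and delay 10 samples, and for every state the Euclidean
nearest neighbour at temporal separation beyond a Theiler window of half a
stride is tracked; λ is the least-squares slope of the mean log-separation
curve over 0–0.5 stride, rescaled to per-stride units. The embedding and
fit-window values are standard practice for this measure in gait, not
facts of any particular dataset; they are configurable in `lds_config()`.
Lower λ means more stable gait. The nearest-neighbour search is O(N²) and
implemented in C++; ties resolve to the smallest index so results are
bit-reproducible. Exactly recurrent trajectories are handled by flooring
separations at 10⁻³⁰⁰ before the logarithm, which turns a perfectly
periodic signal into a flat curve with slope ≈ 0 rather than an error.

## The synthetic generator

`make_gait_trial()` produces a *kinematic template* of treadmill walking:
no forces, no balance control, just trajectories engineered so that every
quantity the pipeline measures has a closed-form ground truth.

* Heel strikes alternate every `step_time` (default 0.55 s). During stance
  a heel tracks its belt backward; a short smooth velocity blend (50 ms,
  C²-continuous) follows foot contact. During swing the heel follows a
  quintic that lands at the programmed position and time. The swing's end
  acceleration is matched to the mean curvature of the contact blend, which
  makes the heel-to-pelvis excursion peak locally symmetric at the strike —
  so the zero-phase filter does not displace the detected event, and
  detection recovers programmed strikes to the exact sample on noiseless
  data.
* The contact blend advances the heel slightly relative to pure belt
  tracking, so the template walks marginally faster than the belt; the
  resulting constant drift speed is solved in closed form and fed into the
  CoM model, keeping every per-step quantity stationary at baseline. The
  drift (~0.06 m/s at defaults) is a template artifact, not physiology.
* The CoM sways medio-laterally at stride frequency (amplitude 2 cm),
  oscillates vertically twice per stride, and leads the landing heel by a
  configurable AP offset (`heel_lead`, default 0.29 m) chosen to give
  baseline AP margins near 0.18 m. Defaults (1.2 m/s, 0.55 s, 0.68 m,
  0.12 m) correspond to comfortable adult treadmill walking.
* Trunk and marker noise are optional white Gaussian perturbations; they
  are the generator's only stochastic component and are driven entirely by
  the seed.

Perturbations are injected during generation. The sway profile is a
trapezoidal-velocity translation — the only simple family that satisfies
the protocol's three printed constraints (5 cm, ~0.7 s, 2.04 m/s² peak)
simultaneously — added to every ML coordinate and the platform channel.
Belt perturbations rewrite the non-dominant belt channel with minimum-jerk
ramps (peak acceleration `1.875·Δv/T`, which reproduces the printed
2.43–5.13 m/s² range across comfortable speeds of 0.86–1.82 m/s) and carry
the stance foot with the modified belt — which by itself produces the
forward (deceleration) or backward (acceleration) landing shifts and the
corresponding AP MoS deficits, with no scripting needed. Sensory
perturbations only log an event. Platform excursion is checked against the
±15 cm hardware bound; repeated sways schedule a slow return-to-centre ramp
after each post-perturbation window so four repetitions fit the bound.

Scripted recovery responses are data (`response_script()`): per post step a
timing, AP-placement and ML-placement deviation. Inside the
six-step window scripted deviations are applied exactly; externally induced
offsets (e.g. the belt-carried progression offset) relax by a factor 0.5
per step, emulating recovery, and after the window all accumulated offsets
relax the same way so the gait returns to baseline well before the next
repetition. `mos_targets` converts desired MoS deviations into placements
analytically, compensating the platform-velocity and belt-speed
contributions to the XCoM at the projected strike times. The default
scripts per perturbation type are shaped to the qualitative recovery
patterns reported for such protocols (narrow first step then recovery for
contralateral sway, backward instability at 2ND for deceleration, fast
recovery for acceleration, nothing for sensory) and produce the expected
ordering of 6S across types; their exact values are template choices, not
measurements.

What the generator does **not** emulate: kinetic consistency (no ground
reaction forces), active balance control and CoM responses to perturbations
(the CoM trajectory is prescribed, so MoS changes arise from foot placement
and XCoM velocity terms only), natural stride-to-stride variability beyond
white marker noise, and soft-tissue or marker-occlusion artifacts. Passing
round-trip tests therefore demonstrates that the pipeline measures what it
claims to measure, not that it has been validated on human data.

## Numerical choices and degenerate inputs

* Time base: samples are 1-based in R; the TSV event sidecar stores 0-based
  sample indices (the sample index, not the time column, is authoritative).
* `find_peaks()` prunes peaks greedily from the tallest; plateau maxima
  report their first sample.
* Central differences are used for all velocities (exact on linear data;
  one-sided at the ends).
* Windows are rejected, with specific error classes, when the trigger is
  more than 3 samples from a heel strike, lands on the dominant side,
  lacks six steps on either flank, or overlaps another event's window.
* Baseline computation errors out (rather than silently shrinking) when
  fewer than 100 steps per side are available; the count is configurable.
* Problem sizes in the test-suite and acceptance runs (60–130 s trials,
  100-stride LDS windows, 1000-case oracle sweeps) were chosen so the whole
  validation completes in a few minutes on a single core while still
  exercising the full 100-step baseline and 100-stride LDS conditions.

## Known limitations

* C3D import is not implemented; trials enter through the TSV dialect.
* The pipeline targets dual-belt treadmill protocols; overground data
  would need `frame = "lab"` and a different step-length convention.
* Group-level statistics (mixed-model ANOVAs etc.) are intentionally out of
  scope; `write_results()` exports tidy tables for external tools.
* LDS magnitudes depend on the embedding settings and on the character of
  the variability in the signal; values from the synthetic generator are
  order-of-magnitude realistic (≈1 per stride at 5 mm trunk noise) but are
  not calibrated against any cohort.
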