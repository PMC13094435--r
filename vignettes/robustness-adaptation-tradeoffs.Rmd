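---
title: "Robustness margins and plan-adaptation frequency in scanned proton therapy: the models behind adaptrt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robustness margins and plan-adaptation frequency in scanned proton therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question the package addresses

Intensity-modulated proton therapy (IMPT) plans for head-and-neck cancer
are made robust against delivery errors by optimizing the worst case over
a set of error scenarios: rigid setup shifts of a few millimetres (the
setup-robustness setting, SR) and systematic proton-range errors of a few
percent (the range-robustness setting, RR, reflecting the CT-to-stopping-
power calibration uncertainty). Larger settings produce wider dose
shoulders around the targets; this protects coverage when the anatomy
changes during the 6-7 week course, but it also irradiates more normal
tissue. Clinics that monitor patients with weekly repeat CTs (rCTs) and
re-evaluate the plan robustly on each of them face a quantitative
question: *if the robustness settings are reduced, how much organ-at-risk
(OAR) dose and complication probability (NTCP) is saved, and how many
additional plan adaptations are triggered?*

`adaptrt` implements that analysis as a fully synthetic, reproducible
simulation: phantom cohorts with progressive anatomical change stand in
for patients, a simplified analytic pencil-beam engine stands in for the
clinical dose engine, and every downstream step — robust optimization,
margin-reduced re-planning, weekly 28-scenario evaluation, course
accumulation, failure-rate statistics, NTCP conversion — is implemented
as in the clinical workflow it emulates.

## The synthetic cohort

Each patient is a cylindrical neck phantom (default 48^3 voxels at 3 mm)
with ellipsoidal structures: a primary CTV (prescribed 70 Gy(RBE)) inside
a prophylactic CTV (54.25 Gy(RBE)), both parotid and submandibular
glands, the three pharyngeal constrictor muscles, oral cavity and
cricopharyngeal muscle, all inside a water-equivalent external contour
(stopping-power ratio 1.0; air 0.001 outside). Patient-to-patient
variation jitters structure centers (SD 1.5 mm) and radii (SD 4%).

Weekly anatomy change has two components:

* **Progressive radial shrinkage** about the cranio-caudal axis — the
  dominant clinical effect of weight loss is a slimming neck, which
  shortens the proton path. The per-patient weekly volume-loss rate is
  drawn from a normal distribution truncated to [0, 0.05] (mean 0.015,
  SD 0.01 per week) and compounds over weeks, so external and parotid
  volumes scale as (1 - rate)^week exactly (up to voxelization). The
  whole grid content is scaled by one radial map, so the stopping-power
  grid, the targets and the OARs stay mutually consistent and the
  parotids translate medially as the neck shrinks.
* **Rigid per-rCT positioning offsets** (SD 1 mm along the beam axis,
  3 mm in the two lateral directions) — a weekly rCT captures the
  patient's position of the day as well as the anatomy, and rCT-based
  robust evaluation cannot separate the two. Without this component an
  axis-aligned-beam engine would make the setup-robustness setting
  dosimetrically inert, because a rigid shift along a beam's own axis
  does not change any water-equivalent depth.

The drift magnitudes are free parameters of the generator: the clinical
cohort they emulate is not publicly characterized. They were chosen once
so that the reference plan's weekly failure rate is moderate (roughly
the 10-20% range seen clinically) and margin-reduced plans fail more
often, and are not adjusted per analysis. Fractionation follows the
clinical patterns (35 fractions; 5/week over 7 weeks conventionally,
6/week over 6 weeks accelerated, chemoradiation delivered
conventionally) with weekly rCTs from week 1, 5-7 per patient with the
clinical frequency (3 patients with 5, 21 with 6, 2 with 7 per 26).

What the generator deliberately does **not** emulate: CT texture and
tissue heterogeneity (bone, air cavities), deformable (non-affine)
anatomy change, tumor regression distinct from the global shrinkage,
intra-fraction motion, and imaging/registration uncertainty. Passing
tests therefore demonstrate the *mechanics* of the analysis — scenario
dosimetry, trigger statistics, trade-off extraction — under a controlled
anatomy-change model, not clinical dosimetric realism.

## The dose engine

Dose is computed analytically: each scanned spot deposits
`MU x B(WED; R) x G(lateral distance)`, where `B` is a single-peaked
Bragg curve — a Gaussian peak (SD 5 mm) at the nominal range on a
smoothly terminated entrance plateau (35% of the peak Gaussian) — `WED`
the water-equivalent depth integrated along the (axis-parallel) ray, and
`G` a depth-independent lateral Gaussian (SD 7 mm). Two lateral opposed
beams along the x axis are used; axis-parallel rays make the WED a
per-column cumulative sum and keep the engine exactly linear in MU.

Error scenarios are realized physically rather than by dose-grid
approximation: a range error of r% multiplies the stopping-power grid by
(1 + r/100); a setup shift resamples the patient into the beam frame
(trilinear), computes dose there, and resamples the dose back. In a
homogeneous phantom this reproduces the textbook equivalence between
shifting the patient and counter-translating the dose grid, including
shifts along the beam axis.

The engine's contracts — and the only properties the analysis relies
on — are: a single peak with the distal 80% falloff within 3 mm of the
nominal range in water, exact MU linearity, and correct first-order
range-error and setup-error semantics. It makes no claim of clinical
dosimetric fidelity: there is no Monte Carlo transport, no nuclear halo,
no heterogeneity-driven lateral scattering, and a constant RBE factor of
1.1 is folded into the prescriptions.

## Robust planning and margin-reduced plans

The reference plan (RR 3%, SR 3 mm) minimizes the composite worst case
over the 14-scenario optimization set (7 isocenter shifts: none and
+/-SR along each axis, crossed with +/-RR) of a weighted-quadratic
objective: one-sided underdose penalties at the prescriptions for both
CTVs, an overdose penalty at 105% of the primary prescription, overdose
and mean-dose penalties on a conformity shell around the prophylactic
CTV, and mean-dose penalties on the OARs (cropped to outside the
prophylactic CTV, where sparing would otherwise fight coverage). The
coverage reference doses carry a small headroom (100.7% and 103% of the
prescriptions) so that the voxel-wise envelope criteria pass with margin
on the planning anatomy. Coverage weights dominate the sparing weights
by orders of magnitude — the voxel-wise minimum criterion requires
*every* scenario's shifted edge shell to be covered, and a softer
balance trades individual shells away.

Because dose is linear in MU, per-scenario influence matrices (objective
voxels x spots, sparsified at a 1e-4 relative threshold) make each
scenario objective piecewise quadratic. The worst case is minimized with
L-BFGS-B under non-negativity bounds on a log-sum-exp smoothed maximum
with a two-stage temperature schedule (10% then 0.5% of the initial
worst case); the true worst case is tracked at every iterate and the
best one returned, so the reported trace is non-increasing by
construction. Initialization is uniform MU scaled so the median primary-
CTV dose equals the prescription; ties among equally-worst scenarios
resolve to the lowest scenario index. Objective voxels are sub-sampled
deterministically (1200 per CTV, 1500 on the shell, 250 per OAR);
the final plans are always re-evaluated with the full engine on the
full grid, so the sub-sampling only affects the optimizer's view.

Margin-reduced plans (2%/3mm, 1%/3mm, 3%/2mm, 3%/1mm) are derived by
dose mimicking: keep the spot geometry, match the reference nominal dose
on the target voxels (quadratic, weight 1000), penalize one-sided
overdose relative to the reference outside the targets (weight 500 —
this pins the near-degenerate direction that swaps dose between the two
entrance channels), re-apply the planning objective's sparing terms to
the nominal dose, and add the worst-case target-underdose penalty over
the *reduced* scenario set, reusing the planning objective's coverage
references and weights scaled by 0.4, starting from the reference MU. A
literal all-voxel two-sided match would simply reproduce the reference
plan — including its wide robust shoulders — and no margin reduction
would ever spare an OAR; restricting the two-sided match to the targets
and letting the sparing terms act where the reduced scenario set permits
reproduces the intended behaviour: target dose preserved, shoulders
trimmed in proportion to the margin reduction. Because the reference
optimization stops at a finite iteration budget in a nearly flat valley,
the mimic may recover residual OAR sparing even under the reference
scenario set; the fixed-point property is exact on small fully converged
problems, while at production sizes the guaranteed invariants are that
target D98 is preserved, acceptance flags keep passing, and the OAR
burden never increases.

## Weekly evaluation, accumulation and statistics

Each plan is evaluated on each rCT over 28 scenarios: 14 shift
directions (6 axis-aligned, 8 body diagonals, all normalized to the full
setup magnitude — the "magnitude" convention; a per-component option
exists) crossed with a symmetric +/- range magnitude. For weekly rCT
evaluation the setup magnitude is 1 mm and the range magnitude is
patient-specific: 1.5 x (1.2% + 0.5 mm / R_mean), with R_mean the plan's
MU-weighted mean spot range. Voxel-wise minimum and maximum envelopes
are taken over the 28 doses; the nominal dose is computed separately
(it is not one of the 28). Coverage passes when the envelope D98% is at
least 94% of prescription for each CTV and the primary D2% stays at or
below 110%; all boundary comparisons are inclusive. D_v% is frozen as
the descending-sort linear interpolation at position 1 + (n-1)v/100
(the type-7 quantile at probability 1 - v/100), verified against a
hand-computed oracle before freezing.

Fractions map to the rCT nearest in time (ties toward the earlier one),
and nominal, voxel-wise-minimum and voxel-wise-maximum doses accumulate
with weight 1/n_fractions on the shared grid — synthetic snapshots need
no registration, which is exact but also means the accumulated metrics
use the planning-CT structures. Failure rates over all rCT evaluations
(the evaluation, not the patient, is the unit, matching the clinical
bookkeeping) get Wilson 95% intervals; each reduced setting is compared
to the reference with a pooled two-proportion z-test, Holm-adjusted
within each criterion's four-comparison family; equivalence uses two
one-sided unpooled z-tests with a 10 percentage-point margin at
alpha = 0.05. Trade-off slopes are ordinary least squares of failure
rate, mean composite-OAR dose (the union of all OARs) and NTCP against
RR (SR fixed) and SR (RR fixed). The normal quantile for 95% is used at
full double precision, not 1.96.

NTCP is logistic in mean OAR doses (identity or square-root transforms)
plus categorical clinical factors; total NTCP is the sum over the three
endpoints (moderate-to-severe xerostomia, dysphagia grade >= 2,
tube-feeding dependence), the convention consistent with additive
per-endpoint slopes. The shipped coefficient file is clearly labelled
synthetic: the validated clinical coefficients live in a national
protocol and are configuration inputs, never invented constants. The
model-based selection rule on photon-minus-proton NTCP differences
(10/15/5 percentage points, inclusive) is provided for completeness.

## Numerical choices and degenerate inputs

* Scenario sets are de-duplicated, so degenerate magnitudes collapse
  (SR = 0 gives 2 evaluation scenarios, RR = 0 gives 7 optimization
  scenarios); the null scenario belongs to the optimization set only.
* The engine skips grid columns whose lateral fluence is below 1e-4 of
  the layer maximum; the threshold is relative, so exact MU linearity
  survives. Scenario doses for DVH metrics are restricted to columns
  within 15 mm of the prophylactic-target projection.
* The plateau tail of the Bragg curve short-circuits the normal CDF
  beyond 7 sigma (error < 2e-12).
* Anatomy resampling uses nearest-neighbour for masks (binary-preserving,
  subset-preserving) and linear interpolation for stopping power; a
  structure shrinking to zero voxels raises a degenerate-anatomy error.
* A cohort seed spawns per-patient substreams, so growing the cohort
  never changes earlier patients.

## Problem sizes

The shipped analyses run at 48^3 resolution with two beams of roughly
150 spots each. Unit tests use 32^3 phantoms and hand-made plans; the
cohort-level directional analysis and the acceptance script use 8
patients with 6 weekly rCTs each and all five robustness settings —
about 240 plan evaluations of 29 scenario doses each plus 40 plan
optimizations per run. These sizes were chosen as the smallest at which
the cohort-level trends are stable across seeds.

## Known limitations

* The primary D2% hot-spot criterion occasionally fails on drifted
  anatomy in this engine (the clinical benchmark reports essentially no
  D2 failures); the analytic SOBP's dose flatness under combined range
  error and anatomy change is cruder than a clinically optimized plan's.
* Failure rates for the prophylactic CTV run higher than the primary's
  by a larger factor than in the clinical benchmark; the elective
  volume's edge sits closer to the phantom surface, where the shrinkage
  model acts most strongly.
* Repeated evaluations of one patient are treated as independent in the
  statistics, exactly as in the clinical bookkeeping being emulated;
  no clustering correction is applied.
* Accumulation sums per-fraction envelope doses (the conservative
  convention); the alternative — enveloping accumulated scenario
  courses — is intentionally not implemented.

## Running the full analysis

```{r}
library(adaptrt)
cfg <- pipeline_config(
  cohort_spec(8, n_rcts_distribution = c(`5` = 0, `6` = 8, `7` = 0),
              seed = 1)
)
res <- run_pipeline(cfg)
res$failure_table   # failure rate + Wilson CI per setting and criterion
res$comparisons     # z-tests vs reference, Holm-adjusted, TOST flags
res$slopes          # trade-off slopes vs RR and SR
cat(res$summary_text)
```

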