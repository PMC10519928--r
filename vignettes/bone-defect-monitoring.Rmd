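---
title: "Mechano-structural monitoring of critical-size bone defect regeneration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechano-structural monitoring of critical-size bone defect regeneration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boneheal)
```

## The monitoring problem

When a critical-size segmental defect in a weight-bearing bone is bridged by
a scaffold and stabilized with an instrumented external fixator, the state
of the regenerate cannot be observed directly. What *can* be measured in
vivo is (a) the peak ground reaction force (GRF) of the operated limb on a
walking platform, (b) the force flowing through the fixator's instrumented
connecting bars during the same stances, and (c) occasional CT scans with a
calibration phantom in the field of view. `boneheal` turns those three
measurement channels into the quantities clinicians and experimenters track:
the force carried by the callus, its apparent axial stiffness, the day the
callus overtakes the fixator as the main load path, and phantom-calibrated
morphometry (CSA, TV, BMD) normalized to the non-operated contralateral
limb.

## The spring-network force-partition model

The operated segment is modeled as an axial spring network. The fixator
(stiffness $K_f$, in N/mm) runs in parallel with the bone path, in which the
callus ($K_c$) sits in series with the proximal and distal cortical
fragments ($K_{b,p}$, $K_{b,d}$). The fragments combine into the equivalent
cortical stiffness

$$K_b = \frac{K_{b,p}\,K_{b,d}}{K_{b,p}+K_{b,d}},$$

always below the softer fragment. Fragment stiffnesses are estimated from
CT cross-sectional area profiles with an axial varying-section rod model,
$K = \left[\sum_z \Delta z / (E\,A(z))\right]^{-1}$, at a cortical modulus
of 21 GPa; bending of the fragments and of the fixator bars is deliberately
ignored, consistent with the axial network idealization.

During stance the internal force $F_i$ splits into the measured fixator
force $F_f$ and the callus force

$$F_c = F_i - F_f,$$

and the apparent callus stiffness is recovered as

$$K_c = K_f\,\frac{F_c\,K_b}{F_f\,K_b + F_c\,K_f}.$$

Two modeling caveats are worth stating plainly. First, the formula above is
implemented exactly in this algebraic form (plus sign in the denominator).
A textbook derivation of a parallel fixator against a series
callus-fragment chain, assuming a single common displacement across the
bridged segment, produces a minus sign instead; the kinematic assumption
behind the plus-sign form ("equivalent system displacement") is not
detailed anywhere we could resolve it from. We keep the published form and
make the simulator use its exact algebraic inverse, so the pipeline is
self-consistent: `forward_load_partition()` and `callus_stiffness()` are
verified to be mutual inverses to 1e-9 relative over a thousand random
parameter draws. The discrepancy between the two derivations is documented,
not resolved. Second, the model is only meaningful while $0 \le K_c < K_b$;
the partition function refuses stiffer-than-bone calluses.

The fixator load-share fraction under this model is

$$\lambda(K_c) = \frac{F_f}{F_i}
  = \frac{K_f\,(K_b-K_c)}{K_c K_b + K_f\,(K_b - K_c)},$$

strictly decreasing from $\lambda(0)=1$, with $\lambda = 1/2$ exactly at
the *crossover stiffness* $K_c^\times = K_f K_b/(K_b+K_f)$ (about
590 N/mm for $K_f = 593$ N/mm and $K_b \approx 114$ kN/mm). This links the
mechanical crossover day — the day the callus out-loads the fixator — to a
specific point on the stiffness trajectory, and the package's crossover
detector is tested against exactly that prediction.

## Internal-force calibration

$F_i$ is not measurable in vivo. Following the constant-ratio convention
for instrumented fixators, `calibrate_force_ratio()` estimates
$r = F_i/\mathrm{GRF}$ during the early window (default days 7–14
post-surgery, half-open), when no mineralized bridge exists and therefore
$F_i \approx F_f$: the ratio is the mean of per-tread $F_f/\mathrm{GRF}$
peak pairs in the window. The ratio is then held fixed for the whole
follow-up, so every later day yields $F_i = r\cdot\mathrm{GRF}$,
$F_c = F_i - F_f$, and a $K_c$ estimate.

Two guards apply to the stiffness series:

* stances with $F_c \le 0$ (no bridging yet, or sensor noise) give no
  numeric estimate;
* once the fixator is essentially unloaded — $F_f$ below 2% of $F_i$ by
  default (`censor_frac`) — the estimate lies outside the load cells'
  calibrated range and is reported as **right-censored**, not as a number.
  Reports render these entries as `>range`.

## Gait processing

Stance detection on the platform trace uses a threshold of 5% of body
weight with a 1% body-weight hysteresis band and a 0.2 s minimum duration;
a stance clipped by the end of a recording is kept once the duration
criterion is already met. Per stance, the GRF and fixator-force peaks are
the maxima over the *same* interval (peak-synchronized pairing; the pairing
rule is a package convention). Daily summaries average at least eight
treads where available — days with fewer treads are kept but flagged
incomplete rather than dropped, which small cohorts need. GRF is expressed
as a percentage of the healthy reference, 42.5% of body weight for this
ovine metatarsal model (midpoint of the published 42–43% range), so
$\mathrm{GRF}\% = 100\,\overline{\mathrm{GRF}}/(0.425\,m\,g)$.

## CT morphometry

Calibration maps Hounsfield units to mineral density by ordinary least
squares of the known phantom-insert densities (defaults
0–0.8 g HA/cm³ across six inserts) on the per-insert mean HU. Manual
segmentation is replaced by calibrated-density thresholding (default
0.15 g HA/cm³ — the published work thresholded interactively and states no
number) within a region of interest that excludes the phantom inserts plus
a 2 mm margin; pin-tract woven bone is handled the same way, by ROI
exclusion, not automatically.

Per z-slice (slice centers, spans half-open in mm), CSA is the voxel count
times the in-plane pixel area; TV integrates CSA over the defect span plus
10 mm margins on each side by the rectangle rule; BMD is the mean mapped
density over masked voxels, with empty slices reported as missing rather
than zero, and the summary BMD taken as the voxel-wise mean over the defect
span (mask-only averaging — whether the published summaries averaged over
the mask or the full cross-section is not stated). Contralateral
normalization divides by the control limb's values over its 15 mm
defect-equivalent span; note the asymmetry that the control TV carries no
margins (the 2.17 cm³ reference equals 144.79 mm² × 15 mm), while the
treated TV includes them.

## The synthetic cohort generator

No raw data accompany the monitored study, so verification runs against a
forward simulator whose defaults *are* the study conditions: eight animals,
60 kg, $K_f = 593$ N/mm, per-animal fragment stiffnesses recycled from the
published reference table, and anchor-based trajectories interpolated with
a monotone shape-preserving (Fritsch–Carlson) spline — chosen because the
printed milestones (crossover near day 30, 650 N/mm at day 40, 7 kN/mm at
day 60) are inconsistent with any single exponential. Extrapolation holds
end values.

Default anchors:

| quantity | anchors |
|---|---|
| $K_c$ (N/mm) | (0, 0), (13, 0), (14, 60), (30, $K_f K_b/(K_b{+}K_f)$), (40, 650), (60, 7000), (70, 15000), (180, $\min(5\times10^4, 0.8 K_b)$) |
| GRF (% healthy) | (7, 42), (120, 70.5), (180, 93) |
| BMD (g HA/cm³) | (0, 0.45), (65, 0.79), (123, 0.81), (365, 1.1875) |
| CSA (% control) | (0, 100), (200, 229.49), (365, 156.13) |

Three of these rows deserve a word. The latency zeros at days 0–13 encode
the absence of any mineralized bridge during the first two post-surgical
weeks; they are what makes the constant-ratio calibration exact in its own
window (with $K_c > 0$ there, the calibration would be biased low by
construction and the whole stiffness series would inherit the bias — the
day-14 anchor of 60 N/mm alone already gives $\lambda = 0.91$). The day-30
anchor is placed *at the per-animal crossover stiffness*, so the designed
crossover day is 30 for every animal regardless of its $K_b$. The day-180
anchor continues consolidation beyond the last printed milestone; without
it the fixator would keep carrying ~3% of a growing internal force forever
and never formally stabilize inside the 5% band.

Per-animal anchor jitter is available but defaults to zero: inter-animal
variation enters through the fragment stiffnesses (which span
70–166 kN/mm) and through sensor noise, which keeps the designed
milestones interpretable. Gait noise is multiplicative Gaussian with
$\sigma = 5\%$ applied independently per tread to each sensed channel
(platform and load cells are separate instruments). The internal-force
ratio defaults to $r_\text{true} = 1$; the published per-animal ratios are
unreported, and the pipeline is required to recover whatever value the
generator used. Stances are half-sine pulses (odd sample count, so the
peak is attained exactly); the pipeline only consumes peaks, so any pulse
with a unique maximum would do. All animals share the monitoring schedule
(2–3 sessions/week through day 70, weekly to day 180, biweekly through the
year); sacrifice days schedule CT time-points only.

CT volumes are digital metatarsi on a 0.3 mm isotropic grid (the published
resolution): a cortical annulus of exactly the contralateral reference
area (144.79 mm², outer radius 8.4 mm) at 1.25 g HA/cm³, interrupted by
the 15 mm defect span, which holds a solid callus cylinder whose area
follows the CSA% trajectory and whose voxel densities are Gaussian around
the BMD trajectory ($\sigma = 0.05$ g HA/cm³) — overgrowth is modeled by
radius scaling of a convex section; lobed real-callus shapes are out of
scope. Six phantom cylinders at known densities run alongside; densities
convert to HU through a configured true line (0.001 g HA/cm³ per HU) plus
2 HU additive noise. The sidecar JSON carries the design truth, so every
pipeline output is scorable.

What the generator does *not* emulate: muscle-force redistribution and gait
compensation (the constant ratio is exactly true by construction),
metal-streak artifacts (optional outlier handling is by ROI exclusion, not
correction), partial-volume blur at tissue boundaries (voxels are assigned
by center-in-shape), irregular callus lobes, and any biological coupling
between the mechanical and imaging channels beyond their common time axis.
Passing tests therefore demonstrate the *estimators* are correct and
well-conditioned under realistic noise, not that the model assumptions hold
in any particular animal.

## Time-course statistics

The crossover day interpolates the sign change of $F_c - F_f$ linearly
between sampling days (daily sampling is coarse against a milestone quoted
as "an average of 30 days", so whole-day reporting would quantize the
estimate). Stabilization is the first sampled day from which the fixator
force stays inside a band (default 5% of the series-mean internal force)
through the end of the record, with at least 14 days of in-band follow-up
observed. Trend fitting offers three families — exponential saturation
$A - B e^{-t/\tau}$, logistic, and a monotone spline (isotonic regression
followed by monotone Hermite interpolation) — because the monitored study
announces fitted trend functions without specifying them.

The gait–mineralization link is a single ordinary least squares regression
of body-weight-normalized GRF on BMD at matched time-points (nearest gait
session within 14 days of each CT), flagged significant only when
$R^2 > 0.5$ **and** $p < 0.005$, with no multiplicity adjustment (one
regression; flag, don't adjust). On the default synthetic cohort this
comes out at $R^2 \approx 0.52$, $p \approx 0.012$ with $n = 11$ CT
time-points: the variance-explained half of the criterion is met, the
p-value half is not, because the synthetic design holds GRF at its last
anchored value while BMD keeps rising through the remodeling year. We
report that plainly rather than reshaping the generator: the joint
criterion is a property of the original cohort's data, not of the
estimator.

## Numerical choices and degenerate inputs

* Units are N, mm, N/mm, days throughout; kN/mm appears only at ingest
  (reference table) and in reports.
* Windows and spans are half-open: calibration days $[7, 14)$, defect and
  TV spans $[a, b)$ in mm at slice centers; voxel indices are 0-based in
  the external convention.
* Monotone interpolation: `stats::splinefun(method = "monoH.FC")`;
  duplicate anchor days are an error, end values clamp.
* Nonlinear fits use Levenberg–Marquardt (`minpack.lm`) with tight
  convergence (`ftol = 1e-14`); constant data short-circuit the
  exponential family to its asymptote ($B = 0$) instead of failing on a
  singular gradient.
* Degenerate designs error loudly: fewer than two phantom densities,
  identical phantom mean HU, zero-variance BMD in the regression,
  non-positive stiffnesses or areas (with the offending slice index).
* An empty segmentation over the defect span yields a missing BMD with a
  warning, never zero.
* Problem sizes in the test suite are chosen for sharp oracles at small
  cost: unit-test volumes use 0.5–1 mm voxels on ~10–40 mm grids, the
  acceptance-grade CT checks use the full 0.3 mm grid, and the cohort
  recovery checks simulate 8 animals × 33 monitoring days × 8 treads.

## Known limitations

* The plus/minus sign question in the stiffness estimator is inherited,
  not adjudicated; all self-consistency claims are relative to the printed
  form.
* The constant-ratio assumption transfers any real change in muscle
  recruitment directly into the $F_i$ estimate; the simulator cannot
  surface that error mode.
* Fragment stiffnesses derived from CT geometry ignore bending and shear;
  the 21 GPa modulus is a convention.
* Contralateral matching is by distance along the bone axis from a
  configured landmark; there is no image registration.
* CT streak artifacts are excluded, not corrected; the published study
  faced the same limitation and scanned sparsely for that reason.
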