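---
title: "Kinetic quantification of dynamic PET with dynpet: models, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic quantification of dynamic PET with dynpet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynpet)
```

## The problem

Static uptake measures (%ID/g, SUV) of a receptor-targeted PET tracer
confound the quantity of interest — specific binding to the receptor —
with perfusion, vascular permeability, plasma clearance and
non-specific accumulation. Dynamic imaging with kinetic modeling
separates these: the tissue time-activity curve (TAC) is interpreted
through a compartment model driven by the arterial plasma
concentration, and macro-parameters such as the total distribution
volume $V_T$ and the binding potential $Bp_{ND}$ isolate the specific
component. `dynpet` implements this quantification chain for
60-minute small-animal studies of reversible tracers (the motivating
case is integrin-targeted RGD peptides in tumor-bearing mice),
together with a simulator that generates data with known ground truth
so every estimator in the package can be validated end to end.

## The kinetic model

Tissue kinetics follow the reversible two-tissue compartment model.
With $C_p$ the plasma concentration, $C_t$ the free/non-specifically
bound and $C_m$ the specifically bound tissue concentration:

$$\frac{dC_t}{dt} = K_1 C_p - (k_2 + k_3) C_t + k_4 C_m, \qquad
  \frac{dC_m}{dt} = k_3 C_t - k_4 C_m,$$

where $K_1$ (ml/g/min) is plasma-to-tissue transport, $k_2$ (1/min)
efflux, $k_3$ (1/min) the association and $k_4$ (1/min) the
dissociation rate. The measurable signal adds a fractional blood
volume $v_B$:

$$ROI(t) = v_B\,C_p(t) + (1 - v_B)\,(C_t(t) + C_m(t)).$$

A reference region devoid of specific binding (muscle) is the
one-tissue special case $k_3 = k_4 = 0$. The macro-parameters are

$$V_{ND} = \frac{K_1}{k_2}, \quad
  V_S = \frac{K_1 k_3}{k_2 k_4}, \quad
  V_T = V_{ND} + V_S = \frac{K_1}{k_2}\Big(1 + \frac{k_3}{k_4}\Big),
  \quad Bp_{ND} = \frac{k_3}{k_4}.$$

`solve_2tcm()` evaluates the model by closed-form convolution: the
impulse response is a sum of two exponentials
$e^{-\alpha_{1,2} t}$ with
$\alpha_{1,2} = \tfrac12\big(S \mp \sqrt{S^2 - 4 k_2 k_4}\big)$,
$S = k_2 + k_3 + k_4$, and for exponential-sum inputs each convolution
term has an analytic primitive. The solution is exact to machine
precision (the test suite checks agreement with a fourth-order ODE
integrator to $10^{-6}$ relative on random parameter sets). Sampled
inputs (e.g. an image-derived blood curve) use an exact
piecewise-linear convolution evaluated with a C-level recursive
filter; the only approximation is the linear interpolation of the
input between samples. Near-cancelling exponentials
($\lambda + \alpha \to 0$) are handled by series expansion, and the
measure-zero double-root configuration of the impulse response is
guarded by a $10^{-7}$ relative floor on the root separation.

## The input function

No arterial samples exist in the emulated design; the blood curve is
image-derived from the left ventricle. The simulator therefore uses a
Feng-type parametric input,

$$C_p(t) = (A_1 t - A_2 - A_3)e^{\lambda_1 t} + A_2 e^{\lambda_2 t}
  + A_3 e^{\lambda_3 t},$$

a linear rise rolling into three decaying exponentials with
$C_p(0)=0$. The default coefficients (`feng_input()`) were fixed once
to represent a ~3.7 MBq tail-vein bolus of a rapidly cleared
hydrophilic peptide dimer:

* peak before 1 min (≈ 0.28 min), as these tracers show in heart and
  liver curves;
* peak amplitude ≈ 3.3 MBq/ml — the dose transiting roughly 1.5 ml of
  mouse blood;
* terminal plasma half-life ≈ 7 min (fast renal washout);
* overall amplitude calibrated so the default high-binding tumor
  reaches ≈ 3.5 %ID/g at 60 min, the static uptake reported for this
  class of tracer.

Two caveats are deliberate. First, the reported *muscle* uptake
(≈ 0.5 %ID/g with $V_T \approx 0.5$) would require a slower 60-min
plasma tail than the fast-washout description supports; a single
exponential family cannot match both, and we match the tumor uptake
and the washout pattern. Second, the finite-time bias of
reference-region Logan analysis is sensitive to the plasma tail: a
slow tail delays tissue-plasma equilibration and inflates the bias,
which is worth remembering when judging simulation results against
real data.

## From curves to frames, and noise

PET frames measure time-averaged activity. `frame_average()`
integrates the model curve over each frame of the 30-frame schedule
(10×30 s, 5×60 s, 5×120 s, 10×240 s; `schedule_60min_mouse()`) on a
fine sub-grid, so it is exact for curves linear within a frame.
`add_noise()` applies the standard count-statistics heuristic:
independent zero-mean Gaussian noise with per-frame standard
deviation $\sigma_j = c\,\sqrt{\max(v_j,0)/\Delta t_j}$, reproducible
under an explicit seed. At the calibrated activity scale, `scale = 1`
gives ≈ 4–5% noise on late tumor frames at the voxel level — the
regime in which published parametric maps visibly operate. The noise
model ignores reconstruction correlations, attenuation, scatter and
partial-volume effects, so passing tests demonstrate estimator
correctness under the stated model, not robustness to scanner
physics.

## Logan graphical analysis

`logan_plasma()` regresses
$y(t) = \int_0^t ROI/ROI(t)$ on $x(t) = \int_0^t C_p/ROI(t)$ at frame
midpoints past $t^*$; after tissue-plasma equilibration the plot is
linear with slope $V_T$. `logan_reference()` replaces plasma with the
muscle curve; its slope is the distribution volume ratio, and
$Bp_{ND} = DVR - 1$. `decompose_vt()` splits $V_T$ into
$V_{ND} = V_T/(1+Bp)$ and $V_S = V_T\,Bp/(1+Bp)$, identities that
hold exactly by construction.

Numerical choices:

* **Running integrals.** Frame values are time-averages, so
  `value × duration` is the *exact* integral over the frame.
  `cumulative_integral()` therefore uses
  `cumsum(value*duration) - value*duration/2`, exact at frame
  boundaries however sharply the bolus peaks inside the early frames
  (a midpoint-trapezoid rule loses 3–5% of the input integral at
  every late midpoint, which propagates directly into the $V_T$
  slope). The first-frame term is the triangle from $(0,0)$ to the
  first midpoint.
* **$t^*$.** Fixed at 30 min by default — the equilibration time of
  these tracers, leaving 7 fitted midpoints. `select_tstar()` offers
  an automated alternative: the earliest midpoint after which every
  point sits within 10% of the line refitted on the remaining points.
* **Degenerate points.** Midpoints with non-positive tissue values
  (possible under noise) are dropped and counted; at least 3 usable
  points are required.
* **Reference form.** The simplified late-time reference equation,
  without the reference-efflux ($k_2'$) correction term, is used. The
  muscle region equilibrates quickly ($1/k_2' \approx 5.6$ min), so
  past 30 min the omission costs little from the reference side; the
  remaining finite-time bias (≈ 4% downward on $Bp_{ND}$ for the
  default tumor, whose slowest eigenvalue is
  $1/\alpha_1 \approx 34$ min) comes from the *target* tissue and
  would not be removed by the $k_2'$ term either. This bias, its
  direction (underestimation, worsening with noise), and its
  stacking with blood-volume contamination (below) are properties of
  the method, documented rather than corrected — bias-reduced
  multilinear variants are out of scope.

The micro-parameter fit (`fit_2tcm_nls()`) is a bounded
Levenberg–Marquardt least-squares against the frame-averaged model
prediction, weighted by frame duration, with a Latin-hypercube
multistart (8 log-space starts, fixed seed, bounds
$[10^{-4}, 5]$ in natural units). The objective has genuine local
minima (a basin with $k_4$ at its upper bound approximates the data
poorly but attracts roughly half of random starts), which is why the
multistart is not optional. The reproducible macro-parameter path
remains the Logan fits; the NLS exists as an oracle and for
micro-parameter exploration.

## VOIs, uptake units and the image-derived input

`threshold_mask()` implements the 30%-of-maximum voxel screen against
tumor heterogeneity: seed-VOI voxels at or above 30% of the seed
maximum on a reference frame (default: the last frame) are kept.
`extract_tac()` is the per-frame masked mean. `to_percent_id_per_g()`
converts kBq/ml to %ID/g via the injected dose (default ~3.7 MBq) and
unit tissue density. `image_derived_input()` delineates the left
ventricle on the second frame (the 0.5-min image, when the blood pool
is hottest), freezes that mask, and applies it to all frames; the
30% screen is applied to the input VOI as well by default (symmetric
with tissue VOIs; set `fraction = 0` to disable). No partial-volume
or spill-over correction is applied — on real mouse data this is a
known source of input underestimation at late times, and the
simulator's clean blood pool does not exercise it.

## Digital phantoms and parametric maps

`build_phantom()` fills labeled spheres/boxes on an isotropic grid
(default 64³ at 0.8 mm) with the frame-averaged curves of each
region's kinetics — tumor, kidney, liver, muscle and a left-ventricle
blood pool carrying $C_p$ — plus optional per-voxel noise, and
returns aligned ground-truth $V_T$ and $Bp_{ND}$ maps computed from
the generating kinetics. The default region kinetics were chosen so
their macro-parameters match the values reported for this tracer
class (tumor $V_T \approx 2.6$, $Bp_{ND} = 3.75$; kidney
$V_T = 4.10$; muscle $V_T \approx 0.56$; liver $V_T = 1.25$), with
$v_B = 0.05$ in tissue (0.02 in muscle).

`map_vt()` and `map_bp()` run the same Logan transforms voxel-wise,
vectorized across the body mask (default: last-frame value ≥ 1% of
image maximum), with identical arithmetic to the region-level fits —
a uniform noise-free region reproduces the region fit to $10^{-9}$.
Failed voxels (< 3 usable points or degenerate regression) are
flagged and filled with 0; $Bp$ maps are clamped below at −1. A full
64³ phantom maps in a few seconds.

One accuracy note: with ground truth defined as $k_3/k_4$ from the
generating kinetics, the voxel-level $Bp_{ND}$ estimate on the
default phantom sits ≈ 10% low. This is the deterministic stack of
blood-volume contamination (the $v_B C_p$ term inflates both running
integrals; ≈ 6% at these $v_B$ values) and the reference-Logan
finite-time bias (≈ 4%); on a blood-free phantom the same machinery
recovers $Bp_{ND}$ within 4%. Real-data practice inherits the same
stack, which is one reason published $Bp$ values from graphical
analysis are conservative.

## Group statistics and the pipeline

`unpaired_ttest()` is the classic pooled-variance Student test (the
design's stated comparison; Welch available by flag), with explicit
handling of zero-variance degeneracies. No multiple-testing
correction is applied, matching the emulated design.
`summarize_groups()` produces the mean ± SD table per tracer, region
and parameter with p-values against the first group.
`run_pipeline()` chains simulation → VOI/TAC extraction → Logan
fits → decomposition → summary for a configurable multi-group study
(default: three tracer groups with $Bp_{ND}$ 3.75/3.39/3.09, four
subjects each), writing TAC CSVs, fit JSON records, optional maps and
a seed-stamped log; a given config + seed reproduces byte-identical
numbers. A thin command-line wrapper lives at
`inst/scripts/run-pipeline.R`.

## Problem sizes used in validation

The shipped tests validate at desk scale, chosen to keep the full
suite under a few minutes: 20-voxel-wide phantoms for voxel-level
identities, the full 64³ phantom for the parametric-map recovery
check, 500 noisy replicates for the Logan noise-bias property, 100
replicates for NLS bias, and 10,000 null replicates for the t-test
size. Simulation grids are 0.001 min for data generation and 0.01 min
inside the NLS objective.

## Known limitations

* The noise model is uncorrelated Gaussian; no reconstruction
  physics, attenuation, scatter, resolution blurring or motion.
* Whole blood is identified with plasma: no metabolite correction or
  plasma-fraction model.
* The reference Logan form omits the $k_2'$ term; estimates carry the
  documented downward finite-time bias.
* The image-derived input has no partial-volume/spill-over
  correction.
* Phantom geometry is simple spheres/boxes — no anatomical atlas.
* Activities are assumed decay-corrected by reconstruction.
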