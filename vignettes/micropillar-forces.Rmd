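---
title: "Measuring spheroid forces from 3D micropillar deflection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring spheroid forces from 3D micropillar deflection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pillarforce)
```

## The measurement principle

A multicellular spheroid growing inside a ring of slender elastic PDMS
micropillars pushes the pillars outward. Each pillar is a force transducer:
if the mechanics of a bent pillar are known, its measured deflection profile
can be inverted to the applied force. Spheroids bend these high-aspect-ratio
pillars by tens of micrometres, far beyond the regime where the tip
displacement alone determines the force, so the measurement uses the whole
3D deflection profile, imaged as a confocal z-stack of the dye-stained
pillar array.

The pipeline has three stages — reconstruct, model, invert — plus a
synthetic-imaging stage that exists so the other three can be validated end
to end with exact ground truth.

## The elastic forward model

Each pillar is a circular cantilever of diameter $d$, height $h$, clamped at
the base and free at the top, made of an elastomer with Young's modulus $E$
(2.6 MPa for the PDMS here, calibrated by uniaxial compression of a
macroscopic post cast from the same material: $E = \text{slope} \cdot H /
(\pi r^2)$ with slope $= F/\Delta L$). The spheroid contacts the upper span
$s$ of the pillar (175 µm of the 300 µm height, measured from the imprints
the pillars leave on the spheroid), and its push is idealized as a
horizontal line load of density $q = F/s$ on $[h-s,\, h]$.

The transverse displacement $w(z)$ solves the Euler–Bernoulli equation
$EI\, w'''' = q(z)$ with $I = \pi d^4/64$, $w(0) = w'(0) = 0$ (clamped base)
and $w''(h) = w'''(h) = 0$ (free top). `deflection_profile()` evaluates the
closed form; the profile is non-negative, non-decreasing in $z$, and exactly
linear in $F$ — the property the inversion exploits. Two classical limits
anchor it: $s = h$ gives the uniform-load tip deflection $qh^4/8EI$, and
$s \to 0$ the point-load $Fh^3/3EI$.

Pillar deflection is often modelled with a full 3D finite-element
discretization of the cylinder. At aspect ratios of 8–11, slender-beam
theory reproduces such a model to within a few percent, so this package
deliberately uses beam theory instead: it is closed-form, dependency-free and doubles as its own test
oracle. Two concessions to the 3D picture remain available:
`fe_beam_profile()` assembles a 1D cubic-Hermite finite-element beam
(exactly consistent nodal loads for the partial uniform load, clamped base)
whose Euler–Bernoulli variant is nodally exact and serves as a mutual
cross-check, and whose `shear_corrected = TRUE` variant adds Timoshenko
shear flexibility with $G = E/(2(1+\nu))$ and the circular shear factor
$\kappa = 6(1+\nu)/(7+6\nu)$ — a ~0.7 % tip effect for these pillars. We do
not claim equivalence with the near-incompressible 3D solid beyond that
order; large-deflection geometric nonlinearity and base compliance are out
of scope.

A numerical note: the assembled beam system mixes displacement and rotation
unknowns whose stiffness entries differ by powers of the element length, so
the solver equilibrates the matrix (rotation unknowns scaled by $1/L$)
before factorization; without this the system exceeds the double-precision
condition limit at fine meshes.

The spring constant reported on devices follows the tip point-load
convention $K = 3EI/h^3$, truncated to an integer in nN/µm:
`spring_constant_nN_per_um()` gives 8 (d = 28 µm) and 23 (d = 36 µm) from
8.72 and 23.82 nN/µm. The truncation is presentation only; all computation
keeps full precision, and the package works in strict SI internally
(metres, newtons, pascals), converting µm/nN only at the I/O boundary.

## 3D reconstruction of pillar deflection

`reconstruct_stack()` runs the three-step segmentation:

1. **Base segmentation** (`segment_base_slice()`): the first slice (the
   pillar bases, $z = 0$) is normalized and thresholded (Otsu); connected
   components above a quarter of the expected disk area are measured by
   intensity-weighted sub-pixel centroid and equivalent-area radius, and the
   expected number of highest-confidence detections is kept.
2. **Propagation** (`propagate_slice()`): on each subsequent slice, the
   previous detection defines a search window (half-width: search radius +
   pillar radius). The window is Otsu-thresholded with an absolute intensity
   floor (default 0.05 of the stack maximum) guarding against signal loss at
   depth; the component nearest the previous centre within the search radius
   is accepted. Failures are flagged invalid and tracking continues from the
   last valid slice. The default search radius of 7 µm
   ($3 \times z_{\text{step}} \times \tan 30^\circ$) bounds physically
   plausible inter-slice bending while excluding neighbouring pillars
   (ring spacing ≫ 7 µm).
3. **Skeleton smoothing** (`smooth_skeleton()`): an energy-weighted cubic
   smoothing spline per coordinate versus height. Invalid slices are
   excluded from the fit and receive interpolated values flagged as imputed;
   `df = 0` switches to exact cubic interpolation.

The per-slice **energy** is the normalized cross-correlation of the local
patch with an ideal disk template of the detected radius, clipped to
$[0, 1]$. This is a package-defined confidence index: it is 1 for a clean
disk and decreases monotonically with noise, which the test-suite verifies;
other definitions of a segmentation energy exist, and this one was chosen
because it is simple, bounded and directly testable.

The smoothing default `df = 8` (equivalent degrees of freedom over 75
slices) was chosen once so that a straight skeleton with 0.5 px centre noise
flattens below 0.2 px residual while a quartic bending curve is tracked
without visible bias; it is exposed as a parameter.

The scalar deflection $d_i$ of slice $i$ is the signed projection of the
smoothed centre displacement (relative to the base-slice centre) onto the
pillar's mean displacement direction. For the radially pushed pillars of a
growing spheroid this is the radial outward deflection; the signed
projection keeps non-radial deformations meaningful. $d_1 = 0$ by
construction. Apparent radius changes along $z$ (an optical artefact of deep
confocal imaging) are recorded per slice but not used to correct centres.

## Inversion: sweep, score, refine

`build_abacus()` precomputes the family of simulated deflection curves over
a force sweep — by default 0 to 1000 nN in 10 nN steps, 101 candidates.
Linearity means only the deflection per unit force is stored; candidate
curves are scalar multiples. `resample_curve()` re-discretizes the
simulated curve onto the experimental slice grid with a cubic spline
(exact at nodes, reproduces cubics, refuses extrapolation).

Each candidate is scored with three statistics
(`fit_metrics()`): $SS_{\text{res}} = \sum_i (d_i - v_i)^2$,
$R^2 = 1 - SS_{\text{res}}/SS_{\text{tot}}$ with
$SS_{\text{tot}} = \sum_i (d_i - \bar d)^2$, and
$M = \max_i |d_i - v_i|$. Since $SS_{\text{tot}}$ is fixed per profile, the
$SS_{\text{res}}$ argmin and the $R^2$ argmax coincide; on noiseless
model-generated profiles the $M$ argmin agrees too, and the tests assert
this three-way consistency. $R^2$/$SS_{\text{res}}$ is the primary
criterion; $M$ is reported as a diagnostic. Exact ties on the grid break
toward the smaller force (conservative). A constant detected profile has
$SS_{\text{tot}} = 0$ and is flagged degenerate rather than scored.

`estimate_force()` additionally returns the continuous least-squares force
$F_{\text{refined}} = \sum_i d_i u_i / \sum_i u_i^2$, exact under the linear
forward model — a refinement beyond the grid estimate, which is retained as
the sweep-faithful output. Fits use all valid slices from base to top (not
only the loaded span), matching how experimental deflection curves are
compared over the full pillar length; slices with failed detections are
excluded and their count reported.

## The synthetic scene: what it emulates, and what it does not

`synthetic_scene()` + `render_stack()` produce ground-truthed stacks whose
defaults mirror the experimental conditions: 12 pillars of 28 µm diameter
and 300 µm height on a 160 µm-radius ring (sized to seat a ~300 µm
spheroid with clearance), imaged as 75 slices at 4 µm steps, forces pushing
radially outward. Centrelines come from `deflection_profile()` — the
mechanics module is the single source of truth for the bending shape.

The optical model is deliberately idealized: hard cylinder cross-sections
drawn as anti-aliased disks, blurred by a Gaussian whose width grows
linearly from 1 µm at the base to 3 µm at the top (reproducing the
documented apparent-size difference between pillar bottom and top),
attenuated linearly to 70 % intensity at the top, with additive Gaussian
noise (σ = 0.02 of full scale; Poisson shot noise optional) and 16-bit
quantization. A fixed seed renders byte-identical stacks. The spheroid body
is not rendered, matching the pillar-channel analysis of the dye-stained
devices.

What passing the synthetic tests shows: the segmentation, tracking,
smoothing and inversion recover forces within ±20 nN under these
degradations, and accuracy degrades monotonically as noise and attenuation
grow. What it does not show: robustness to a real confocal PSF (asymmetric,
depth-dependent in shape, with scattering), to cells aggregating around
pillars, to debris or staining inhomogeneity, or to pillar shapes that
deviate from cylinders. Real-data use should treat the energy and the valid
mask as first-class outputs and inspect low-confidence pillars.

## Study-level statistics

`summarize_forces()` reports arithmetic means and sample SDs ($n-1$) per
device, day or stiffness group, excluding (but counting) degenerate
estimates. `force_rate()` fits an OLS slope of force versus time in nN/hr
(day $k$ maps to $24k$ hours from device loading; acquisition clock times
are not modelled). `compare_days()` is the classical pooled-variance
two-tailed Student's t test (Welch via a flag), with stars at 0.05, 0.001
and 0.0001 and no multiple-testing correction — comparisons are per-pair by
design, as is conventional for such figures. Pillar-within-device
correlation is not modelled (no mixed effects); both the pillar and the
device can serve as the unit of analysis, and `simulate_force_study()`
organizes synthetic draws into devices so both can be compared. The
simulator draws plain normal forces at prescribed per-day means and SDs; it
demonstrates the statistical machinery, not spheroid biology.

## Numerical choices and degenerate inputs

* Strict SI internally; µm/nN only at I/O boundaries (configs, CSVs,
  profile tables).
* Spline resampling is `stats::splinefun(method = "fmm")`; extrapolation is
  an error, never silent.
* Grid ties break toward the smaller force; degenerate profiles
  ($SS_{\text{tot}} = 0$, or a zero unit profile) yield flagged estimates
  with `NA` forces, never ±∞.
* Fewer than 4 valid slices makes a skeleton unusable (flagged, not
  smoothed); fewer than 2 valid slices is an error for force estimation.
* Detection-count shortfalls on the base slice are errors that report what
  was found; a pillar rendered out of the field of view is an error naming
  the pillar.
* Test problem sizes: the full-device integration test renders one
  12-pillar, 75-slice stack at 256×256 px; Monte-Carlo force recovery uses
  200 replicates of 75-slice profiles at 0.5 µm centre noise. Both chosen
  as the smallest sizes that exercise the documented claims.

## Known limitations

Forces are scalar per pillar (magnitude along the mean displacement
direction); no vector decomposition or load-distribution inference along
the contact zone. The beam model assumes small deflections and a rigid
base. Time-lapse stacks are processed independently — no tracking of
pillars across days. Uncertainty on a single pillar's force is not
propagated from image noise; the Monte-Carlo spread under stated noise is
the available guide.
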