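---
title: "Biventricular mechanics with bivmech: models, methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biventricular mechanics with bivmech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`bivmech` simulates quasi-static biventricular cardiac mechanics driven by
image-derived boundary data — cavity-volume traces, chamber pressures and
valve-annulus motion — and personalises the passive stiffness of the
myocardium from end-diastolic shape. This vignette explains the models, the
discretisation, the synthetic data generator, and every numerical choice a
user might reasonably want to question.

## Constitutive model

The myocardium is a nearly incompressible, transversely isotropic
hyperelastic solid. With deformation gradient $F$, $J=\det F$,
$C = F^TF$, $I_1 = \mathrm{tr}\,C$, $\bar I_1 = J^{-2/3} I_1$ and fibre
pseudo-invariant $I_f = C : (f_0 \otimes f_0)$, the first Piola–Kirchhoff
stress is split into passive, volumetric and active parts:

$$P_{p} = a_0\,e^{b_0(\bar I_1-3)} J^{-2/3}\Big(F - \tfrac{I_1}{3}F^{-T}\Big)
 + 2 a_f (I_f-1)_+\, e^{b_f (I_f-1)_+^2}\, f \otimes f_0,$$

$$P_{vol} = p\,J F^{-T}, \qquad
P_{act} = (\alpha_{lv}\phi + \alpha_{rv}(1-\phi))\,
  \tanh\!\big(2 (I_f - 0.8)_+\big) \Big(f\otimes f_0 + \tfrac13 F\Big),$$

with $f = F f_0$. This is the reduced Holzapfel–Ogden family: an isotropic
exponential ground substrate (scale $a_0$, kPa) plus a tension-only
exponential fibre reinforcement (scale $a_f$, kPa). The exponents
$b_0 = b_f = 5$ give a physiological end-diastolic pressure–volume
response and are not personalised. The label field $\phi$ is 1 in the LV
free wall *and the whole septum*, 0 in the RV free wall, so the two scalar
activations $\alpha_{lv}, \alpha_{rv}$ act chamber-wise. The active
cross-fibre term $\tfrac13 F$ represents myofibre dispersion and shares the
$\tanh$ length-dependence factor with the fibre term (the printed form is
ambiguous on this point; a single shared prefactor is the reading we
implement).

The hydrostatic pressure $p$ is an independent field tied to volume change
by the weak equation $K[(J-1) + k\,\ln J] - p = 0$ with bulk modulus
$K = 1000$ kPa. The coefficient $k$ of the logarithmic term is nowhere
defined in the source material; both $k=0$ and $k=1$ vanish at $J=1$ and
differ only in the effective bulk stiffening, so `k_log` is a configuration
value with default 1.

Each valve annulus carries a surface stress
$P^k_{valve} = c_1\big(e^{c_2 (I_f^k - 1)} - 1\big) f^k \otimes f_0^k$
along the circumferential ring tangent $f_0^k$, with $c_1 = 0.1$ kPa,
$c_2 = 0.5$ for all valves: a thin collagenous ring that resists annular
dilation.

**Numerical regularisation of the switches.** The positive parts
$(I_f-1)_+$ and $(I_f-0.8)_+$ are kinks in the stress. Newton iterations on
states straddling the kink cycle instead of converging. We therefore use a
C1 blend: exactly zero below the threshold, quadratic over a zone of width
$10^{-3}$ in the invariant, shifted linear above. The identical smoothing is
used in the energies, so stress–energy consistency is preserved to
round-off, and the tension-only semantics (exact zero for $I_f \le 1$) are
untouched. The perturbation to any stress value is below
$a_f \cdot 5\times10^{-4}$ kPa.

## Virtual-work formulation and discretisation

At each frame the displacement $u$, pressure $p$, activations, and one
3-vector multiplier $\lambda^k$ per valve satisfy the quasi-static
virtual-work balance containing: internal stresses and the pressure
equation; valve-annulus surface stresses; the follower pressure load
$P_k(t) JF^{-T}N$ on each endocardial surface; a scalar cavity-volume
constraint per chamber; and the valve ring constraints. Three solution
modes share one assembly:

* **diastolic** — activations are zero and the chamber pressures are the
  unknowns conjugate to the volume constraints (passive inflation);
* **active** — pressures are prescribed data and the activations are the
  Lagrange multipliers that make the model volumes follow the measured
  traces;
* **forward** — both pressures and activations prescribed, volumes free
  (used for twin experiments).

The truncated cavity volume is evaluated on the *open* endocardial surface
as $V = -\int_\Gamma \tfrac12 [(I-n\otimes n)(X+u)]\cdot JF^{-T}N\,d\Gamma$:
the projector along the truncation-plane normal makes the missing planar
cap contribute exactly zero, which is also why the formula is invariant
under rigid translation. The per-facet below-plane indicator is applied at
reference facet centroids.

The valve (green-term) constraint is interpreted as the *area-averaged*
ring displacement equalling the measured centroid displacement — three
scalars per valve with a constant 3-vector multiplier — matching the
"average position enforced by Lagrange multipliers" description; pointwise
enforcement is deliberately not used. The pulmonary trace is the exact
arithmetic mean of the mitral, aortic and tricuspid traces. The epicardium
is traction-free.

Discretisation is continuous linear (P1) for both $u$ and $p$ on
tetrahedra, as in the source formulation. Single-point quadrature is exact
for the constant-gradient volume terms; the pressure mass matrix is the
exact P1 matrix; surface terms use facet-centroid quadrature; the finite
bulk modulus acts as a perturbed-Lagrangian stabilisation of the P1/P1
pair. Consistent tangents are built from central finite differences of the
analytic element/facet residuals (verified against directional finite
differences of the assembled residual to ~1e-9), with analytic columns for
the activation and pressure multipliers and the linear constraint blocks.

**Nonlinear solver.** Newton with sparse LU (Matrix), full steps, and three
safeguards that the floppy thin-walled RV free wall makes necessary: a
trust-region-like cap on the displacement increment (default 2 mm;
temporarily raisable), backtracking only on element inversion/non-finite or
order-of-magnitude residual growth, and LU-factor reuse while progress is
good. Between data states an adaptive continuation marches a blend
parameter, doubling the step after easy solves and halving it on failure;
cycle drivers warm-start each frame with a residual-checked linear
predictor. Cycles start at the frame with the lowest LV pressure — the
easiest state to reach quasi-statically from the unloaded reference.
Tolerance is an absolute residual infinity norm of 1e-7 (force rows in
kPa mm²; volume rows in mL; ring rows in mm), which leaves converged
volume errors around 1e-12 mL and ring errors around 1e-14 mm.

**Admissibility.** Prescribed pressures must be at least the passive
pressure at the prescribed volume, otherwise the activation multiplier
turns negative (an outward push) and the thin RV wall buckles numerically.
`check_admissibility()` runs this pre-flight test explicitly; it is not
folded into `solve_active_cycle()` because it costs a full passive solve
per checked frame. In the intended workflow — personalise first, so the
material matches the group end-diastolic pressure — the synthetic traces
are admissible by construction.

## Rule-based fibre field

A Laplace–Dirichlet transmural coordinate $d$ (0 on the epicardium, 1 on
the endocardium) and an apex-to-base harmonic field define a local
orthonormal wall basis (transmural, longitudinal, circumferential). For the
septum, whose fibres follow the LV rule across its whole thickness, the
RV-facing septal surface takes the epicardial value and the RV free-wall
endocardium the endocardial value, so one solve covers both walls. Helix
angles vary linearly across the wall: −60° to +60° (epi to endo) in the LV
and septum, −25° to +90° in the RV free wall. The fibre vector is the
circumferential direction rotated about the transmural axis; sheet and
sheet-normal complete a right-handed orthonormal triple.

The valve-ring fibre angles measured ex vivo are not available, so within a
configurable 5 mm band below the base the helix angle blends linearly to a
per-valve ring angle whose default (0°, i.e. ring-tangent alignment)
reproduces the intent of ring-aligned collagen; both the band and the
angles are configurable. P1 maximum-principle overshoots of the harmonic
fields on near-degenerate elements are clipped to [0, 1].

## Synthetic study conditions

The generator provides everything the pipeline needs without patient data.
The idealized biventricle is two intersecting truncated ellipsoid walls at
the end-systolic reference state, truncated by the basal plane; boundary
nodes are snapped onto the exact surfaces of a Kuhn (6-tet) lattice mesh,
with a local sliver-repair pass (near-degenerate tets either re-positioned
or removed) because element quality bounds the conditioning of everything
downstream. Presets follow the cohort group means: LV end-systolic cavity
volumes of about 71/98/48 mL and wall thicknesses of 8.4/9.1/11.5 mm for
the healthy/dilated/hypertrophic groups; the RV is a laterally offset
thin-walled ellipsoid tuned to the group RV volumes with a 5 mm wall — at
the thick end of the physiological range so that coarse lattices resolve
it. The four valve "rings" are the posterior/anterior halves of each
basal wall annulus (mitral/aortic on the LV, tricuspid/pulmonary on the
RV): a reproducible idealization of annuli that in reality come from
template fitting.

Traces are piecewise-cubic Hermite templates with zero slope at the
end-diastole, end-systole and diastasis knots, warped segment-by-segment to
the five cycle events and anchored to the group pressures (end-diastolic
1.1/2.7/3.2 kPa, end-systolic 16.0/16.0/24.4 kPa; RV end-systolic
4.0/4.0/6.1 kPa). The diastolic plateau sits at half the end-diastolic
pressure and the diastasis volume at 70% of the filling excursion so that,
after personalisation, prescribed pressures stay above the passive filling
curve (the admissibility requirement above). The RV end-diastolic pressure
defaults to 0.4 of the LV value until personalisation supplies its own.
What the generator does *not* emulate: MR acquisition physics, fitting
residuals of real anatomy (outflow tracts, trabeculation, atria), beat-to-
beat variability, or measurement noise on volumes and pressures — passing
tests demonstrate correctness of the machinery on clean geometry, not
robustness to real-data artefacts.

The label-image/landmark generator draws the same ellipsoid geometry into
short-axis class maps and synthesises ten valve-landmark tracks, then
injects recorded corruptions (small false components, interior holes,
landmark jumps, missing frames with the [0,0] sentinel) under a single
seed, so QC operations can be verified corruption-by-corruption.

## Label and landmark quality control

Cleaning follows the stated rules: per class, 4-connected components with
*fewer than* 50 pixels are removed (a 50-pixel component is kept — the
threshold is read strictly); interior holes are filled with the enclosing
class, resolved by majority over the hole's perimeter when several classes
touch it. Connectivity is not specified in the source; 4-connectivity is
the conservative choice and is configurable.

Landmark repair flags a frame as invalid when it carries the [0,0] sentinel
or lies farther from the landmark's temporal median position than
max(3 × 1.4826 × MAD, 10 mm) — a robust, parameter-light rule covering
both described failure modes. Flagged frames are linearly interpolated with
periodic extension, then each coordinate is low-pass filtered by periodic
Fourier truncation above 10 cycles per cardiac cycle: zero-phase (no bias
on valve-timing extraction) with exactly unit DC gain. The cutoff is not
specified in the source and is configurable.

Slice rejection rasterises short- and long-axis masks onto their 3-D
intersection line and computes the dice overlap of the samples; slices
below 0.5 are rejected. Contours are traced from the cleaned masks
(LV endocardium, LV epicardium, RV septum/free wall split at the
myocardium junctions, insertion points), the RV epicardium is generated by
offsetting the free-wall contour 3 mm along its outward normal, and each
contour point carries its slice's dice score as weight (a linear mapping;
rejected slices get weight zero).

## Passive personalisation

Only the anisotropy ratio $\gamma = a_0/a_f$ is identifiable from
volume-driven displacements, because both scales enter the law linearly and
therefore scale linearly with pressure. The sweep inflates the ventricles
to the end-diastolic volumes with $a_0^{sim} = a_f^{sim} = 1$ kPa, then
holds the volumes while $a_0^{sim} = \gamma$ descends over a 19-point grid
from 1.0 to 0.1 (step 0.05, warm-started); at each $\gamma$ the objective
is the RMS point-to-surface distance from the end-diastolic contours
(LV epicardium, LV endocardium and RV septum only — the RV free wall is
omitted) to the deformed surface, with exact point-to-triangle distances.
The objective is evaluated at end-diastole only. Absolute stiffnesses
follow from the assigned group end-diastolic pressure:
$a_f = a_f^{sim}\,EDP^g_{lv}/p^{ED}_{lv}$, $a_0=\gamma a_f$, and the RV
end-diastolic pressure is recovered through the same scale.

Group pressures come from a shipped literature table of invasive
measurements, combined by sample-size-weighted means; the healthy 8/120
mmHg values are textbook constants, not table entries. The weighted mean of
the dilated-cardiomyopathy end-diastolic rows is 19.3 mmHg, not the 20.2
mmHg quoted alongside the same table; the rule as stated does not reproduce
that number, so the package documents the discrepancy and the synthetic
presets use the published 2.7 kPa.

## Reporting

Clinical metrics are standard: EDV/ESV from trace extrema, EF =
100(EDV−ESV)/EDV, and wall thickness as the distance from each endocardial
facet centroid to the nearest epicardial point, with distances above three
times the median discarded as basal-ring artefacts (the measurement is
nowhere defined in the source; this nearest-point variant is documented and
configurable). Note that on coarse staircase lattices the nearest-point
definition underestimates thin walls (the 5 mm RV wall reads ~3.5 mm at a
6 mm lattice); LV values and all relative comparisons are robust to this.
The 17-segment AHA division splits the apex-to-base axis into an apical cap
(default 15% of the axis; segment 17, dropped in the 16-segment variant),
apical, mid and basal bands with 4/6/6 circumferential sectors measured
from the anterior LV/RV insertion; sector angles are rounded to 1e-6
degrees so exact ties stay stable under rigid rotations. Fibre stretch is
reported relative to the end-diastolic frame; active fibre stress is the
fibre-fibre component of the active Cauchy stress,
$\sigma_f = J^{-1}(P_{act}F^T):(\hat f\otimes\hat f)$ — a definition choice
recorded here because the source plots the quantity without defining it.

## Problem sizes and verification scope

The test-suite sizes are deliberate package choices: constitutive oracles
run on 100 random deformation states; the thick-sphere inflation oracle
uses a structured icosphere-layer shell of ~3.8k tets (the voxel-lattice
shell is measurably overstiff at this resolution, so the structured
generator exists precisely for oracle comparisons); cavity-volume checks
use a ~2.9k-tet biventricle; the cycle/twin experiments run a 10-frame
personalised healthy cycle at a 6 mm lattice (~2.9k tets) and γ-recovery
twins at a 7 mm lattice. Twin experiments share their discretisation
between forward and inverse runs, so they verify the constraint and
recovery machinery, not discretisation accuracy; the sphere oracle and the
patch test carry that burden.

## Known limitations

* P1 tetrahedra are overstiff at coarse resolution; quantitative stress
  values on the test meshes are resolution-limited even though constraint
  satisfaction and twin recovery are exact.
* The idealized RV is a single ellipsoidal crescent without an outflow
  tract; its basal "rings" are annulus halves, not anatomical annuli.
* Inertia, pericardial boundary conditions, circulation coupling and
  regionally varying activation are out of scope by design.
* The template-fitting stage that produces patient meshes in the original
  workflow is bypassed: contours feed the personalisation objective
  directly.
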