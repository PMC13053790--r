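---
title: "Modeling post-infarction left-ventricular mechanics and collagen histology quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling post-infarction left-ventricular mechanics and collagen histology quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its science: the continuum
model, the discretization, the in-silico experiments, the image-analysis
statistics, and the design decisions taken where the problem was
genuinely open. Nothing here states an empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## The mechanical model

### Passive material

Myocardium is modeled as a transversely isotropic hyperelastic solid.
With `E` the Green–Lagrange strain expressed in a fiber-aligned frame
(axis 1 = fiber, axis 2 = cross-fiber in the wall plane, axis 3 =
transmural), the strain energy is exponential:

$$W = \frac{C}{2}\left(e^Q - 1\right),\qquad
Q = b_1 E_{11}^2 + b_2\!\left(E_{22}^2+E_{33}^2+E_{23}^2+E_{32}^2\right)
  + b_3\!\left(E_{12}^2+E_{21}^2+E_{13}^2+E_{31}^2\right).$$

The second Piola–Kirchhoff stress is
$S = \partial W/\partial E - pJC^{-1}$ and the Cauchy stress
$\sigma = J^{-1} F S F^{\mathsf T}$. Four canonical parameter sets are
bundled (`material_params()`, also as YAML in `inst/extdata/`): healthy
myocardium, infarct scar, patch-implanted scar, and the epicardial patch
itself, all sharing C = 359 Pa and density 1.37e3 kg/m³ and differing in
$(b_1,b_2,b_3)$. The scar sets were originally obtained by fitting the
uniaxial force development at a 0.2 fiber-strain point to 35% (infarct)
and 49% (implanted scar) of the healthy response.

**Strain-measure reading.** Whether "0.2 strain" is engineering strain
($\lambda = 1.2$) or Green strain ($\lambda = \sqrt{1.4}$) is not fixed
by the parameter tables alone. Evaluating the incompressible uniaxial
response of the bundled sets shows the Green reading reproduces the
35%/49% fitting targets substantially better (about 31%/45% vs 26%/40%
for the engineering reading), so Green strain is the package default;
`strain_measure = "engineering"` switches the convention everywhere it
matters (`force_reduction_ratio()`, `fit_reduced_params()`).

**Refitting utility.** The printed scar sets are not a uniform scaling
of the healthy set, and a one-number target cannot determine three
coefficients; `fit_reduced_params()` therefore uses a single global
scale on $(b_1,b_2,b_3)$ — a well-posed one-parameter objective — and
is intended for constructing variants, not for re-deriving the bundled
sets (which are taken verbatim).

**Patch equivalence.** The patch set is in-plane isotropic
($b_1 = b_2$), stated to be fitted so its uniaxial force–length curve
matches the infarct region. Under the incompressible uniaxial protocol
implemented here the two printed sets agree only within a factor of
about 2.6 over $\lambda \in [1, 1.25]$ (the original fitting protocol
is not recorded); the property test asserts this bounded agreement
rather than a tight equivalence.

### Active tension

Contraction is an added stress in the fiber frame,
$\mathrm{diag}(T_0,\,0.4\,T_0,\,0.4\,T_0)$, applied as a second
Piola–Kirchhoff stress. $T_0$ is sarcomere-length dependent:

$$l = l_R\sqrt{2E_{11}+1},\qquad
ECa_{50} = \frac{(Ca_0)_{max}}{\sqrt{e^{B(l-l_0)}-1}},\qquad
T_0 = T_{max}\,\frac{Ca_0^2}{Ca_0^2 + ECa_{50}^2}\; C_t .$$

Defaults: $T_{max}$ = 135.7 kPa, $l_0$ = 1.58 µm, $l_R$ = 1.91 µm, B =
4.75 /µm, $Ca_0 = (Ca_0)_{max}$ = 4.35 µmol/l. For $l \le l_0$ the
tension is clamped to zero ($l_0$ is by definition the no-tension
length; the algebraic form used is continuous at the clamp). Only the
two static limits of the activation time course are used: $C_t = 0$ at
end-diastole and $C_t = 1$ (maximal calcium) at end-systole; the
time-course constants (m, b and the phase formula) are stored but
unused — the study design is two static equilibria, not a twitch.

**Which regions contract.** Scar tissue contains no cardiomyocytes, so
the infarct zone develops no active tension in the diseased models (and
an actively contracting scar would make the infarcted model's ejection
fraction exceed the control's, the opposite of the modeled physiology).
The epicardial patch is likewise passive by default (graft maturity at
the modeled time point is unknown). Both choices are switchable
(`active_iz`, `patch_active`).

## Geometry and discretization

The reference ventricle is a truncated prolate spheroid: endocardial
semi-axes $a$ (equatorial) and $c$ (long axis), uniform wall thickness
added outward, cut by a flat basal plane at $z = c\,(2f-1)$ where $f$
is the fraction of the long axis retained. The wall is divided into
three transmural layers with helical fiber angles (+60°, 0°, −60°) from
endocardium to epicardium, each fiber lying in the local
circumferential–longitudinal tangent plane (0° = circumferential).
Which sign sits endocardially is not anatomically fixed here; the
default (+60° endo) is switchable through `fiber_angles`.

Hexahedral trilinear elements are laid out in circumferential rings and
longitudinal strips; the apex strip uses collapsed (wedge) hexahedra
sharing the apical node of each transmural level. Ring nodes are placed
at a slightly enlarged radius (factor
$\sqrt{(2\pi/n_c)/\sin(2\pi/n_c)}$) so the inscribed polygon has the
area of the circle it replaces; with uniform polar-angle ring spacing
this keeps the discrete cavity volume within 1% of the closed-form
truncated-spheroid volume at the default 20 × 12 × 3 resolution
(~10³ hexahedra with the patch layer — the scale at which all study
protocols are run; finer meshes change volumes by under a percent but
multiply run time).

**Regions.** The infarct zone (IZ) is a contiguous anterior sector
selected as the centred index window whose reference wall-area fraction
is closest to 13.4%; its wall is thinned to 1/3 of the original
thickness by moving each transmural node line toward its endocardial
anchor (the cavity is preserved; the epicardial surface moves inward).
The patch window (22.8% of wall area, constrained to contain the IZ)
defines the border zone BZ = window − IZ; everything else is the remote
zone RZ. The control model carries the same sector labels without
thinning or material change, so regional strains are always compared on
matched wall sectors. The patch is one element layer (default 1 mm)
extruded outward from the (possibly thinned) epicardium over the patch
window, sharing nodes — perfect bonding.

**Geometry calibration (one-time, frozen).** The source study's
reference dimensions are not printed. The defaults
(a = 20 mm, c = 48 mm, wall 19 mm, f = 0.75) were fixed once by a scan
over human-scale spheroids targeting only the control-model ejection
fraction under the stated two-phase protocol, and are frozen in
`lv_geometry()`; no other quantity was used in the calibration. All
diseased-model outputs are predictions of that frozen configuration.

## Solver

A quasi-static total-Lagrangian finite-element solver:

* **Incompressibility** is enforced by a volumetric penalty
  $U = \tfrac{\kappa}{2}(J-1)^2$ with $\kappa$ = 1e7 Pa by default; the
  static pressure of the continuum formulation is recovered as
  $p = -\kappa(J-1)$. At the protocol load levels this keeps
  $|J-1| \lesssim 10^{-3}$–$10^{-2}$ at every quadrature point (asserted
  in tests); doubling $\kappa$ changes cavity volumes by far less than
  the mesh-resolution error but degrades conditioning.
* **Selective reduced integration**: deviatoric and active terms use
  full 2×2×2 Gauss quadrature, the volumetric penalty a single centre
  point — the standard remedy against volumetric locking of trilinear
  hexahedra.
* **Follower pressure** on the endocardial facets is integrated on the
  deformed bilinear surface with its exact (nonsymmetric) load
  stiffness; the net load on the open endocardial surface equals
  cavity pressure × basal opening area, an identity used as a test
  oracle.
* **Boundary conditions**: basal-plane nodes are fixed axially;
  rigid-body modes are removed by pinning the in-plane motion of the
  basal epicardial ring.
* **Newton with incremental loading**: pressure, activation and
  prescribed displacements ramp together over 10 equal increments
  (automatic halving on divergence, down to 1/320 of the load). The
  consistent tangent (material + geometric + penalty + active coupling
  + follower-load stiffness) is assembled in C++; the linear systems are
  solved by a banded LAPACK LU after reverse Cuthill–McKee ordering.
  Full Newton steps are accepted unless the residual grows beyond a
  50-fold safety cap (transient growth is normal for Newton);
  backtracking engages only on blow-up. The solve is deterministic.
* **Degenerate equilibria.** The coarse symmetric shell admits
  symmetry-equivalent equilibria (the discrete rotation group maps one
  converged state onto another). All reported quantities — cavity
  volumes, regional mean strains, energies — are invariant under these
  symmetries and are what the renumbering-invariance test asserts;
  pointwise displacement fields are determined only up to such
  symmetry images.

Verification oracles: a single-element uniaxial stretch against the
closed-form incompressible response (within 1%), inflation of an
isotropic thick-walled hemisphere against the 1D radial equilibrium
solution obtained by quadrature and root finding (within 2%), and
finite-difference consistency of residual and tangent (< 1e-4, in
practice ~1e-8).

## The in-silico experiments

Three models share the frozen geometry: control (healthy everywhere),
infarcted (thinned IZ, infarct material), implanted (thinned IZ,
patch-implanted scar material, passive epicardial patch). End-diastole:
1500 Pa, no active tension. End-systole: 13,000 Pa (control) or
10,000 Pa (diseased models) with maximal activation. Ejection fraction
is 100(EDV − ESV)/EDV from deformed cavity volumes (divergence-theorem
surface integral closed by the basal plane). Regional strain is the
reference-volume-weighted mean of the fiber Green strain E11 (or the
first-principal Green strain) over a region's wall elements; strain
reductions between models are relative percent changes on matched
sectors, with an absolute percentage-point mode also available.

Two readings in the source text required a decision:

* The 14% end-diastolic IZ strain reduction belongs to the
  infarct-vs-implanted comparison (the patch treatment), not
  infarct-vs-control: a scar that is simultaneously thinned to 1/3 and
  mechanically weakened *increases* its end-diastolic strain relative
  to control under any geometry, so the patch-treatment reading is the
  only physically consistent one and is what `strain_reduction()` on
  the two diseased models' end-diastolic states reports.
* The stiffness-sensitivity sweep ("material properties reduced to ½ or
  1/5") scales the stress scale C of the patch-treated IZ material —
  the uniform stiffness scaling the words describe. Scaling the
  exponents $(b_1,b_2,b_3)$ instead collapses the stress by orders of
  magnitude at working strains and the end-systolic equilibrium ceases
  to exist (the scar balloons); both modes are exposed in
  `scale_material()`. The sweep's baseline 11% figure was reported for
  the IZ, and the sweep limit is continuous with the patch-free
  variant's IZ value, so the sweep reports the IZ reduction (all
  regions are returned).
* The 11/7/0.2% reductions are evaluated at end-systole (they follow
  the end-systolic statement in the source); the phase is an argument.

## Histology quantification and its synthetic ground truth

The imaging component mirrors a standard collagen-quantification
workflow:

* **Birefringence classes** (polarized picrosirius red): pixels are
  classified in CIE Lab space — dark pixels (L* below a threshold) are
  background, the rest split into orange-red (mature, predominantly
  type I collagen; a* ≥ 0) vs green-yellow (immature, type III; a* < 0).
  The maturity ratio is orange-red / green-yellow area.
* **Fiber orientations**: the fiber mask is skeletonized (Zhang–Suen
  thinning), junction pixels are removed, the remaining branches are
  labelled with 8-connectivity, and each branch of sufficient length
  contributes the principal-axis angle of its pixel cloud, measured
  from the image x-axis in (−90°, 90°].
* **Orientation histogram**: 5° bins over (−90°, 90°]; median-peak
  normalization circularly shifts all bins so the peak bin (ties broken
  by smoothed count, then by circular-median proximity) lands just
  right of 0°; the alignment fraction is the mass of the two central
  bins, i.e. orientations within 0 ± 5° (with 5° bins this two-bin
  window and a single centred 10° window contain identical angles).
  For exactly uniform orientations the expectation is 2/36 ≈ 5.56%.
* **Fibrosis fraction** (Masson's trichrome): blue (fibrotic) pixel
  area over total tissue area, near-white background excluded, in RGB.

The colour thresholds of the original ImageJ workflow are not printed;
the defaults separate the synthetic generator's palettes exactly and
are fully exposed (`color_thresholds()`) — calibrating them against
real slides is explicitly the user's task.

**The generator** (`gen_fiber_image()`, `gen_trichrome_image()`,
`gen_angle_sample()`) draws anti-aliased fiber strokes with axial von
Mises orientations (von Mises on the doubled-angle circle — fibers have
no head or tail), alpha-over compositing with per-pixel class ground
truth, and luminance-matched class palettes (both classes sit at
L* ≈ 55) so that intensity thresholds trim the anti-aliased fringes of
both classes alike. Trichrome fields are thresholded Gaussian random
fields inside an elliptical tissue region; the quantile threshold makes
the realized blue fraction match the target exactly before noise.
Seeds are mandatory arguments and the caller's RNG state is never
touched.

**What the synthetic data does and does not show.** The generator
emulates colour separability, orientation statistics, stroke geometry
and area fractions with known truth; it does not emulate polarization
optics, stain variability, out-of-focus blur, or tissue texture. A
pipeline that recovers generator truth is verified as a correct
implementation of the measurement definitions — not as calibrated for
any particular microscope or staining batch.

**Estimator caveats.** Segments split at fiber crossings inherit the
parent fiber's angle, so segment counts are clustered, not independent;
the uniformity test therefore simulates its null with the same
clustering. Orientation estimates on very short skeleton fragments are
lattice-biased (they snap toward 0°, 45° and 90°), which is why a
minimum segment length is enforced. At high stroke density,
near-parallel fibers merge into single skeleton chains, narrowing the
measured orientation distribution around the mode; quantitative
recovery of analytic orientation mass is therefore validated in the
sparse regime (fiber area fraction of a few percent, segments ≥ 25 px),
which is also the regime in which per-fiber angle measurement is
meaningful on real slides.

## Problem sizes and determinism

The bundled study configuration uses the 20 × 12 × 3 mesh
(~2900–3600 degrees of freedom, ~10³ elements with the patch), at which
a full two-phase solve takes on the order of half a minute and the
complete three-model protocol with sweep variants a few minutes.
Synthetic-image tests use 192–448 px images with hundreds of fibers.
All solvers and generators are deterministic given their configuration
and seeds; protocol summaries serialize with fixed formatting so
repeated runs are bit-identical.

## Known limitations

* The source geometry behind the study's finite-element model is not
  printed; with the geometry calibrated only against the control-model
  ejection fraction, the diseased-model ejection fractions come out a
  few percentage points above the study's values while preserving every
  ordering (control ≫ infarcted ≈ implanted; IZ > BZ > RZ strain
  reductions). Quantitative agreement beyond that would require the
  original mesh.
* Two static equilibria stand in for the cardiac cycle: no twitch
  dynamics, no circulation coupling, no viscoelasticity, no growth or
  remodeling.
* Trilinear hexahedra with selective reduced integration are a
  pragmatic, locking-resistant but low-order choice; strains are
  reported at element centres.
* The histology thresholds are generator-calibrated defaults, not
  slide-calibrated ones.
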