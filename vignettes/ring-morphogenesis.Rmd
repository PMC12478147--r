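---
title: "Boundary-driven morphogenesis of an elastic tissue ring: models, pipeline, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Boundary-driven morphogenesis of an elastic tissue ring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(morphoring)
library(dplyr)
```

At the onset of *Drosophila* gastrulation the hindgut primordium — a ring of
roughly 450 cells between the posterior midgut and the germ band — deforms
from a circle into a characteristic triangular "keyhole" without divisions,
death, or appreciable rearrangements of its own cells.  `morphoring`
implements a minimal mechanical account of this deformation in which the ring
is entirely passive: the invaginating posterior midgut reduces the apical
area the ring encloses, the extending germ band prescribes the position of
the two points where the ring crosses the embryo's mid-sagittal plane, and
everything else follows from bending elasticity and the geometry of the
ellipsoidal eggshell.  The package also implements the measurement side: a
pipeline that turns tracked nuclei into deforming closed contours and shape
metrics, a purely geometric "coupled-ring" model that explains the relative
kinematics of neighboring contours, and a synthetic-embryo generator that
provides ground truth for all of it.

This vignette records the models, their assumptions, the tunable parameters,
and the numerical decisions — including the places where the design was
genuinely open and we had to choose.

## 1. The planar constrained elastica

The primordium is skeletonized to a closed, planar, inextensible elastic rod
(an elastica) of bending energy

$$E = \tfrac12 \oint_C \kappa(s)^2\,\mathrm{d}s ,$$

with arclength $s$ and curvature $\kappa$.  Lengths are nondimensionalized
so the half-perimeter is 1 (total length 2); the undeformed circle then has
radius $1/\pi$, anteroposterior (AP) diameter $d_0 = 2/\pi$ and area
$A_0 = 1/\pi$.  Three constraints act:

* **inextensibility** (the contour-length of the midline barely changes in
  the live data, which is what justifies an elastic rather than viscous
  description);
* the **enclosed area** $A$, set by midgut invagination;
* the **AP diameter** $d$: the two material points where the ring meets the
  sagittal midline are held by the germ band at $(0,0)$ and $(d,0)$.

Stationarity of the energy under these constraints gives, for the half-ring,

$$\kappa'' + \tfrac12\kappa^3 - \lambda_0 \kappa + p = 0,$$

with tension multiplier $\lambda_0$ and pressure multiplier $p$, completed by
$\theta' = \kappa$, $x' = \cos\theta$, $y' = \sin\theta$ and the boundary
conditions $\theta(0) = \pi/2$, $\theta(1) = -\pi/2$,
$x(0) = y(0) = y(1) = 0$, $x(1) = d$, plus the integral area condition.  The
perpendicular crossings at the marked points express the bilateral symmetry
of the embryo: the germ band acts as a *clamp*, prescribing position and
tangent direction.

### What the clamps imply: the exact four-fold degeneracy

Because the marked points are clamps, the curvature of the ring may jump
there (a clamp can exert torque), and the upper and lower half-rings
decouple once the multipliers are shared.  If $P$ is an AP-asymmetric
half-ring profile (the "keyhole" half, with its apex lobe toward one marked
point) and $P'$ its AP reflection, then the four upper/lower pairings
$(P,P)$, $(P',P')$, $(P,P')$, $(P',P)$ are all stationary rings of exactly
equal energy: two bilaterally symmetric keyholes whose apex points to either
marked point, and two skew variants.  `enumerate_branches()` constructs the
family this way, which is why the degeneracy in its output is exact rather
than merely numerical.

```{r branches, eval = FALSE}
br <- enumerate_branches(2 / pi, 0.85 / pi)
tidy(br)
autoplot(br)
```

At $d = d_0$ and $A = 0.85\,A_0$ the four keyhole variants have energy
$E \approx 21.89$, clearly below the best AP-symmetric branch
($E \approx 26.50$).

### A mode the boundary conditions exclude

If one drops the clamp directions and requires only the two marked
*positions*, the global minimizer is a different object: an oblique,
point-symmetric, two-lobed shape (energy $\approx 14.5$ at the parameters
above) whose halves are congruent by rotation rather than reflection.  It
breaks the bilateral symmetry of the embryo and is excluded by the model's
boundary conditions, but it is physically instructive — the bilateral
symmetry of the observed keyhole is inherited from the symmetry of the
forcing, not spontaneous.  `ring_polygon_minimize(symmetric = FALSE)`
exposes this unreduced problem.

### Numerics

The boundary-value problem is solved by damped Newton iteration on an
implicit-midpoint collocation discretization of the six-state system
(curvature, its derivative, tangent angle, position, cumulative area), with
the two multipliers as unknowns; the Jacobian is assembled sparsely by a
compiled kernel.  Solutions are then polished by single shooting with an
adaptive integrator (relative tolerance $10^{-12}$), which brings boundary
and area residuals to about $10^{-11}$ and makes the energy of the circle
exact to $10^{-10}$.  Branches are reached by continuation from the circle:
curvature seeds $\kappa = -\pi + a\cos(k\pi s)$ or $a\sin(k\pi s)$
(modes $k = 2\ldots4$, both signs, amplitude $0.1$ by default), stepping
first in $A$ and then in $d$ with step halving, a patient damping schedule
for the first step off the (singular) circle, and a stagnation guard that
abandons folds quickly.  Converged profiles are deduplicated by normalized
root-mean-square curvature distance ($10^{-4}$ threshold) modulo the AP
reflection.

Two independent numerical routes guard the solver.  A discrete polygon
minimizer (`ring_polygon_minimize()`: 200 equal segments, augmented
Lagrangian over the heading angles, bilateral symmetry built into the
parameterization) reproduces the keyhole energy to better than 0.1%; and
the accessibility boundary $A_{\max}(d)$ has a closed form from the
two-circular-arc family (each half of the optimal curve is an arc of length
1 through both marked points), cross-checked against a brute-force area
maximizer.

### The phase diagram

`scan_phase_diagram()` classifies each cell of a $(d, A)$ grid (defaults:
$21\times21$ over $d/d_0 \in [0.7, 1.4]$, $A/A_0 \in [0.5, 1.0]$) by the
symmetry of its minimum-energy branch.  Cells with $A > A_{\max}(d)$ are
geometrically inaccessible to inextensible deformations and are flagged, not
solved.  Each grid column is anchored at an easy mid-range area and swept
outward with warm-started continuation; a column whose default seeds fold
away is re-seeded by a small large-amplitude sweep at the anchor.  Because a
tracked branch can merge into the other symmetry class at a pitchfork, every
converged state is re-classified by its own profile symmetry before energies
are compared.  Cells where no branch converges are reported `unresolved`,
never filled.  The result reproduces the expected topology: a large
contiguous keyhole-lowest region around $d_0$ for moderately reduced areas,
bounded by AP-symmetric shapes when the diameter grows too large.

```{r phase, eval = FALSE}
pd <- scan_phase_diagram()
autoplot(pd)
```

The scan uses a 61-point collocation mesh by default in the tests
(classification margins are percent-level, far above the mesh error); the
figures in this vignette use 101.

## 2. Rings confined to a sphere or ellipsoid

The planar model cannot say *which* of the four degenerate shapes the embryo
picks.  For that the ring is confined to the embryo surface: a sphere, or an
ellipsoid with the embryo-like aspect ratio 2.5:1:1.  A ring is a closed
curve in surface coordinates — colatitude $u$ from the posterior pole and
azimuth $v$ about the AP axis — expanded in six Fourier harmonics per
coordinate and winding once around the pole axis.  `evaluate_ring()`
computes its length, the enclosed (pole-side) surface area by an exact
meridional quadrature, and the bending energy.

Two energy definitions are available, because for a curve in a surface the
planar $\kappa^2$ splits into geodesic and normal parts:
`energy_kind = "geodesic"` (the default; the intrinsic analog of the planar
model, and the choice under which all results in this package are reported)
and `"full-space-curve"` ($\kappa_g^2 + \kappa_n^2$).  On a sphere the two
differ by a constant and share minimizers; on the ellipsoid they can differ,
which is why the choice is exposed.

`minimize_surface_ring()` minimizes over the Fourier coefficients with an
augmented Lagrangian for the length and area constraints and hard position
anchors (ramped quadratic penalties) for the two marked material points;
gradients are computed semi-analytically by chaining pointwise derivatives
of the integrands through the Fourier basis.  Candidate minima whose sampled
curve self-intersects are rejected.  Constraint residuals of returned rings
are at the $10^{-6}$ relative level.

On a sphere with two anchors and a reduced area the ring buckles, and the
constraint set's symmetry group (the mirror across the anchor plane and the
anchor swap) predicts a four-fold degenerate set of minima.
`degenerate_minima()` finds one buckled minimum by multi-start, maps it
through the symmetry group, and re-converges each image from its own seed —
the four energies agree to about $10^{-5}$ relative, and the signed
orientation statistics come in $\pm$ pairs.  The valley connecting these
minima is extremely shallow (the phase of the buckling pattern costs almost
no energy), which is precisely why the degeneracy is resolved by geometry on
the ellipsoid.

The **orientation statistic** (`orientation_statistic()`) quantifies the
triangular orientation: the real part of the third Fourier harmonic of the
ring's radial profile about its centroid, measured in the tangent-plane
frame aligned with the AP direction.  It vanishes for circles, flips sign
under the AP reflection, and its sign defines the orientation class used in
all selection tests.

### Genetic-perturbation scenarios

`run_scenario()` encodes the boundary conditions of wildtype and three
mutants on the 2.5:1:1 ellipsoid.  The scenario geometry is parameterized by
the initial ring colatitude ($u_\mathrm{ring} = 0.55$, a ring comfortably
around the posterior cap), the dorsal translation of the anchors along the
sagittal ellipse (0.8 of the initial pole-to-crossing arc for WT — far
enough off the pole that the curvature gradient is substantial, while the
ring still encircles the pole), the enclosed-area factor (0.85), and an
anchor-separation factor (1.25 for the *bcd osk* dorsal-contraction case).
Anchors are placed at fixed *arc* distances along the sagittal section —
placing them at fixed parametric angles instead would stretch the AP
diameter far beyond what an inextensible ring can accommodate on a prolate
surface.

Each scenario runs in two stages: first the ring relaxes under length and
anchors alone (germ-band translation with a free enclosed area), then the
area is constrained to the scenario's fraction of the relaxed value (midgut
constriction).  The relaxed stage defines the area reference; without it the
combination "translated anchors + pole-cap reference area" is geometrically
infeasible.  Predictions: WT buckles into a keyhole with one consistent
orientation selected by the curvature gradient; *fog* (no constriction, no
translation) stays a circle at the pole to within 1% in energy; *bcd osk*
(translated, wider anchors) still forms an AP-elongated keyhole; *bcd osk
spz* (constriction without translation) buckles with an orientation that
varies from seed to seed — no persistent bilateral axis.

## 3. From nuclear tracks to contours and metrics

`run_kinematics()` implements the measurement pipeline:

1. **Smoothing.** Each coordinate of each track gets an exponential moving
   average with coefficient $\alpha = 2/(w+1)$, window $w = 10$ timepoints,
   initialized at the first observation.  Only complete tracks are
   accepted; `read_tracks()` drops incomplete ones (a few percent in real
   exports) with a message.
2. **Band coordinates.** First-frame positions are mapped to cylindrical
   coordinates $(w, \phi)$.  We use the eigenbasis of the *covariance*
   matrix with the axial direction taken as the smallest-variance
   eigenvector.  A correlation matrix — the obvious alternative — is nearly
   the identity on a ring band (standardized ring coordinates are
   uncorrelated), leaving its eigenbasis undefined; and the *largest*
   covariance direction lies in the ring plane, not along the band axis.
   The sign of $w$ is fixed data-intrinsically (the small-$w$ end is the one
   with the smaller mean cylindrical radius, i.e. the inner rows), so the
   whole pipeline is equivariant under rigid motions of the input.
3. **Binning.** Nuclei are assigned to 5 equal-width bins of $w$ (equal
   count optional) once, at the first frame, and the labels are propagated
   unchanged.
4. **Contour fitting.** Per bin and timepoint, positions are ordered by
   initial azimuth, repeated three times against edge effects, and smoothed
   per dimension by a cubic smoothing spline in the csaps parameterization
   ($p\sum(y_i - f_i)^2 + (1-p)\int f''^2$, $p = 0.01$, integer index
   sites).  The loop is closed by walking simultaneously forward and
   backward from the midpoint of the repeated array until two knots fall
   within half the median inter-knot spacing (both even- and odd-period
   matches are checked), and the closed curve is resampled to 500 points at
   constant arclength.  At $p = 0.01$ the spline is a deliberate low-pass:
   with $\sim$90 points per contour the once-per-loop harmonic is attenuated
   by about 0.2% (negligible against the 1% recovery tolerance), but a
   40-point contour would already be shortened by several percent — the
   smoothing penalty, not the data, sets that scale.
5. **Metrics.** Length is the arclength of the fitted curve.  The area is
   the bilateral-midline Riemann sum: the contour is split at its two
   extreme points along the dorsoventral direction (by default the
   contour's own first principal axis, which keeps the metric
   motion-invariant; exact for curves mirror-symmetric about the split
   axis), arms are paired at equal normalized arc position, and rung length
   times midline step is summed.  Roundness is $R = A/L^2$ ($1/4\pi$ for a
   circle).  Axis extents $f_x, f_y$ are projections onto the embryo frame;
   intercontour distances $d_i, d_o$ are mean nearest-point distances from
   the middle contour.  Each series is normalized by its value when the
   contour's ventral-most point first reaches the reference sagittal angle
   (the innermost contour's initial position), and positions are expressed
   as the elliptic arclength $s(\theta) = E(\theta, \varepsilon)$ along the
   sagittal ellipse.  The default eccentricity is $\varepsilon = 0.92$,
   consistent with the 2.5:1 sagittal aspect ratio; both are configuration,
   not derived quantities, since reported embryo semi-axes and aspect ratios
   do not quite agree with each other.

`detect_stage_change()` offers an advisory two-piece linear fit for locating
the transition between the translation-dominated stage (S1) and the
contraction stage (S2); in real data that transition is usually identified
by inspection.

## 4. The coupled-ring model

The contrasting S1 trends of the inner and outer contours need no mechanics
at all.  If the middle contour is an ellipse of constant length (or constant
area) and the inner and outer contours are its normal offsets at the
*measured* distances $d_i(t), d_o(t)$, then the parallel-curve closed forms

$$L_\pm = L \pm 2\pi h, \qquad A_\pm = A \pm L h + \pi h^2$$

immediately predict that growing offsets shorten and shrink the inner
contour while lengthening and growing the outer one.
`coupled_ring_predict()` implements this, rescaling the measured middle
semi-axes at each timepoint to hold the perimeter (or area) at its initial
value, and `offset_curve_metrics()` enforces the convexity limit (an inward
offset reaching the minimum radius of curvature $b^2/a$ self-intersects).
The closed forms are verified against dense polygon offset constructions to
$10^{-6}$ relative.

## 5. The synthetic embryo

`generate_tracks()` builds track tables with exact ground truth: about 475
nuclei in five rows of a band around the posterior pole of a
$115.6 \times 46.25 \times 46.25\ \mu m$ ellipsoid, followed for 100
timepoints with isotropic Gaussian positional noise
($\sigma = 0.5\ \mu m$).  The flow has two stages:

* **S1** (the first 60% of the movie): the band translates toward dorsal
  along the sagittal plane (0.15 µm/timepoint at the band) while widening
  slightly — the middle row keeps its angular radius, the innermost tightens
  and the outermost spreads by 18% over the stage.  We verified numerically
  that pure translation across the spheroid's curvature gradient does *not*
  reproduce the observed inner/outer divergence (rigid rotation preserves
  all row metrics exactly, and constant-speed tangential advection leaves
  the inner row flat); the divergence in real embryos comes with growing
  intercontour distances — in-plane AP stretch between the contours — and
  the band widening is the minimal way to emulate exactly that.
* **S2**: each row contracts homothetically about its centroid, the scale
  chosen so its enclosed area falls linearly to exactly 0.6 of its initial
  value by the final frame, with inner rows leading outer rows by 3
  timepoints.  The homothety makes the ground-truth area ratio exact by
  construction (the points leave the surface slightly; the pipeline never
  assumes on-surface positions).

What the generator deliberately does **not** emulate: the full 3D involution
of the midgut (contours remain simple closed curves), tracking dropout and
misassignment (noise is purely positional), cell-scale granularity of the
flow, and any in-plane shear within a row.  Passing the pipeline tests on
these fixtures therefore demonstrates correct geometry processing and
metric recovery under realistic sampling and noise — not robustness to
segmentation failure modes.

```{r pipeline, eval = FALSE}
sim <- generate_tracks(generator_params())
res <- run_kinematics(sim$tracks)
autoplot(res)
plot_contours(res)
```

## 6. Problem sizes, tolerances, degenerate inputs

* Collocation meshes: 201 points for single solves (tolerance $10^{-10}$),
  121–151 for branch enumeration, 61 for the phase scan.  Energies of
  refined solutions are accurate to $\sim10^{-10}$; scan-level energies to
  $\sim10^{-4}$ relative, far below classification margins.
* Surface minimization: 192 quadrature samples, 6 harmonics, 5–7 penalty
  stages; constraints met to $10^{-6}$ relative.  Self-intersection is
  checked on 256 samples.
* Pipeline fixtures in the tests use the full 475-nuclei, 100-timepoint
  generator for end-to-end checks and smaller bands (2–3 rows, a few
  timepoints) for unit properties.
* Degenerate inputs raise classed conditions rather than returning junk:
  infeasible $(d, A)$, collinear point sets, rank-deficient first frames,
  empty bins, failed loop closures, inward offsets past the curvature
  radius, self-intersecting rings.
* The multipliers of the undeformed circle are not unique (any
  $(\lambda_0, p)$ with $p = \pi^3/2 - \lambda_0\pi$ reproduces it); the
  package reports the $p = 0$ member.  This is also why the first
  continuation step away from the circle needs a patient damping schedule.

## 7. Known limitations

* The planar model is quasistatic and exactly inextensible; there is no
  dynamics, no stretching elasticity, and no contact with the vitelline
  membrane.
* On the ellipsoid the geodesic and full-space-curve energies genuinely
  differ; all headline results use the geodesic definition, and the other
  is provided for sensitivity analysis rather than validated against data.
* The skew members of the planar quartet rely on the clamp interpretation
  of the germ-band constraint; if the biological boundary condition
  transmits no torque, only the two bilaterally symmetric keyholes remain.
* The phase diagram may contain `unresolved` cells near the accessibility
  boundary and at extreme diameters where branch continuation fails; they
  are reported as such.
* The area metric's midline pairing is exact only for contours
  mirror-symmetric about the split axis; for strongly skewed contours it is
  a few-percent approximation — consistent with how the metric is defined
  for the real data, but not an exact area.
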