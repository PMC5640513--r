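---
title: "Guard-cell wall mechanics and AFM stiffness mapping: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Guard-cell wall mechanics and AFM stiffness mapping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

stomech studies how a stomatal guard-cell pair opens its pore when turgor
pressure rises, and how spatial patterns of wall stiffness measured by
atomic force microscopy (AFM) relate to that mechanics. It has two
computational halves: a finite-element (FE) model of the pressurized
guard-cell pair, and a force-volume analysis pipeline with a synthetic
force-map generator that provides ground truth for validating it. This
vignette explains the models, their assumptions, the tunable parameters,
and the numerical choices, in enough detail that a reader can judge what
the package's tests do and do not demonstrate.

## The mechanical model

### Geometry

Each guard cell is an inflated, tapering tube whose dorsal edge follows
the stomatal outline ellipse (semi-axes `a_s`, `b_s`) and whose ventral
edge follows the pore ellipse (`a_p`, `b_p`); flat polar walls close the
tube at both ends and are shared between the two cells, which are exact
mirror images through the long-axis midplane. Cross-sections are circles
(optionally scaled out-of-plane by `z_flatten`) whose diameter tapers
from the equator towards the poles; the enclosed wall surface of each
cell is closed and sphere-like (Euler characteristic 2). The mesh is a
structured triangulation with a per-element thickness, a wall-patch
label (`ventral`, `dorsal`, `periclinal_outer`, `periclinal_inner`,
`polar_wall`) and a unit fiber direction.

Default dimensions (complex 45 × 30 µm, pore 18 µm long) sit in the
range reported for *Vicia faba* stomata. They are **calibration
values**, not measurements: no dimensioned drawing of the modeled
complex exists to copy. Two defaults deserve emphasis:

* `pore_width0 = 0.5` µm — the resting pore is nearly closed, as in a
  turgorless stoma.
* `z_flatten = 1.6` — the cross-section is taller (out of the leaf
  plane) than wide. This ratio controls the mechanical advantage of the
  epidermal confinement over the pore walls and was calibrated (together
  with the material defaults below) so that the baseline model's opening
  threshold and plateau match the published aperture–pressure landmarks.
  After calibration these values are frozen; they are not adjusted per
  analysis.

The cellulose microfibrils are circumferential: each element's fiber
direction is the in-surface tangent to the level sets of a stored
pole-to-pole potential (on the polar walls, circles around the wall
centre). Computing the direction from the node coordinates makes the
field exactly tangent and equivariant under rigid motions.

The variable-wall-thickness (VWT) variant realizes the rounded-triangular
cross-section of mature guard cells in two coupled ways. The ventral
(pore-facing) half of the cross-section is blended from a circle into a
superellipse (`ventral_flat_exponent`, default 3), flattening the
ventral face while preserving the extreme ventral point — so the resting
pore outline is identical across section kinds. On top of that, the
thickness blends smoothly from `t_wall` on the dorsal crest to
`t_wall * (1 + ventral_thickening)` (default 3 µm) on the ventral crest
(`((1 - cos ψ)/2)^blend_exponent` weighting) — the differential
inner-wall thickening that the triangular lumen produces. The shape
component matters mechanically: thickness scaling alone shifts the
curve but cannot reproduce the characteristic crossover (larger aperture
at low pressure, smaller at high pressure) that the flattened ventral
face produces by bulging into the pore at high turgor. The `m_v`
multiplier (0.9/1.0/1.1) scales the ventral-patch thickness only.

A known limitation follows from the thin-shell idealization: a ±10%
change of ventral thickness enters the pore-release balance through the
flat face's bending stiffness (roughly cubically), so the ±10% VWT
curves agree only to within ~10% of the aperture range here, where a 3D
solid-wall model shows essentially superimposed curves. The scenario
report states this check's result as measured.

### Wall material

The wall is a transversely isotropic Veronda–Westmann solid: an
exponential isotropic matrix with a single circumferential fiber family,

$$W = C_1\left(e^{C_2(\bar I_1 - 3)} - 1\right)
  - \tfrac{C_1 C_2}{2}(\bar I_2 - 3) + W_f(\lambda)
  + \tfrac{K}{2}(\ln J)^2,$$

with deviatoric invariants $\bar I_1, \bar I_2$, fiber stretch
$\lambda = \lVert F a_0\rVert$, and the piecewise fiber law
$\lambda W_f'(\lambda) = 0$ for $\lambda \le 1$ (fibers carry no
compression), $C_3(e^{C_4(\lambda-1)}-1)$ in the exponential toe, and
$C_5\lambda + C_6$ beyond the straightening stretch $\lambda^\*$, with
$C_6$ solved for continuity rather than configured. The shipped
defaults — $C_1 = 2.5$ MPa, $C_2 = 1.2$, $C_3 = 3$ MPa, $C_4 = 5$,
$C_5 = 600$ MPa, $\lambda^\* = 1.05$, $K = 50\,C_1$ — are calibration
values: the parameter set used in the original simulations was published
elsewhere and is not reproduced here, so the defaults were chosen once so
that the baseline aperture–pressure curve opens near 1.3 MPa and
saturates above 5 MPa, then frozen. The stiff post-toe fiber modulus is
essential to the curve shape: it is what makes the aperture saturate
rather than collapse back at high turgor (a soft hoop lets the
cross-section balloon and the ventral walls re-close the pore).

`cauchy_stress()` is the analytic push-forward of $\partial W/\partial C$
and is verified against central-difference differentiation of the energy
in the tests (100 random states, relative error $<10^{-3}$).

### Membrane finite elements and loading

The wall is thin (1 µm on a ~7 µm tube radius), so the solver uses
constant-strain membrane triangles with the incompressible plane-stress
reduction of the material ($\lambda_3 = 1/\sqrt{\det C_{2\times 2}}$,
volumetric term eliminated), plus a discrete-hinge bending
regularization (bending rigidity $D = \texttt{bending\_factor}\cdot C_1
t^3$ on edge dihedrals) that suppresses mesh-scale wrinkling without
affecting the membrane-dominated response.

All loads are conservative potentials:

* guard-cell turgor: $-P_{gc} V_{cell}$ through the enclosed-volume flux
  of each closed cell surface (a follower pressure);
* epidermal pressure: $+P_{epi}$ times the flux integral over the loaded
  patches. The default loaded set is **dorsal + both periclinal bands** —
  the complex confined on all outward faces. This set is exactly
  self-equilibrated across the mirror pair. Loading fewer faces (say,
  dorsal only) leaves each cell with a net outward force that no tissue
  reaction balances in a two-cell model, and roughly halves the pore
  release pressure; the patch set remains a config switch.
* a midplane no-penetration penalty keeps each cell on its side of the
  plane of symmetry — this both models the ventral wall contact of the
  closed pore and the mutual support of the two polar walls;
* the coincident polar-wall nodes of the two cells are tied
  (the cells are fused at their shared polar walls);
* a weak rigid-body penalty (on mean translation and rotation) removes
  drift of the free-floating complex.

Equilibrium at each of the staged load steps (`P_epi = min(P_gc, 0.5)`
co-ramp, then turgor alone to 6 MPa) is found by minimizing the total
potential energy with L-BFGS (warm-started, backtracking line search,
convergence on the maximum nodal force imbalance relative to the mean
applied pressure force, default $10^{-3}$), with adaptive halving of the
load increment on non-convergence. Minimization was chosen over a
Newton iteration because every load is conservative here, which makes
the energy landscape the authoritative description of equilibrium and
gives unconditional robustness through the pore-release event, where the
tangent is nearly singular. The analytic gradient of every energy term
is verified against finite differences in the tests.

The `fixed_poles` variant pins the long-axis displacement of the
`pole_tips` node set — the polar walls plus the adjacent collar of the
tube ends (reference $|x| \ge a_p + 0.5(a_s - a_p)$), the region the
pectin-based polar stiffening would cement. Pinning the thin polar wall
alone is not enough: the soft tube simply bulges axially past the pinned
wall and the complex still elongates.

### Solver validation

`inflate_sphere_benchmark()` solves a closed thin spherical shell with
fibers disabled and compares against the closed-form incompressible
membrane relation $P = 2 t_0 \sigma(\lambda) / (r_0 \lambda^3)$ with
$\sigma = 2(\lambda^2 - \lambda^{-4})(W_1 + \lambda^2 W_2)$; agreement is
within 0.1% at moderate inflation. A work–energy audit (trapezoidal
$\int P\,dV$ along the load path vs stored energy) closes to better than
1%.

### Observables

* **aperture**: minimum transverse gap between the two deformed ventral
  walls on the equatorial ring (a width, µm);
* **complex length**: long-axis extent over all nodes;
* **pore length**: long-axis extent of the deformed pore lip;
* **opening threshold**: smallest turgor at which the aperture exceeds
  its value at the end of the co-ramp by 1% of the total aperture gain
  (linearly interpolated) — an operational reading of "the aperture
  starts to increase";
* **plateau onset**: smallest turgor above which the aperture gain per
  MPa stays below 1% of the total gain;
* **effective stress/strain**: von Mises invariant of the Cauchy stress;
  for strain, the analogous $\sqrt{\tfrac23 E':E'}$ on the
  Green–Lagrange tensor (values reported uncapped; a cap is available
  for plotting). The theoretical maximal pore area
  $a_{max} = 0.25\,\pi l^2$ is kept strictly separate from the aperture
  width.

Problem sizes: the package's own studies use ~2000 elements per guard
cell and 60 load steps for headline numbers (the opening threshold and
plateau onset change by well under 1% between 2000 and 3000 elements per
cell) and ~800 elements for the five-variant scenario matrix; the
default mesher target (20000 elements per cell) reproduces the mesh
density of the original study and is used for mesh bookkeeping.

## The AFM pipeline

Force-volume maps are grids of approach curves (retraction is never
analyzed). Per pixel: voltage → force calibration (`F = V s k`),
baseline/tilt removal on the identified pre-contact segment, contact
detection by sustained 5-SD threshold crossing refined with a weighted
$\sqrt F$ versus $(z - F/k)$ regression over the lower rise of the curve
(for a Hertzian contact $\sqrt F$ is linear in tip-sample distance, so
the long window averages deflection noise down to nanometre-level
contact precision — short parabolic windows leave >100 nm errors at 1%
noise), indentation $\delta = (z - z_0) - F/k$, and a least-squares fit
of the four-sided pyramidal Hertz model

$$F = \frac{\tan\theta}{\sqrt 2}\,\frac{E_a}{1-\nu^2}\,\delta^2$$

over a configurable depth window (default 10–100% of $\delta_{max}$),
with $\theta = 17.5°$ the face half-angle and $\nu = 0.5$. $E_a$ is an
*apparent* modulus: the half-space assumption is knowingly violated on a
leaf surface, so only spatial contrasts are interpreted.

Transects are sampled from the $E_a$ map by bilinear interpolation:
`diameter` crosses the stoma centre along its short axis (averaged over
a narrow band of parallel lines, which suppresses pixel-phase noise on
narrow wall ridges); `circumference` follows the wall-annulus midline
ellipse from the equator. The stiffness-gradient statistic detects the
four wall peaks (local maxima, prominence ≥ 10% of the profile range,
minimum separation 0.5 µm), takes per guard cell
(max inner-wall $E_a$ − max outer-wall $E_a$) divided by the peak
distance, and averages the two cells. Peak heights and positions are
refined by fitting a Gaussian ridge profile to the raw map pixels around
each detected peak: pixel values are exact point samples of the field,
so the fit recovers the crest of a sub-pixel ridge that the interpolated
profile systematically attenuates. Per-stoma gradients use the mean of
the two guard cells (the published analysis does not state per-cell vs
per-stoma pooling). The Mann–Whitney U comparison uses the exact null
distribution for small untied samples and the tie-corrected normal
approximation otherwise, cross-checked against `stats::wilcox.test`.

## The synthetic generator

`make_ground_truth()` builds 2D modulus fields with stage presets:
mature (inner ridge 10 MPa, outer 6 MPa, polar caps 12 MPa, background
2 MPa, crest separation 1.0 µm), young (both ridges 8 MPa, caps
present), and GMC (three equal walls, no caps). Features are narrow
Gaussian crests (SD 0.25 µm — sub-micrometre cell walls) combined by
maximum, so crest values equal the preset moduli exactly and the true
diameter gradient of the mature preset is (10 − 6)/1.0 = 4 MPa/µm.
`simulate_force_map()` runs the pyramidal Hertz forward model per pixel
up to the 1000 nN setpoint and adds baseline tilt/offset, deflection
noise (default SD 1% of setpoint), contact-point jitter (5 nm) and
per-pixel modulus jitter (2%), all deterministic given the mandatory
seed. The sample is modeled as flat (no topography term): plasmolysed
tissue shows stiffness contrast without corresponding surface relief,
and turgor contributes nothing to the measured moduli, so the generator
has no pressure term either.

Two acquisition geometries appear. The overview acquisition (100 × 100
µm at 128 × 128 points, the default `afm_config()`) reproduces the
documented mapping of whole epidermis fields, but its 0.78 µm pixel
pitch cannot resolve two wall crests 1.0 µm apart — they are beyond the
Nyquist limit of the sampled map, for any detector. Stoma-level maps are
close-ups: the recovery study (`run_afm_study()`) therefore images one
stoma per map on a 40 µm field at the same 128 × 128 grid (0.31 µm
pixels), which resolves the ridge pairs. One consequence of the preset
background (2 MPa) is that background pixels indent ~1.3 µm at the
1000 nN setpoint, slightly beyond the 100–1000 nm range quoted for
measurements on stomata; the approach range is sized so these pixels
still complete, and the depth-range check is asserted on stomatal-wall
pixels.

What passing recovery tests shows — and what it does not: the pipeline
recovers known moduli through its own forward model, including contact
detection, baseline handling and sub-pixel ridge profiling, under
realistic noise magnitudes. It does not validate the Hertz half-space
assumption on real wall geometry, substrate (bottom) effects, tip wear,
or adhesion, none of which the generator emulates.

## The study drivers

`run_scenario_matrix()` solves baseline, VWT, VWT ± 10% ventral
thickness, and fixed-poles variants on identical protocols and tabulates
the curve-level orderings (fixed poles opens earlier and wider with
constant complex length; VWT slightly earlier but lower final aperture;
VWT ± 10% essentially superimposed; baseline complex length grows above
~1 MPa). `run_afm_study()` generates 14 mature and 18 young maps
(distinct seeds, randomized stoma pose), recovers per-stoma gradients,
and reports the medians and the Mann–Whitney p value. Both drivers write
plain CSV/JSON reports and are deterministic given their seed.

## Known limitations

* The membrane + weak-bending idealization underestimates through-wall
  stress gradients that a 3D solid model would resolve; contract is the
  curve-level behavior, not pointwise stress values.
* Thickness variation (VWT) is a property field on a fixed mid-surface,
  not a re-meshed lumen geometry.
* The epidermal "pressure" stands in for the mechanical action of
  neighboring cells; no tissue is modeled, and the loaded-patch set is a
  declared modeling choice.
* Material parameters and several dimensions are calibrated, not
  measured; all results should be read as qualitative mechanics with
  calibrated landmarks, which is also how the acceptance checks are
  framed.
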