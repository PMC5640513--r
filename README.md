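# stomech — guard-cell wall mechanics and AFM stiffness mapping of stomata

Stomata regulate plant gas exchange through a pore whose width is set by
the turgor-driven deformation of a pair of guard cells. Two long-standing
questions about the mechanics are (i) how much the classic radial
stiffness gradient of the guard-cell wall (inner/ventral wall stiffer
than outer/dorsal) actually contributes to opening, and (ii) what role a
localized stiffening of the *poles* of the stomatal complex plays.
`stomech` provides the computational tools for studying both:

* a **finite-element model of a pressurized guard-cell pair** — each cell
  a closed, tapering hyperelastic tube with circumferential cellulose
  microfibrils, fused to its twin at the polar walls, confined by
  epidermal pressure, and inflated by turgor — that predicts
  aperture–pressure response curves, complex-length changes, and wall
  strain/stress fields for baseline, variable-wall-thickness (VWT) and
  fixed-pole model variants;
* an **AFM force-volume pipeline** that turns grids of force–distance
  curves into apparent-modulus (E_a) maps, stomatal transect profiles,
  and a radial stiffness-gradient statistic, plus a **synthetic
  force-map generator** with known ground truth for validating every
  stage of that pipeline.

It is aimed at plant biomechanicists and AFM users who want a fully
scriptable, testable counterpart to instrument-vendor force-curve
processing and to black-box FE tool chains.

## The models in brief

**Wall material.** Transversely isotropic Veronda–Westmann solid:

    W = C1 (exp(C2 (I1b − 3)) − 1) − (C1 C2 / 2)(I2b − 3)
        + W_f(λ) + (K/2)(ln J)²,

with deviatoric invariants `I1b`, `I2b`, fiber stretch `λ = |F a0|`
along the circumferential microfibrils, and a piecewise fiber law — no
compression, exponential toe `C3 (exp(C4(λ−1)) − 1)`, then linear with
modulus `C5` past the straightening stretch `λ*` (continuity constant
solved, not configured). Equilibria of the pressurized pair are computed
as minimizers of the total potential energy (membrane elements + weak
bending regularization + enclosed-volume pressure potentials + polar
ties and midplane contact), by warm-started L-BFGS with adaptive load
stepping. The solver is validated against the closed-form inflation of a
thin incompressible spherical shell (< 0.1 % error) and by a work–energy
audit (< 1 %).

**AFM.** Per pixel: `F = V·s·k` calibration, baseline/tilt removal,
contact detection (5 SD threshold + Hertz-shape √F regression),
indentation `δ = (z − z0) − F/k`, and a pyramidal Hertz fit
`F = (tanθ/√2)·(E_a/(1−ν²))·δ²`. Transects (diameter/circumference) are
sampled from the E_a map; the per-stoma gradient statistic is
(max inner-wall E_a − max outer-wall E_a)/peak distance, averaged over
the two guard cells, with sub-pixel ridge crests recovered by a Gaussian
ridge fit against the raw map pixels.

All geometric and material defaults are documented calibration values
(see the methods vignette, `vignettes/guard-cell-mechanics.Rmd`).

## Worked example

Simulate a stoma-level force map (40 µm field, 128 × 128 curves, mature
stiffness pattern), fit one pixel, then recover the radial stiffness
gradient of the whole stoma:

```r
library(stomech)

cfg <- afm_config(map_size = 40)            # per-stoma acquisition
gt  <- make_ground_truth("mature", map_size = 40)
fm  <- simulate_force_map(gt, cfg, noise_model(seed = 1))

curve <- map_pixel_curve(fm, 64, 64)        # one approach curve
curve <- correct_baseline_tilt(calibrate_curve(curve, cfg))
z0    <- detect_contact_point(curve, k = cfg$spring_constant)
fit   <- fit_hertz_pyramid(compute_indentation(curve, cfg, z0), cfg)
fit
#> <hertz_fit> Ea = 2.04 MPa (ok, n = 230, rms 9.82 nN, depth 1252 nm)
# (this pixel sits on the 2 MPa background; truth there is 1.99 MPa)

em   <- process_force_map(fm)               # full E_a map
prof <- extract_transect(em, gt$pose, mode = "diameter")
gradient_statistic(prof)
#> <gc_gradient> 3.64 MPa/um (cells: 3.7 / 3.58)
# ground truth for the mature preset: (10 − 6 MPa) / 1.0 µm = 4 MPa/µm
```

The numbers mean: the single background pixel fits an apparent modulus
of 2 MPa from a ~1.3 µm indentation at the 1000 nN setpoint, and the
per-stoma statistic recovers the built-in inner-vs-outer wall stiffness
gradient. `run_afm_study()` repeats this over 14 mature and 18 young
maps and compares the two gradient samples with a Mann–Whitney test;
`autoplot()` methods display E_a maps, transects and gradient samples.

On the simulation side:

```r
mesh <- build_geometry(geometry_params(mesh_resolution = 800))
sol  <- solve_quasistatic(mesh, material_params(), load_protocol(steps = 30))
glance(sol)          # threshold, plateau, max aperture, residuals
plot_aperture_curve(sol)
rep <- run_scenario_matrix()   # baseline, VWT, VWT±10%, fixed poles
```

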