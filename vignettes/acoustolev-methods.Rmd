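---
title: "Modelling acoustic levitation of tissue spheroids: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling acoustic levitation of tissue spheroids: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(acoustolev)
```

## The physical problem

A bulk-acoustic-wave platform aligns 3D tissue spheroids (HepG2 and
HCT-116 aggregates, 140–340 µm diameter) on a single horizontal plane
inside a hydrogel precursor before the gel is crosslinked and sectioned.
A 3 × 3 array of 2 mm PZT units, diced from one disc and embedded in
epoxy, drives the floor of a fluid chamber of height $h = 1.1$ mm closed
by a glass lid. At 660 kHz the column is close to its half-wave resonance
($c/2f \approx 1.12$ mm), so a vertical standing wave with a single
pressure node forms; spheroids are pushed to the node by the acoustic
radiation force and held laterally by one trap above each PZT unit.

`acoustolev` models this chain end to end: chamber field → radiation
force → levitation dynamics → measured-height statistics, with a seeded
synthetic-data generator standing in for the microscopy measurements.

## Chamber acoustics

The time-harmonic pressure $p(\mathbf{x})e^{-i\omega t}$ satisfies the
Helmholtz equation $\nabla^2 p + k^2 p = 0$, $k = \omega/c$, in a box,
with

* a displacement-driven floor, $\partial p/\partial z = \rho\omega^2
  D(x, y)$, where $D$ is the piecewise-constant map of the array
  (`transducer_map()`); in the homogeneous scenario (`model_a_config()`)
  every unit moves 1.15 nm/V and the epoxy kerf 0.6 nm/V at 60 V drive;
  in the measured inhomogeneous scenario (`model_b_config()`) the centre,
  edge and corner units move 1.7, 1.2 and 1.0 nm/V;
* impedance (Robin) walls, $\partial p/\partial n = i\omega\rho\,p/Z$:
  the glass lid and aluminium frame are not meshed but represented by
  locally reacting impedances of 13 and 17 MPa s m⁻¹ — the same
  idealisation the device is designed around (both are strongly but not
  perfectly reflecting against water, $|R| \approx 0.8$);
* mirror symmetry planes at $x = 0$, $y = 0$, so only a quarter of the
  chamber is discretised for the symmetric reference maps.

The hydrogel grid and its liquid precursor are more than 80% water and
are treated as one continuous water-like fluid (ρ = 1000 kg m⁻³,
c = 1480 m s⁻¹ by default, overridable in the config file); no fluid
damping is applied by default, and a relative `loss` factor on $k$ is
available to regularise exact lossless resonances.

**Discretisation and solver.** Second-order central finite differences
with ghost-point closures on a regular grid, default spacing
(100, 100, 50) µm, i.e. roughly λ/22 laterally and λ/45 vertically
(≈ 6 × 10⁴ unknowns on the quarter domain). Because the box, the
constant wavenumber and the axis-aligned boundary conditions make the
discrete operator separable, the complex linear system is solved
*directly* by eigendecomposition of the two 1D lateral operators and a
small tridiagonal solve along $z$ per lateral eigenmode. This is
algebraically exact for the discretised system — the test suite checks
the assembled interior residual at ~10⁻¹³ — and solves the default grid
in about a second on one CPU, so convergence studies
(`convergence_study()`) and the model B comparison are cheap. The same
discretisation solved by a generic sparse LU would give identical
answers at far higher cost; R's sparse-matrix stack has no complex
support, which made the tensor-product route the natural design.

**Velocity and node extraction.** The acoustic velocity is
$v = \nabla p/(i\omega\rho)$, evaluated by finite differences, with the
normal component forced to zero on mirror planes (its exact parity). The
pressure node (`node_plane()`) is the deepest interior local minimum of
$|p(z)|$ along a vertical line, refined by three-point parabolic
interpolation; a finite-impedance field never reaches $|p| = 0$, so
minima with modulation below 1% of the column maximum are treated as
absent (this cleanly rejects the matched-lid travelling wave).

**1D oracle.** `solve_column()` is the closed-form driven column with
the same boundary conditions; it validates the sign conventions through
the matched / rigid / pressure-release limits and pins the 3D solver on
laterally uniform configurations (< 1% L2 in the tests).

## What the solver reproduces — and what it does not

Computed on the defaults, the model B field reproduces the per-unit
force hierarchy of the measured displacement map: the maximum vertical
radiation force above the centre unit exceeds the edge and corner units
by factors of about 1.6 and 2.3, and the force on a 150 µm spheroid is
≈ 1 µN, two orders of magnitude above its ≈ 19 nN weight. These are the
quantities `scripts/acceptance.R` recomputes.

Two absolute field numbers come out differently from the reference
finite-element study the device was designed with: our lossless in-phase
model yields a peak pressure of ≈ 3.1 MPa and a node at ≈ 515 µm,
where the reference reports 1.4 MPa and 450 µm. The 1D closed form
brackets our result (3.3 MPa, node at $h - \lambda/4 = 539$ µm for a
uniform 69 nm drive), so this is a modelling-input difference, not a
numerical one: the absolute amplitude is controlled by constants and
details (fluid properties, damping, and the *phase* of the epoxy motion)
that are not part of the printed configuration. A sensitivity experiment
is instructive: letting the kerf move in antiphase with the units — a
common behaviour of dice-and-fill arrays — pulls the node down to
≈ 400 µm at similar amplitude, showing the node height is mostly set by
the lateral structure of the drive, which only the measured surface
motion pins down. We deliberately keep the printed in-phase map and
textbook water constants rather than fitting unobserved parameters.

## Gor'kov radiation force

For a compressible sphere of radius $a \ll \lambda$ the time-averaged
radiation potential is

$$U = V\left[f_1\frac{\langle p^2\rangle}{2\rho_m c^2}
      - f_2\,\frac{3}{4}\rho_m\langle v^2\rangle\right],
\qquad
f_1 = 1-\frac{\kappa_p}{\kappa_m},\quad
f_2 = \frac{2(\rho_p-\rho_m)}{2\rho_p+\rho_m},$$

with $\langle\cdot\rangle = |\cdot|^2/2$ for complex amplitudes, and
$F = -\nabla U$ by central differences. The implementation is validated
against the planar-standing-wave closed form
$F_z = 4\pi\Phi k a^3 E_{ac}\sin(2kz)$, $\Phi = f_1/3 + f_2/2$, to
better than 1%, and the discrete force field is curl-free to machine
precision because the difference operators commute.

Spheroid parameters: ρₚ = 1099 kg m⁻³ (measured for the spheroids used
on the platform) and a tissue-like compressibility κₚ = 4.0 × 10⁻¹⁰
Pa⁻¹ by default. κₚ of a living aggregate is not known to better than
~10%, and the force scales with $f_1 \approx 1 - \kappa_p/\kappa_m$,
so absolute force magnitudes carry that uncertainty; the per-unit
*ratios* are insensitive to it.

`unit_force_comparison()` quantifies the per-unit hierarchy as the
maximum $|F_z|$ along the vertical line through each unit's centre —
the way per-unit force profiles are plotted — rather than over the whole
footprint, whose maxima sit on kerf edges shared between neighbouring
units and dilute the contrast.

## Levitation dynamics

A 75 µm spheroid in a ~1 mPa s precursor has a momentum relaxation time
$2a^2\rho_p/9\mu \approx 1.4$ ms, far below the seconds-scale transport,
so the dynamics are overdamped: $\dot{x} = F_{net}/(6\pi\mu a)$ with
$F_{net}$ the interpolated radiation force plus the buoyancy-corrected
weight $(\rho_m-\rho_p)Vg\hat z$ (≈ −1.7 nN). The integrator is an
adaptive explicit Heun scheme whose step is capped by a displacement
limit and additionally *backtracked* whenever a step would increase the
total potential $U + (\rho_p-\rho_m)Vg z$ — overdamped motion is a
gradient flow, so monotone descent is enforced by construction, and a
point from which no step descends is a discrete potential minimum and
terminates the run. Floor and lid contact is handled by clamping the
centre to $[a, h-a]$ and dropping the into-wall force component while in
contact. The fluid itself is quiescent (no streaming, no bulk flow).

Because both the radiation force and the net weight scale with particle
volume, the equilibrium height (`equilibrium_height()`, bracketed
bisection of net $F_z$ to 0.1 µm) is independent of spheroid size — the
property that lets differently sized spheroids co-align on one plane —
and independent of viscosity, which only sets the kinetics.

## Synthetic measured populations

The generator replaces the cross-section microscopy of the wet
experiment and emulates exactly the structure its statistics see:

* **sizes**: truncated-Gaussian diameters (±3σ rejection), e.g.
  140 ± 10 µm;
* **sedimented heights**: centre of mass at one radius above the floor
  plus three artifacts — half-normal floor roughness (the cast gel
  bottom is uneven), stacking (a random partner's diameter is added with
  some probability), and wall adhesion (uniform height with small
  probability) — plus Gaussian measurement noise. The frozen defaults
  (35 µm roughness, 0.25 stacking, 0.03 wall, 15 µm noise for the
  140 µm line) were calibrated once against the reported Gaussian fits
  (150 ± 105 µm) and are not revisited;
* **levitated heights**: node height plus a per-block Gaussian offset
  (frame-height inhomogeneity between hydrogel blocks) plus per-spheroid
  jitter, independent of diameter. The presets use exact variance
  addition, e.g. 30 µm block offset ⊕ 40 µm jitter = 50 µm pooled SD for
  the 285-spheroid HepG2-140 population over 4 blocks.

Block counts and sample sizes follow the reported per-population values
(220/3, 76/4, 285/4, 45/3, 155/3 spheroids/blocks). Two statistical
consequences of the block design are worth noting, because they bound
what a passing test can claim: with $k$ balanced blocks the pooled-SD
expectation is $\sqrt{\sigma_j^2 + \sigma_b^2(1-1/k)}$ (≈ 47.7 µm, not
50 µm, at $k = 4$), and the standard error of the pooled mean is
dominated by $\sigma_b/\sqrt{k}$, an order of magnitude above the naive
$\sigma/\sqrt{n}$. The tests use these hierarchical sampling
distributions. The generator does not emulate image-level effects
(segmentation error beyond Gaussian noise, spheroid fusion or
deformation), so passing tests validate the statistics pipeline, not the
microscopy.

## Alignment statistics

* `fit_gaussian()`: ML Gaussian fit on raw heights (sample mean, SD with
  $n-1$), with a one-sample KS distance as goodness. Fitting raw data
  rather than least-squares on a binned frequency curve is binning-free
  and asymptotically equivalent.
* `central_interval_width(σ, 0.70)` $= 2\,z_{0.85}\,\sigma \approx
  2.073\sigma$: the thickness of the slab containing the central 70% of
  a fitted population; σ = 105 µm gives 217.6 µm, reported as 220 µm at
  the 10 µm granularity used for such numbers. We adopt this central
  -interval definition because the alternative reading "mean + 2SD" is
  not consistent with any reported thickness.
* `fraction_within_slab()`: $2\Phi(t/2\sigma)-1$ analytically, or a
  maximised sliding window on an empirical sample.
* `ks_two_sample()`: two-sided two-sample KS via `stats::ks.test`,
  asymptotic p at effective size $n_1 n_2/(n_1+n_2)$ by default (exact
  enumeration available for small samples); the suite cross-checks D
  against brute-force ECDF enumeration and the null rejection rate over
  1000 seeded replicate pairs (0.05 ± 3 SE).
* `circularity()` $= 4\pi A/P^2$, the shape metric used when segmenting
  spheroid images.
* `group_report()` assembles per-group fits, 70% slab thicknesses and
  the pairwise KS matrix; groups under 8 samples are flagged and
  excluded.

## Pipeline, reproducibility, problem sizes

`simulate_full_experiment()` chains build → solve → force → trace →
synthesise → report, writes each stage's output as CSV/VTK, and finishes
with a JSON manifest (config hash, seed, versions). One global seed is
expanded by fixed offsets into per-stage seeds, so the generator stages
are bit-reproducible independently; solver stages are deterministic.
The default problem sizes — quarter-domain grids of ~6 × 10⁴ nodes,
trajectory batches of a handful of spheroids over a few seconds of
simulated time, synthetic populations matching the reported sample sizes
(45–285) — keep a complete run including both model solves well under a
minute on one CPU while leaving the vertical grid ≈ 45 points per
wavelength.

## Known limitations

* Locally reacting impedance walls ignore elastic waves in the frame and
  lid; thermoviscous boundary layers, acoustic streaming and secondary
  (inter-particle) radiation forces are out of scope.
* The Gor'kov model assumes $a \ll \lambda$; at 340 µm diameter vs
  λ ≈ 2.2 mm the ratio is ~0.15, marginal, and the package warns beyond
  $a > \lambda/10$.
* Absolute pressure amplitude depends on unmeasured loss and drive-phase
  details (see above); force *ratios* and the statistics stage do not.
* The gel is treated as fluid throughout; crosslinking kinetics during
  levitation are not modelled.
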