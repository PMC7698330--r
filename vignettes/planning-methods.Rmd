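---
title: "Phased-array hyperthermia planning: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phased-array hyperthermia planning: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`sarfocus` plans localized microwave heating of a breast tumor with an
eight-dipole ring applicator: it builds a voxel phantom, solves each
antenna's electromagnetic field, optimizes the per-antenna powers and
phases so the specific absorption rate (SAR) focuses on the tumor, and
simulates the resulting transient temperature. This vignette records the
models, the tunable parameters and the numerical choices, and what the
validation suite does and does not demonstrate.

## The synthetic phantom

Anatomically derived voxel breast models are rarely redistributable, so
the generator emulates one statistically rather than anatomically: a
hemispherical breast (default outer radius 70 mm) attached to a
cylindrical pectoral-muscle slab, with a 2 mm skin shell, a subcutaneous
fat shell (5 mm default), and a glandular core interspersed with
breast-fat lobules carved by a seeded, smoothed Gaussian random field
(12 mm correlation length) thresholded at the exact quantile that hits the
target fat fraction. A spherical tumor (muscle dielectric and thermal
constants, temperature-dependent perfusion) overwrites the core at
(0, −12, 12) mm.

The mammographic composition class steers the bulk make-up: the muscle
slab thickness and the core breast-fat fraction are derived from the class
targets (heterogeneously dense by default: muscle 20 %, gland 60 %,
fat 20 % of soft tissue), and the realized voxel fractions land within a
few percentage points of them. The rationale is that bulk composition, not
lobular anatomy, drives the aggregate electro-thermal behavior; fine
anatomical hot-spot structure is outside what this phantom can represent,
and results on it should be read as trends, not patient-specific values.

Geometry conventions: right-handed mm coordinates with the array center at
the origin; voxel centers on integer multiples of the spacing, so the
default tumor center is exactly a voxel center at every divisor spacing;
tumor voxels by the center-inside-sphere rule. Skin closure is enforced
explicitly: any interior voxel left facing air by the discretized shell is
relabeled skin, so the interior is watertight at every resolution. The
breast radius, skin thickness, and slab depth are configuration defaults
(70 mm / 2 mm / class-derived), documented as choices, not as claims about
any particular anatomy.

## The electromagnetic solver

Each dipole (two 50 mm arms, 1 mm nominal radius and feed gap, shortening
factor 0.67 of the resonant half-wave length) is a one-cell PEC line on
the Yee lattice, fed by a resistive (50 Ω) edge-port voltage source of
1 V amplitude at 1 GHz. The field is advanced with a standard FDTD scheme
(Courant factor 0.99 of the 3-D limit, time step rounded so one source
period is an integer number of steps) inside convolutional PML absorbers
(8 cells per face, cubic grading, standard conductivity scaling for the
background medium). After a four-period raised-cosine ramp the field is
demodulated at the drive frequency over four-period windows; steady state
is declared when the port voltage/current phasors and a few field probes
change by less than 10⁻³ between windows. Demodulation samples every few
steps (a divisor of the steps per period, keeping the quadrature sums
exact); staggered components are averaged back to voxel centers.

Power convention: the sources are voltage-driven, but the optimizer's
variables are per-antenna powers. Each solved field is therefore
normalized to 1 W *accepted* port power — computed from the port circuit
as delivered source power minus the drop across the internal resistance —
so superposition can use amplitudes Aₙ = √(Pₙ/1 W). This makes the 8 W
total-power budget directly enforceable and the quadratic forms carry
watts consistently.

Validation: the solver is checked against the closed-form field of a
center-fed thin-wire dipole with sinusoidal current (complex wavenumber in
lossy media). Because that oracle fixes the current scale differently from
a port-driven wire, the comparison is on the field *shape* (normalized at
the innermost probe): the complex shape agrees within 10 % at mid-range
equatorial distances in vacuum, and the amplitude envelope (attenuation
plus 1/r spreading) within 10 % in a glandular-tissue medium, the latter
using an electrically short test dipole for which the sinusoidal-current
assumption is accurate. The radiated (transverse) field
vanishes on the dipole axis; note that at near-field distances the *total*
axial field is dominated by the non-radiating axial component, so the
classic axial null is asserted on the transverse components (FDTD) and on
the total field only in the far zone (closed form). A broadband port run
gives S11(f) and Z_in(f); the shortened dipole's reflection minimum falls
in the 1.1–1.5 GHz band, above the 1 GHz operating frequency, as expected
for a shortened element. Exact S11/Z_in values depend on the port model
and wire discretization and are not asserted.

## SAR quadratic forms

Pointwise SAR is σ|E|²/(2ρ) with peak phasors. For a region of M voxels
the mean SAR under any excitation is Re(Aᴴ H A) with
H_mn = (1/M) Σ_l [σ_l/(2ρ_l)] E*_m(r_l)·E_n(r_l): Hermitian, positive
semidefinite, computed once per region and independent of amplitudes and
phases. The printed polar parametrization of this machinery
(per-pair modulus and phase-lag tables) is self-referential if read
literally; the package computes the complex average directly and exposes
modulus/argument (`form_polar()`) as derived accessors, which avoids
arctangent quadrant ambiguities. Voxels have equal volume, so the plain
mean (no mass weighting) is used. The core correctness test drives the
form against a brute-force superposition oracle on seeded synthetic
fields: relative error below 10⁻⁹ for 100 random excitations.

## Excitation optimization

The objective — tumor mean SAR over healthy mean SAR — is a generalized
Rayleigh quotient of two Hermitian forms in the complex amplitude vector,
maximized exactly by the principal generalized eigenvector of
(H_tumor, H_healthy); the package whitens the healthy form by its
eigendecomposition (Tikhonov-regularized if near-singular) and solves the
transformed Hermitian eigenproblem. Because the ratio is invariant to a
global scale and phase, the solution is rescaled post-hoc to exactly the
8 W budget and gauged so antenna 8 has 0° phase, with phases wrapped to
(−180°, 180°]. The healthy region is all non-tumor, non-air tissue
(configurable). A seeded multistart Nelder–Mead refiner over the 2N−1
free parameters documents that no better feasible point exists; on random
fixtures it never improves the eigen solution beyond 10⁻⁶ relative.

## Bioheat simulation

The Pennes balance ρC ∂T/∂t = ∇·(k∇T) + ρ_bC_bρHTR·(T_b−T) + ρHGR + Q is
advanced by explicit forward Euler with harmonic-mean face conductivities
(flux-conserving across tissue interfaces; an insulated uniform block
conserves mean temperature to machine precision). The time step defaults
to half the per-voxel stability bound ρC / (Σ face conductance/Δ² + Robin
conductance + perfusion coefficient), which reduces to ρCΔ²/(6k) in a
uniform medium. Air is not solved; skin–air faces exchange heat by a
Robin condition with ambient 25 °C. The convective coefficient h is not a
published constant of the study; the default 10 W/m²/K is a standard
effective value for natural convection with radiative/evaporative losses
lumped in, and it is a configuration parameter. The faces where the
truncated muscle slab meets air are artificial cuts of the chest wall and
are insulated rather than cooled. Inside the tumor the perfusion sink is
C_b·ω(T)·(T_b−T) with ω(T) = 0.4 + 0.4 exp(−(T−37)⁴/880) kg/m³/s,
evaluated explicitly at the current temperature; its 880 constant carries
implicit °C⁴ units as printed in the source model. Exposure is 1800 s with
the SAR-derived source Q = ρ·SAR, followed by a 600 s cool-down (the
post-exposure window length is a package default; only its qualitative
decay is meaningful). Analytic checks: uniform-medium steady state
T_b + ρ(HGR+SAR)/(ρ_bC_bρHTR_SI) within 0.5 %, and a pure-diffusion slab
against the Fourier-series transient within 1 %.

## Problem sizes and runtime choices

The default study grid is 3 mm voxels (about 13 cells per in-tissue
wavelength at 1 GHz; roughly 30×49×49 phantom voxels and a 60×95×95 FDTD
domain), chosen so the whole eight-antenna solve-optimize-simulate chain
runs in a few minutes per tumor radius on one CPU; 1 mm operation is a
configuration change, not a code change. The default pipeline mode (and
the validation suite) recomputes the eight unit fields for every tumor
radius, because the tumor carries muscle dielectrics that differ from the
gland it replaces; `field_mode = "shared"` solves them once on the
largest-radius phantom and reuses them, an eight-fold saving per
additional radius that perturbs only the small tumor-volume dielectric
contrast (about 10 % in conductivity) while the SAR and thermal stages
still use the exact per-radius tissue maps.

## Known limitations

Single-frequency dielectric constants (no Debye/Cole–Cole dispersion);
no inter-antenna coupling or feed-network model; no water bolus; no
regulatory mass-averaged SAR; explicit (not implicit) thermal stepping;
the phantom reproduces composition statistics, not anatomy, so absolute
SAR maxima and hot-spot geography are not comparable to patient-derived
models — monotone trends with tumor size, the optimization gain over the
uniform drive, and the sub-42 °C operating point at 8 W are the
reproducible quantities.
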