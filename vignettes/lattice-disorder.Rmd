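---
title: "Modeling and subtracting lattice disorder in protein crystal diffuse scattering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and subtracting lattice disorder in protein crystal diffuse scattering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latticevibes)
```

## The model

Proteins in a room-temperature crystal vibrate about their average
lattice positions. Because these displacements are correlated over many
unit cells, they concentrate diffuse X-ray intensity in halos around the
Bragg peaks, on top of the weaker, cloudier signal from motions internal
to each molecule. `latticevibes` models the lattice part so it can be
refined against measured halos, cross-validated without a model, and
subtracted.

**Rigid bodies and generalized coordinates.** Each protein chain image
in the unit cell is a rigid body. Its displacement field is linear in
six generalized coordinates (three translations, three infinitesimal
rotations about the center of mass):
`u_j = A(x_j) w`, with `A(x) = [ I | S(x) ]` and `S(x) ω = ω × x`. This
is the TLS parameterization of rigid-body disorder, so the model's
zero-offset covariance blocks are literally the T, L, S matrices of
structure refinement.

**Elastic network.** Atom pairs of *different* body instances (same or
neighboring cells) closer than a 4 Å cutoff are joined by springs. A
hybrid spring has force-constant matrix `γ_g I + γ_p ûûᵀ`: a Gaussian
part restoring any relative displacement and a parallel part restoring
only the component along the contact vector. Space-group symmetry is
enforced at the parameter level: contacts in one orbit of
(body, body, cell-offset) triples under the space group — one
protein–protein *interface class* — share constants. Three grouping
levels (global, per interface, per residue pair) form a nested
hierarchy used by the staged refinement.

**Lattice dynamics.** On a periodic `N₁×N₂×N₃` supercell the equations
of motion block-diagonalize over wavevectors
`k = (n₁/N₁, n₂/N₂, n₃/N₃)`. With the generalized mass matrix per body
`M = Σ_j m_j A_jᵀA_j = L Lᵀ` (Cholesky; any factor gives identical
observables — tested), the dynamical matrix is
`D(k) = L⁻¹ Φ(k) L⁻ᵀ` with `Φ(k)` the Fourier-transformed generalized
Hessian. Classical equipartition yields the covariance of generalized
coordinates (the V-Cov),

```
⟨w_l w_l′ᵀ⟩ = N⁻¹ k_BT Σ_k exp(i k·(R_l − R_l′)) L⁻ᵀ D⁺(k) L⁻¹ .
```

At `k = 0` exactly three eigenvalues vanish (rigid supercell
translations); the pseudo-inverse removes them, which is the statement
that the supercell's center of mass is fixed. A consequence worth
knowing when interpreting outputs: summed over all offsets the
translational covariance is exactly zero, so positive short-range
correlation is always balanced by long-range anti-correlation.

**Diffuse intensity.** In the one-phonon (small-displacement)
approximation each mode scatters independently, contributing only at the
satellite points `q = g_h − k`:

```
I⁽¹⁾(q) = k_BT · G(q) (L⁻ᵀ D⁺(k) L⁻¹) G†(q),
G_κ(q) = [ q F_κ(q) ; −q × F{(r − o_κ) ρ_κ}(q) ] .
```

Two routes to `G` are provided: an analytic sum over Gaussian atoms
(exact for the synthetic fixtures; the simulation default) and the
grid route — soft-mask partitioned unit-cell density, oversampled FFT,
tricubic interpolation of the real and imaginary parts with a phase
factor undoing the origin shift. The two agree to the interpolation
tolerance (tested).

## Parameters that matter

| parameter | default | unit | meaning |
|---|---|---|---|
| contact cutoff | 4 | Å | inter-body atom pairs joined by springs |
| γ_g, γ_p | refined | k_BT/Å² | Gaussian / parallel spring constants |
| supercell | 8×8×8 | cells | range of modeled correlations (toys use 2–5) |
| k_BT | 1 | — | only the product k_BT·(1/γ) enters any observable, so temperature is folded into the spring units |
| soft-mask blur B | 50 | Å² | smooths the density partition between bodies |
| transform padding | 4× | — | oversampling of the molecular transform |
| halo window, count | 2.0–2.5 Å, 400 | | Bragg peaks whose halo blocks enter the fit |
| ΔPDF truncation | 1.6 | Å | resolution limit before the FFT |
| peak mask d | 4 | Å | spherical crop of each ΔPDF lattice peak |
| low-res exclusion | 5 | Å | deconvolution samples with larger d-spacing dropped |
| shell width | 0.02 | Å⁻¹ | resolution bins for SD/CC statistics |

Toy fixtures scale the resolution-dependent values to their small cells
(≈13–21 Å): map truncation 2.2 Å, halo windows 3–5 Å, peak mask 3 Å.
The published defaults remain in `workflow_config()`.

## Refinement

`refine_springs()` minimizes the inverse-sigma weighted squared error
between measured and simulated halo intensities. The per-halo linear
background (exactly 4 coefficients: constant + gradient in the
fractional offset from the reciprocal-lattice point) is a linear
subproblem and is profiled out exactly at every step — tested against
the normal equations. Spring constants are optimized on a log scale
(positivity by construction) with `nlminb`, relative χ² tolerance 1e-6,
at most 200 iterations. Stages run global-Gaussian →
interface-Gaussian → interface-hybrid → residue-pair-hybrid; each stage
starts from its parent's values (hybrid stages seed the parallel
constant at 1e-4 of the Gaussian one), so χ² is non-increasing across
stages.

## Model-free validation by peak deconvolution

The 3D-ΔPDF — the FFT of the variational diffuse map — has a sharp peak
at every lattice node `R_n`. For translation-dominated disorder the peak
is the Patterson origin peak convolved with `F{q·V_n q}`, `V_n` the
joint-ADP of bodies separated by `R_n` (for symmetric space groups: the
group-averaged effective joint-ADP). The deconvolution is done entirely
in reciprocal space: with `Y_n` and `X` the inverse FFTs of the masked
peak and masked Patterson peak, the six unique elements of `V_n` solve
the ordinary least squares problem `Y_n(q) ≈ X(q)·(q·V_n q)` over a
sample domain `D`.

Numerical choices that proved essential:

* **Exact node alignment.** One edge plane of the (odd) map grid is
  dropped before the FFT so lattice translations fall exactly on the
  real-space grid; Friedel completion is done on the periodic grid so
  the transform is real to machine precision (a one-voxel misalignment
  here attenuates off-origin peaks by `cos(2π/s)` — caught by a
  shift-theorem test).
* **Real-space oversampling.** The reciprocal box is zero-padded
  (factor 2, Nyquist plane split to preserve symmetry) so the ~1 Å
  real-space step of the raw band does not alias the masked peaks.
* **Band matching.** The Patterson is truncated to the same resolution
  and Miller box as the map, and the fit domain `D` keeps only samples
  inside the data band: `res_cutoff ≤ d ≤ exclusion`. Samples beyond
  the band contain only mask ringing, for which the peak model does not
  hold; leaving them in biases `V` down severely. The low-resolution
  exclusion (default 5 Å) removes sensitivity to unknown constant
  offsets in either map.

Residual error sources are the mask-boundary commutator (Patterson
density at the mask radius) and truncation ringing; on the fixtures they
leave per-component errors at the few-percent level, while *correlations*
across nodes — the published validation metric — reach 0.999 (isotropic)
and ≈0.98 (anisotropic).

## What the synthetic fixtures emulate — and what they do not

`make_toy_crystal()` builds deterministic few-atom rigid bodies
(Gaussian pseudo-atoms, fixed width) in P1 (triclinic-like) and
P2₁2₁2₁ cells, with jittered geometry so symmetry orbits are generic,
connected stable spring networks, and distinct true constants per
interface class. They exercise every code path: symmetry expansion,
orbit grouping, stable dynamics, halo structure, refinement and
deconvolution.

They do **not** emulate: realistic protein geometry or solvent; the
protein regime in which rotational (librational) covariance between
neighbors is negligible. A few-atom body has small inertia, so with full
6-dof dynamics its rotations contribute to the diffuse map on par with
translations, and the translational peak model is (correctly) only
approximately valid — recovery correlations drop to ≈0.9. The
joint-ADP acceptance surrogate therefore uses translation-only (3-dof)
dynamics with hybrid springs, which realizes exactly the stated
assumption of the deconvolution while keeping the covariances
anisotropic. A green surrogate test establishes the correctness of the
pipeline under its stated assumption, not the size of the rotational
correction for any particular crystal.

Two independent oracles guard the physics: a brute-force supercell
Hessian pseudo-inversion (equal to the per-wavevector covariance to
1e-8 relative) and a Monte-Carlo harmonic ensemble whose sampled
diffuse intensity matches the one-phonon formula within 2% at 0.1 Å
displacement scale.

## Degenerate inputs and tie-breaks

* Collinear or single-atom bodies have singular inertia: `mass_factor`
  rejects them with guidance (use `dof = 3` point bodies).
* Contact cutoffs above half the smallest cell-face spacing are rejected
  (periodic image ambiguity); the search box widens automatically when
  the cutoff exceeds a face spacing.
* Contacts are stored once per unordered pair of body instances; the
  Hessian assembly adds both directions (no double counting).
* Zero eigenvalues: anything below 1e-8 of the spectral maximum is a
  zero mode; exactly three are required at `k = 0`, none elsewhere — a
  violation reports the offending wavevector and mode instead of
  proceeding.
* Voxels exactly at integer Miller indices use the pseudo-inverse
  convention (acoustic modes removed), which is also what a one-cell
  comparison supercell needs (only `k = 0` optical modes survive).
* `fill_missing` iterates six-neighbor means until nothing more can be
  filled; unreachable voxels stay flagged rather than being invented.

## Robust regridding and target maps

To compare with a fixed-supercell (e.g. MD) simulation, the lattice
simulation is subtracted on the fine experimental grid, the residual is
regridded onto the coarse Miller grid with the robust error-weighted
Savitzky–Golay filter — spherical neighborhoods of radius
`(3v_t/4π)^{1/3}`, quadratic polynomial, inverse-variance weights,
bisquare re-weighting `w_i = (1 − (r_i/6m)²)²` for `|r_i| < 6m` (else 0,
with `m` the median absolute deviation of inverse-sigma-weighted
residuals from a tricubic back-interpolation of the first pass) — and
the one-phonon intensity at the wavevectors allowed by the comparison
supercell is added back. Sigma propagates through the weighted normal
equations. Neighborhoods with fewer than 10 usable voxels are flagged
missing rather than extrapolated.

## Known limitations

* No internal (within-body) normal modes, anharmonicity, or
  temperature-dependent force fields; `k_BT` is a single scale.
* The deconvolution recovers only the symmetric, translational part of
  inter-body covariance (no rotational or cross-group terms), as the
  peak function dictates.
* The grid structure-factor route is percent-accurate for bodies that
  fill their cell; use larger padding (`oversample`) or the atom-sum
  route when that matters.
* Map I/O is plain text (TSV with a JSON header); there is no HDF5 or
  CCP4/MRC container in this implementation.
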