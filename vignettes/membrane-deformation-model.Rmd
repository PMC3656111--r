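---
title: "Thickness deformations, inclusion shape, and mechanosensitive gating"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thickness deformations, inclusion shape, and mechanosensitive gating}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memdef)
```

## The physical model

`memdef` treats a membrane protein as a rigid cylindrical-ish inclusion
spanning a lipid bilayer and computes the elastic cost of the **thickness
deformations** it induces. The bilayer hydrophobic thickness is `2ℓ` at
rest; the field `u(x, y)` is the local deviation of one leaflet's
hydrophobic half-thickness from `ℓ`. Its energy is

$$G = \frac12 \int dx\,dy \left[ K_b (\nabla^2 u)^2
  + K_t \left(\frac{u}{\ell}\right)^2
  + \tau\left(\frac{2u}{\ell} + (\nabla u)^2\right) \right],$$

the standard quadratic membrane functional: a bending term, a
thickness-compression term normalized by the relative strain, and two
tension couplings (to the lipid area liberated by thinning, and to the
gradient of the surface). Midplane bending decouples from `u` at this
order and is not modeled. Minimization gives

$$K_b \nabla^4 u - \tau \nabla^2 u + \frac{K_t}{\ell^2} u + \frac{\tau}{\ell} = 0 .$$

The constant forcing is absorbed by shifting to
`v = u + τℓ/K_t` (tension thins the far-field membrane to
`u∞ = −τℓ/K_t`, see `u_far_field()`); the homogeneous operator then
factorizes into two Helmholtz operators whose roots `ν±` solve
`K_b ν² − τ ν + K_t/ℓ² = 0` (`helmholtz_roots()`). Below
`τ = 2√(K_b K_t)/ℓ` — about 46.6 kBT/nm² at the defaults, far above any
physiological tension — the roots are complex conjugates, so the radial
kernels `K_n(√ν r)` are exponentially damped *oscillations*. All root and
Bessel arithmetic is therefore done in complex numbers end to end; the
reality of every physical output is asserted (tolerance `1e-10` relative),
never silently forced by taking real parts.

### Boundary conditions

The protein enters through its boundary curve and two conditions on it:
`u = U` (half the hydrophobic mismatch, `U = (W − 2ℓ)/2` for protein
hydrophobic thickness `W`) and a prescribed normal slope `U′`, zero by
default — the hydrophobic belt pins the leaflet surface, and the contact
slope is poorly constrained experimentally, so the conventional clamped
choice `U′ = 0` is the default throughout.

### Non-circular cross sections

A boundary `r(θ) = R_0 (1 + ε(θ))` with
`ε(θ) = Σ_n (c_n cos nθ + s_n sin nθ)` models the cross section of an
oligomer: the rotational symmetry order of the protein is the dominant
harmonic. Two shipped families:

* **polygonal** (`make_ngon()`): the Fourier series of the exact regular
  P-gon radius, truncated at `max_multiple` multiples of P. The leading
  relative amplitude falls quickly with P (triangle ≈ 0.37, square ≈ 0.14,
  pentagon ≈ 0.086, hexagon ≈ 0.058), so polygons approach the circle as
  the symmetry order grows;
* **clover-leaf** (`make_cloverleaf()`): a single cosine harmonic at the
  symmetry order `s`, the propeller-like outline of subunit lobes. Here the
  amplitude is a free morphological parameter, and the deformation energy
  *grows* with `s` at fixed amplitude — higher harmonics force steeper
  angular variation of the field.

`solve_perturbed()` maps the boundary conditions on the true curve onto an
equivalent cylinder at `R_0`, to leading order in `ε`: Taylor expansion of
the zeroth-order profile gives per-harmonic effective data
`U_n = −R_0 ε_n u_0'(R_0)` and `U'_n = −R_0 ε_n u_0''(R_0)`
(`effective_boundary_data()`), and each angular channel is closed by a 2×2
linear solve. The n = 0 channel is exactly the cylinder solution because
`ε` has no mean component by construction (any mean is absorbed into
`R_0`). Solutions are linear in `(U, U′)` jointly and in each `ε_n`;
consequently the energy is exactly quadratic in the harmonic amplitudes and
additive across harmonics (angular orthogonality kills cross terms), both
of which are asserted in the test suite at `1e-6`/`1e-8` relative.

### Energy and its decomposition

On the Euler–Lagrange solution the area integral collapses, via Gauss's
theorem in the plane, to a line integral over the inclusion boundary,
which the per-harmonic structure turns into a closed-form sum
(`deformation_energy()`). The zero of energy is the flat membrane at the
uniform tension-set thickness, so an undeformed bilayer has zero energy and
`G ≥ 0` whenever `τ = 0`. `shape_decomposition()` reports
`ΔG_shape = G_total − G_cyl` against the equal-area cylinder by default;
equal-circumference is available because both conventions are physically
defensible — equal area fixes the in-plane footprint that tension acts on,
equal circumference fixes the length of bilayer–protein contact line. The
excess is computed as a difference of two closed-form energies at identical
parameters rather than from a separate formula, avoiding cancellation
surprises at the `O(1–10)` kBT magnitudes involved.

### Gating

The two-state Boltzmann model gives
`P_open(τ) = 1/(1 + exp[ΔG(τ) − τΔA])` in kBT units. `gating_tension()`
finds `P = 1/2` by bracketed root finding; in the default
`tension_dependent` mode the membrane energy difference is re-evaluated at
every candidate tension (the energy functional itself contains `τ`), which
lowers `τ*` by roughly 10–20 % relative to the `fixed_dG` mode that
evaluates `ΔG` once at `τ = 0`. Both modes are exposed since both are
useful: fixed-`ΔG` matches zero-tension energy decompositions, the
self-consistent root is the physically complete statement. Only the
membrane contribution to `ΔG` is modeled; protein-internal free energy
differences are outside scope and would shift every gating curve rigidly.

## Shipped parameterization

All numeric constants live in `inst/extdata/mscl_params.yaml`
(`load_params()`); library code contains none. Defaults, with the reasoning:

| quantity | default | why |
|---|---|---|
| `Kb` | 20 kBT | canonical fluid-PC bending rigidity |
| `Kt` | 60 kBT/nm² | PC area-stretch modulus (≈ 247 mN/m) expressed per strain |
| `τ` | 0 | energy scans are at zero tension; gating sweeps it |
| `r_c`, `r_o` | 2.5, 3.5 nm | cylinder-model radii of closed/open MscL from structural estimates; `ΔA ≈ 18.8 nm²` matches the measured area change |
| tail map | `2ℓ = 0.175 (n−1)` nm | classic fluid-PC hydrophobic thickness per tail carbon |
| `W` (equal mode) | 1.925 nm | protein thickness matching a PC12 bilayer, the fitted value of the cylinder gating model; gives `U = −0.525` nm in PC18 |
| `W_c`, `W_o` (distinct mode) | 2.5, 2.1 nm | crystallographic closed-state and modeled open-state hydrophobic thicknesses; the larger open-state mismatch shifts gating to higher tension |
| clover-leaf amplitudes | 0.22 (closed pentamer), 0.13 (open pentamer), 0.12 (hexamer) | reconstructed from the morphology of the structural models (closed pentamer visibly deeper-lobed than open) under the qualitative constraints the model family must satisfy: the closed-pentagon → open-clover-leaf hybrid gates hardest, the reverse hybrid carries a small positive penalty, and the pentameric pair gates well below the cylinder yet at positive tension |
| polygon truncation | 3 multiples of P | resolves the corner shape visibly while keeping every retained harmonic within leading-order validity |
| validity threshold | max abs eps 0.35 | leading-order theory; larger deviations are flagged with a warning, not refused |

The polygon orientation convention puts a vertex at θ = 0 (recorded in the
shape metadata); orientation is physically irrelevant since the energy is
rotation-invariant, which the tests assert to `1e-12`.

## Numerical choices

* **Complex modified Bessel functions.** No installed R package evaluates
  `K_n` of complex argument, so `cbesselK()` implements the integral
  representation `∫ exp(−z cosh t) cosh(nt) dt` with the trapezoid rule
  (step 0.01, adaptive upper limit). The integrand is even and decays
  double-exponentially, so the rule converges spectrally; agreement with
  base `besselK()` on the real axis and the Wronskian identity against an
  independent power-series `I_n` hold to ≈ `1e-11` across the used domain
  (`|arg z| ≤ π/4`, `n ≤ 20`). Derivatives use the three-term recurrences.
* **Scaled evaluation is unnecessary here**: fields are only needed within
  ≈ 40 nm of the boundary, where the kernels stay above 1e-9 of their
  boundary values; beyond, the far-field constant is returned by
  construction of the series.
* **Degenerate inputs.** The per-harmonic 2×2 solves abort with a
  conditioning diagnostic when `|det|` falls below `1e-14` of the
  coefficient scale; non-star-shaped or non-positive radii are rejected at
  shape construction.
* **Oracles.** The radial oracle discretizes the fourth-order per-harmonic
  ODE with second-order central differences, one-sided third-order
  closures, and clamped decay at `R_max`; the 2D oracle solves the full
  equation on the boundary-fitted map `ρ = C(θ) + (R_max − C(θ))ξ`,
  imposing the value and true normal-slope conditions exactly on `C(θ)`
  (a boundary-fitted rather than immersed treatment — the boundary
  handling is precisely what is under test). Fourth-order operators are
  composed from second-order first-derivative operators; boundary closures
  are one order higher than the interior so Richardson extrapolation over
  a factor-2 grid pair cleanly removes the leading `h²` error. Error
  budgets are always split into an estimated discretization part (from the
  grid pair) and the `O(ε²)` truncation part — no bare magic tolerances.
* **Problem sizes.** The shipped verification studies use a radial grid of
  4000 points over 8 nm plus an adaptive decay margin, and 2D grids of
  61×(64–128) with factor-2 refinement; these resolve the fields to well
  below the perturbative remainder at the amplitudes studied (0.05 and
  0.10) while keeping a full verification sweep in minutes on one CPU.
* **Root finding.** Gating tensions use Brent's method on
  `ΔG(τ) − τΔA` with absolute tolerance `1e-9` kBT/nm²; a bracket without
  sign change is an explicit error (a channel whose `ΔG ≤ 0` is open at
  zero tension and has no positive gating tension).

## The synthetic structure generator

`write_synthetic_structure()` emits minimal PDB text: carbon atoms placed
on a radially modulated ring (`r = C(θ)(1 − d)`, `d` uniform within a thin
inward band) inside a z slab, i.e. an idealized transmembrane hydrophobic
belt with a prescribed cross-section outline. It emulates exactly what the
extraction pipeline consumes — an atom cloud whose angular silhouette is
the boundary of interest — and nothing else: no secondary structure, no
side-chain atoms, no depth-dependent packing, no ellipticity of real
subunits, no membrane tilt. Round-trip tests (generate → outline → Fourier
fit) therefore validate the extraction and fitting machinery, not the
biological realism of any particular outline; for deposited structures the
slab position, probe radius and bin count remain the user's
responsibility. The outline itself is a shrink-wrap silhouette (per-bin
maximum radius plus probe), deliberately not a convex hull: clover-leaf
cross sections are non-convex, and a hull would erase the lobes that the
elastic model exists to study. Note the probe radius inflates the fitted
mean radius but not the absolute lobe amplitude, so round-trip comparisons
are made on `c_n · R_0` in nm.

## Known limitations

* Leading order in `ε`: energies are exact through `O(ε²)`; for the
  triangle (`ε ≈ 0.37`) and strongly lobed shapes the quantitative values
  carry `O(ε³)` errors, and the package warns above `max|ε| = 0.35`.
* Constant `U` and `U′` along the boundary by default; angularly resolved
  mismatch is supported by the data structures (`boundary_data()`
  harmonics) but no shipped model uses it.
* One inclusion in an infinite membrane: no inclusion–inclusion
  interactions, no finite patch or vesicle geometry.
* The gating model is two-state; sub-conductance states and kinetics are
  out of scope, as is the protein-internal contribution to the gating
  energy.
* Midplane (bending) deformations are decoupled and ignored; spontaneous
  lipid curvature and higher-order membrane models are not included.
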