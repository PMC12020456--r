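---
title: "Smooth conductor-like PCM with dynamic cavity radii: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Smooth conductor-like PCM with dynamic cavity radii: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swigcpcm)
```

## The model

`swigcpcm` implements the conductor-like polarizable continuum model (CPCM)
for solutes described by classical point charges.  The solvent is treated as
a scaled conductor: the solute sits in a cavity of overlapping atom-centred
spheres, the cavity surface carries induced charges $q$ obtained from the
linear response equations

$$ A\,q = -f_\varepsilon\, v, \qquad
   f_\varepsilon = \frac{\varepsilon - 1}{\varepsilon + x},\ x = 0, $$

where $v_i = \sum_K Z_K / \lVert r_i - R_K \rVert$ is the solute potential
at the surface points, and the polarization energy is
$E_\mathrm{pol} = \tfrac12 q^\top v = -\tfrac{f_\varepsilon}{2}
v^\top A^{-1} v \le 0$.

Two refinements define the package:

1. **Switching-Gaussian discretization (SwiG/iSwiG).** Each surface point
   carries a spherical Gaussian of width
   $\xi_i = \xi_\mathrm{Born} / (R_I \sqrt{w_i})$ rather than a point
   charge.  Off-diagonal interactions are
   $A_{ij} = \mathrm{erf}(\xi_{ij} r_{ij}) / r_{ij}$ with
   $\xi_{ij} = \xi_i \xi_j / \sqrt{\xi_i^2 + \xi_j^2}$; the diagonal is the
   Gaussian self-interaction divided by a smooth switching value,
   $A_{ii} = \xi_i \sqrt{2/\pi} / F_i$, where
   $F_i = \prod_{J \neq I(i)} f(r_{iJ}; R_J)$ attenuates points that pass
   into foreign spheres,
   $f = 1 - \tfrac12[\mathrm{erf}(\xi_i (R_J - r_{iJ})) +
   \mathrm{erf}(\xi_i (R_J + r_{iJ}))]$.
   This keeps the potential-energy surface continuous as surface points
   enter and leave the cavity.

2. **Dynamic radii.** Cavity radii respond to the electronic environment:
   $R_I = f_I R_{I,0}$ with
   $f_I = \mathrm{erf}\!\big(a_I (q_{I,\mathrm{eff}} - b_I)\big) + 1 \in (0, 2)$
   and $q_{I,\mathrm{eff}} = q_I (1 + k_I\, \mathrm{CN}_I)$, driven by
   electronegativity-equilibration (EEQ) partial charges and a smooth
   coordination number CN.  Because $f_I$ is strictly positive no radius
   floor is needed, and clamping would break gradient continuity.

The central deliverable is the **complete analytical nuclear gradient** of
$E_\mathrm{pol}$.  Since $E_\mathrm{pol}$ is stationary in $q$,

$$ \frac{\partial E_\mathrm{pol}}{\partial R_A}
   = q^\top \frac{\partial v}{\partial R_A}
   + \frac{1}{2 f_\varepsilon}\, q^\top
     \frac{\partial A}{\partial R_A} q , $$

with no $\partial q / \partial R_A$ term.  The $1/(2 f_\varepsilon)$
prefactor follows from differentiating
$E_\mathrm{pol} = -\tfrac{f_\varepsilon}{2} v^\top A^{-1} v$ and is
confirmed by a dedicated test: at $\varepsilon = 4$ the alternative
$\tfrac{f_\varepsilon}{2}$ reading disagrees with the finite-difference
oracle by orders of magnitude while the implemented form matches to
$10^{-8}$.

With dynamic radii every geometric ingredient acquires a radius-chain term:
grid points move with their sphere's radius
($r_i = \mathbf{R}_I + R_I u_i$ with laboratory-frame-fixed unit vectors
$u_i$, so
$\partial r_i / \partial R_A = u_i \otimes \partial R_I / \partial R_A +
[I{=}A]\,\mathbb{1}$), Gaussian widths scale as $1/R_I$, the switching
factors see both the moving point and the foreign sphere's changing radius,
and the radius derivative itself chains through the EEQ charges and the
coordination numbers,

$$ \frac{\partial R_I}{\partial R_A}
   = \frac{2 R_{I,0}\, a_I}{\sqrt{\pi}}
     e^{-[a_I (q_{I,\mathrm{eff}} - b_I)]^2}
     \left[ \frac{\partial q_I}{\partial R_A} (1 + k_I \mathrm{CN}_I)
          + q_I k_I \frac{\partial \mathrm{CN}_I}{\partial R_A} \right]. $$

Setting $a_I = 0$ for every element makes all chain terms exactly zero and
reproduces the static-radius model bit for bit (a test asserts this).

## Parameters

| Parameter | Units | Default | Role |
|---|---|---|---|
| `epsilon` | — | 78.4 | solvent dielectric; `Inf` = conductor limit |
| `scheme` | — | `isogrid` | cavity discretization (see below) |
| `n_leb` | points | 194 | Lebedev order per sphere (isogrid) |
| `rho_leb` | pts/Å² | 7.5 | target surface density (isodensity) |
| `f_min` | — | 1e-8 | switching screening threshold |
| `cn_shift` | bohr | 2 | additive constant in the CN long-range falloff |
| `r0` | Å | Bondi × 1.2 | base cavity radii |
| `rcov` | Å | covalent radii | CN distance scale |
| `chi, eta, alpha, kappa` | a.u. | per element | EEQ electronegativity, hardness, width, CN coupling |
| `a, b, k` | a.u. | per element | radius-scaling steepness, offset, CN coupling |

The per-element defaults shipped in the package are pragmatic choices —
Bondi-style van der Waals radii scaled by 1.2, covalent radii from standard
tabulations, and EEQ/scaling values chosen to give chemically reasonable
partial charges (for the water-like solute the EEQ defaults give
$q_\mathrm{O} \approx -0.66$, $q_\mathrm{H} \approx +0.33$) and radius
responses of a few tenths of a bohr.  They are model data, not constants:
every value can be overridden per element through `cpcm_params(elements =
...)` or a JSON config (`load_parameters()`).  The EEQ right-hand side uses
$-\chi_I + \kappa_I \sqrt{\mathrm{CN}_I}$, with
$\sqrt{\mathrm{CN} + 10^{-14}}$ smoothing so isolated atoms cannot produce
singular derivatives.  The `cn_shift` constant carries length units; it is
interpreted in bohr, consistent with all-atomic-unit internals, and is
configurable — any fixed smooth interpretation yields a correct,
finite-difference-verifiable gradient.

Solute charges are a fixed input (their nuclear derivative is zero); the
EEQ charges that drive the radius scaling are a separate, geometry-dependent
quantity with their own analytic Jacobian.  Any charge provider exposing
`(q, jacobian)` with charge conservation and translational invariance can
replace EEQ (`fixed_charges()` is the degenerate second implementation).

## Cavity schemes and width calibration

* **isogrid** (default): one Lebedev order for every sphere.  The grid
  deforms smoothly with the radii, so the PES stays continuous.
* **isodensity**: per sphere, the packaged order closest to
  $\rho\, 4 \pi R_I^2$.  When a radius crosses the midpoint between two
  packaged orders the grid switches abruptly; with geometry-dependent radii
  this makes the energy discontinuous.
* **isodensity-frozen**: isodensity orders chosen at the first geometry and
  then held fixed (`frozen_orders`), restoring continuity.

`bond_scan()` quantifies this on a water-like triatomic stretched from
0.8× to 2.0× of its equilibrium bond with the trapezoid defect
$|E_{k+1} - E_k - \tfrac12 (g_k + g_{k+1}) \Delta r|$: at
$10^{-3}$ Å steps the isogrid defect stays below $10^{-8}$ hartree
(measured: about $4 \times 10^{-11}$), while the isodensity scan jumps by
several orders of magnitude exactly at its grid-switch step.

$\xi_\mathrm{Born}$ is not a hard-coded table: `calibrate_xi_born()` finds,
per Lebedev order, the root of "single-sphere conductor energy $+\,1/(2R)$"
by bracketed search on $[1, 10]$, to a residual below $10^{-12}$.  The
discretized single-sphere energy scales exactly as $1/R$, so the constant
is dimensionless and radius-independent; it is cached per order for the
session.  After calibration the Born energy is exact to better than
$10^{-10}$ at every tested radius, and an off-centre charge in a conductor
sphere reproduces the classical image-charge energy
$-\tfrac12 R/(R^2 - d^2)$ to a relative error of about $10^{-5}$ at order
590.

## Numerical choices

* **Lebedev grids** are stored as octahedral orbit generators (type,
  generator coordinates, weight) and expanded in code; constrained
  coordinates are recomputed from the unit-norm condition, so points sit on
  the sphere to machine precision.  Weights are normalized to sum to 1 per
  unit sphere.  The packaged orders are 6–770; the **74-point rule carries
  a negative weight** — fine for quadrature, unusable for Gaussian widths
  $\xi_i \propto 1/\sqrt{w_i}$ — so cavity construction rejects it and
  isodensity selection skips it.
* **Point orientations are fixed in the laboratory frame**: the $u_i$ do
  not rotate with the molecule.  The gradient derivation assumes exactly
  this; rotational invariance of the energy holds only to discretization
  accuracy and is documented rather than asserted.
* **Screening**: points with $F_i <$ `f_min` $= 10^{-8}$ are excluded from
  the linear system and the gradient.  A test verifies that keeping all
  points changes the energy by less than $10^{-10}$ hartree, so activation
  events do not break smoothness at the tested scale.  Elementary switching
  factors that underflow to zero mark points buried far beyond the
  threshold; their switching derivative is set to zero (the value is flat
  zero in a whole neighbourhood).
* **Dense symmetric solve**: the system is solved by Cholesky factorization
  (with a guarded fall back to a general solve); no iterative solver is
  needed at desk scale ($\lesssim 10^4$ points).  The solve residual
  $\lVert A q + f_\varepsilon v \rVert_\infty$ is verified below
  $10^{-10}$.
* **The A-matrix derivative is never materialized.**  The off-diagonal
  contraction $q^\top (\partial A / \partial R_A) q$ is collapsed onto
  per-point coefficient vectors, so the $O(n^2)$ pair work is done once per
  gradient, not once per atom.
* **Finite-difference oracle**: the four-point central formula with
  $\delta = 5 \times 10^{-3}$ bohr, rebuilding the entire pipeline
  (charges, CN, radii, cavity, calibration cache) at every displaced
  geometry, without a translational-invariance shortcut.  For the *raw*
  derivative layers (switching values, surface potential) the fifth
  derivatives are much larger than for the energy, so those suites use
  $\delta = 10^{-3}$ bohr; the measured deviation scales as $\delta^4$,
  confirming that the residual is oracle truncation, not analytic error.

## What the generated test systems do and do not show

The test molecules are synthetic: a rigid water-like triatomic with fixed
classical charges (O $-0.834$, H $+0.417$) and seeded random clusters of
H/C/N/O atoms in a 7-bohr box with a 2.2-bohr minimum separation and random
solute charges summing to zero.  They exercise every term of the model —
overlapping spheres, buried points, charge and CN chains — at the problem
sizes the suites use (3–8 atoms; Lebedev orders 26 for the
finite-difference suites, 194 for the headline checks, 590 for the
image-charge limit; scans of 1201 steps).

What passing tests show: the implemented gradient is the exact derivative
of the implemented energy, the discretization reproduces closed-form
conductor results, and the PES continuity contrast between schemes is real.
What they do not show: agreement with any quantum-mechanical reference
(there is no electronic density here — the potential is purely nuclear), or
solvation free energies of real molecules (the shipped element parameters
are plausible defaults, not a fit to experiment).  One known artifact of
the EEQ model is inherited deliberately: at large separations it keeps
fractional charges on fragments, so the direction of the radius response
along a bond stretch depends on the parametrization.  With the shipped
defaults the stretched H sphere shrinks (its charge relaxes toward zero);
with other parameter sets it can grow.  The continuity phenomenology only
requires that radii change materially along the scan, which they do (a few
tenths of a bohr).

## Limitations

* Classical point-charge solutes only: no SCF coupling, no electronic
  potential term, no response of the solute charges to the solvent.
* Van der Waals cavities only (no solvent-accessible or solvent-excluded
  surfaces); no non-electrostatic terms.
* Dielectric scaling is fixed at $x = 0$; the conductor limit is the
  `epsilon = Inf` sentinel.
* The analytic Hessian is not implemented; second derivatives can be
  obtained by finite differences of the analytic gradient.

## A minimal session

```{r example}
fit <- cpcm(water_molecule(), cpcm_params())
summary(fit)
```
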