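---
title: "Models and numerics behind vesselfem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerics behind vesselfem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(vesselfem)
```

vesselfem simulates steady, laminar, incompressible blood flow through
two-dimensional channels carrying serial stenoses (wall intrusions) or serial
aneurysms (wall bulges), and extracts the hemodynamic severity indicators used
to compare the two lesion families: axial velocity and pressure profiles, wall
shear stress (WSS), recirculation zones and percent-deviation metrics.  This
vignette records the models, the parameter choices with their rationale, the
numerical design, and what the accompanying verification suite does and does
not demonstrate.

## Vessel geometries

Both vessel models are mirror-symmetric about the channel axis (`y = 0`) with
healthy half-height `R0 = 1` (inlet height `D = 2`).  A cosine stenosis of
depth `eps` over the interval `[xc - Ls/2, xc + Ls/2]` has wall half-height

```
y(x) = 0.5 D (1 - (eps/D) (1 + cos(pi M(x)))),   M(x) = 2 (x - xc) / Ls,
```

so the throat (half-height `0.5 D - eps`) sits exactly at the lesion center
and the profile is C0-continuous at the lesion ends.  `M(x)` maps the lesion
interval to `[-1, 1]`; this is the standard cosine-stenosis construction and
the only reading that keeps the profile continuous with the throat at the
center.  An aneurysm over `[l0, l0 + la]` scales the healthy radius by the
quartic ratio

```
h_a(t) = 1 + eps/(2 R0) (11 t - 47 t^2 + 72 t^3 - 36 t^4),  t = (x - l0)/la,
```

which vanishes at both lesion ends and carries two symmetric apex humps near
`t = 1/6` and `t = 5/6`.  Note that the midpoint excursion of this polynomial
is `eps/(4 R0)` — smaller than the humps; `lesion_landmarks()` reports the
polynomial's true extrema (found by golden-section refinement of a dense
scan) rather than any nominal midpoint height.

Defaults, chosen once: two lesions of unit length (`Ls = la = 1`), centers
two units apart, `eps = 0.5` for both models (a 50% radius reduction is the
canonical moderate-to-severe stenosis; the matching bulge raises the local
radius by up to ~21%), and entrance/exit runs of three channel heights so the
inlet profile develops and the outflow condition sits far from the last
lesion.  Total channel length 15.  All of these are arguments of
`stenosis_spec()` / `aneurysm_spec()`.

## Governing equations and constitutive cases

The steady dimensionless system on the channel `Omega` is

```
div U = 0
Re (U . grad) U = -grad p + beta Lap U + div sigma + f
Wi (U . grad) sigma + sigma = 2 mu_v* V(U) + Wi [ (grad U) sigma + sigma (grad U)^T ]
```

with `V(U) = (grad U + grad U^T)/2`, shear rate `gamma_dot = sqrt(2 V:V)`
(the second-invariant definition, which reduces to `|dU/dy|` in simple
shear), solvent coefficient `beta = mu_n / (mu_n + mu_v)` and dimensionless
polymer viscosity `mu_v* = mu_v / (mu_n(inf) + mu_v)`.  The extra stress
`sigma` is symmetric with components `(s11, s12, s22)` and is transported by
the upper-convected derivative, whose steady homogeneous-shear solution
`s11 = 2 mu_v* Wi gamma_dot^2`, `s12 = mu_v* gamma_dot`, `s22 = 0` doubles as
the inlet boundary data and as an exact verification fixture.

Four constitutive cases share this system:

| case | solvent viscosity `mu_n` | extra stress |
|------|--------------------------|--------------|
| Newtonian (N) | `mu_inf` | off |
| generalized Newtonian (GN) | Cross `mu(gamma_dot)` | off |
| Oldroyd-B (OD) | `mu_inf` | on |
| generalized Oldroyd-B (GD) | Cross `mu(gamma_dot)` | on |

The generalized Cross law
`mu = mu_inf + (mu0 - mu_inf) / (1 + (lam gamma_dot)^b)^a` uses the standard
whole-blood fit `mu0 = 0.16 Pa s`, `mu_inf = 0.0036 Pa s`, `lam = 8.2 s`,
`a = 1.23`, `b = 0.64`, with blood density `rho = 1050 kg/m^3`.  The polymer
viscosity is never fixed by the blood parameter set; vesselfem takes
`mu_v = mu_inf` for the elastic cases, giving the symmetric split
`beta = 1/2` in the infinite-shear limit.

## Scales

The study operates on dimensionless knobs `Re` (up to 3000) and `Wi` (up to
1) while reporting velocity magnitudes of 0.06–0.15 and pressures of order
1–15.  vesselfem fixes the dimensional anchors once: the geometry unit length
is the healthy half-height (0.01 m of a 2 cm vessel) and one velocity unit is
1 m/s, so the simulated speeds (~0.06–0.15) are physical arterial speeds in
m/s and the Cross law is evaluated at the resulting physical shear rates
(tens of 1/s inside the lesions).  At those rates blood sits in its
shear-thinned regime, which is why the four constitutive cases produce
closely similar velocity fields — the behaviour the severity comparison
relies on.  Evaluating the Cross law instead at the nominal
Reynolds-characteristic rate (about 1 1/s at these velocity magnitudes) would
put the generalized cases near their zero-shear plateau, with viscosity
ratios of 2–6 and strongly blunted jets; that regime contradicts the premise
of arterial flow, and the revision away from it is a deliberate, documented
model choice.  The inlet mean velocity defaults to `Ui = 0.046`
(peak `1.5 Ui = 0.069`), the undisturbed healthy-section axial speed in these
units; with the 2 cm vessel this corresponds to a relaxation time
`lam_x = Wi L / U` of a few hundredths of a second at `Wi = 0.6`, a
physiologically sensible value for blood.

## Discretization

Mixed Galerkin finite elements on six-node (quadratic) triangles: velocity
and extra-stress components carry unknowns on all six nodes, pressure on the
three corner nodes (the Taylor–Hood-type pair that satisfies the inf-sup
condition).  Elements are straight-sided; curved walls are resolved by the
boundary polyline density.  All integrals use a 7-point degree-5 rule, exact
for products of quadratic bases and their gradients on affine elements.

Meshes are deterministic boundary-fitted grids: axial node columns graded
from `h_far` to `h_lesion` in a band around every lesion (by integrating an
axial density function), and `ny` element rows following the local wall
profile, so the narrowest throat always carries `ny >= 6` element layers.
Cell diagonals are mirrored between the lower and upper half so the mesh is
exactly symmetric under `y -> -y`; symmetric data then yield symmetric
discrete solutions to solver precision, one of the invariants under test.
There is no unstructured Delaunay generator behind this module: for channel
domains a graded mapped grid gives the same approximation power with exact
symmetry and reproducibility, which the tests rely on.

Weak forms follow the printed element-matrix structure of the discretized
system: the viscous term is assembled in gradient–gradient (Laplacian) form
`beta grad U : grad N`, and the extra-stress divergence is tested directly
(`- N div sigma`, not integrated by parts).  Two consequences are worth
noting.  First, with the Laplacian form the natural ("do-nothing") outflow
condition is `-p n + beta dU/dn = 0`, which fixes a zero outlet pressure
datum weakly and is exactly satisfied by fully developed channel flow — so
Poiseuille and fully developed Oldroyd-B states are reproduced to machine
precision, including their stresses.  Second, because no stress boundary
integral arises, the only stress boundary data needed are the inlet values,
which is also where the transport equation's characteristics enter the
domain.  For constant `beta` the Laplacian and symmetric-stress forms agree
on divergence-free fields; for shear-thinning runs they differ by a
`grad(beta)` term, and the Laplacian form is the modelled equation.  Wall
shear stress is postprocessed from the full deviatoric traction
`(2 beta V + sigma) n` regardless.

## Solver

The nonlinear system is solved by Newton iteration with an analytic Jacobian
(including the Cross-viscosity derivative via
`d gamma_dot / d grad U = 2V / gamma_dot`) and sparse direct factorizations.
A backtracking line search on the residual norm guards each step.
Convergence requires the summed absolute nodal increment of every field —
velocity, pressure, stress — to fall below `tol = 1e-5`, with a
relative-residual safety criterion (`1e-8`, or increment stationarity on two
consecutive iterations) so the absolute sum cannot silently pass on a stalled
residual.  Reynolds continuation (`100, 300, 1000, 2000, 3000` truncated at
the target) initializes each harder solve from the previous one;
`solve_case()` can return the intermediate states, which the Reynolds sweeps
reuse.  Because the Cross law has an unbounded slope at zero shear for
`b < 1`, its dimensionless closure evaluates at
`sqrt(gamma_dot^2 + 1e-10)`; this bounds the Newton linearization and
perturbs the viscosity only on a vanishing neighbourhood of zero shear.

Above `Re = 500` (configurable: `stabilize = "auto"/"on"/"off"`) the
discretization adds residual-based SUPG: the momentum equations are also
tested with `tau_m Re (U . grad N)` against their strong residual (available
element-wise because P2 Laplacians and P1 pressure gradients are
element-constants), and the stress equations with the advection-perturbed
weight `N + tau_s Wi (U . grad N)`.  Both weights are frozen at the current
iterate inside the Jacobian (a standard quasi-Newton treatment; the residual
stays consistent, so converged solutions are unpolluted — on developed
channel flow the stabilized and plain solutions agree to `1e-10`).
Verification solves run with stabilization off so analytic comparisons are
clean.

## Postprocessing definitions

* Axial profiles sample `|U| = sqrt(u^2 + v^2)` and `p` on `y = 0`.
* Extrema masks: one channel height excluded at each end ("masked"); the
  closed interval between the two lesion centers ("between"); the lesion
  span from the first lesion start to the second lesion end ("span").  The
  severity metric is `100 (max - min) / max`.  For stenoses it pairs the
  masked maximum with the between minimum (hub vs inter-lesion trough); for
  aneurysms, with the masked minimum (the slowest axial flow sits inside a
  bulge).  The same formula applied to pressure extrema is reported as
  `p_pct_dev`, with the caveat that published pressure percentages for this
  configuration family could not be reverse-engineered from their printed
  extrema, so that column is descriptive rather than comparative.
* The "throat window" used when asserting that the global speed maximum sits
  at a stenosis is the lesion interval extended half a lesion length
  downstream: at these effective Reynolds numbers the attached jet core can
  peak just beyond the geometric lesion end on coarse meshes.
* WSS is `(sigma . n) . t` with `n` the wall normal pointing into the fluid
  and `t` the downstream unit tangent, so positive WSS drags the wall
  forward and negative WSS flags reversed near-wall flow.  Recirculation is
  detected twice — negative-WSS wall intervals and reversed near-wall axial
  velocity (probe at 90% of the local half-height) — and the two detectors
  must agree when the minimum WSS is non-negative.
* `flux()` defaults to the discretely conservative functional (axial velocity
  weighted by the gradient of a corner-interpolated ramp), which inherits
  exact station-independence from the discrete continuity equation; a direct
  per-element line integration is available as a cross-check.

## Verification, and what it shows

The verification module generates every fixture in code: Poiseuille flow
(exact for the discretization, so errors at solver precision), the steady
homogeneous-shear Oldroyd-B stress triple, and a divergence-free
trigonometric manufactured solution whose forcing closes the Newtonian
momentum equation exactly.  Grid convergence on the manufactured case over
three meshes must show an observed L2 velocity order of at least 1.8 and
pressure order at least 0.9 (quadratic/linear elements).  Manufactured
elastic cases are deliberately omitted: the stress equations are instead
verified through the exact channel states and the constitutive degeneracies
(GN with `mu0 = mu_inf` equals N; OD with `mu_v = 0` equals N; GD with
`mu0 = mu_inf` equals OD, all to `1e-10` nodally).

These checks validate the discretization and solver on steady, laminar,
rigid-wall, two-dimensional flows.  They say nothing about pulsatility,
vessel compliance, three-dimensional secondary flows, or patient-specific
lumen shapes — all outside this package's scope — and passing them does not
certify the physiological accuracy of the Cross/Oldroyd-B description of any
individual's blood.

## Problem sizes

The default lesion mesh (`h_far = 0.35`, `h_lesion = 0.15`, `ny` from the
lesion spacing) has about 1,700 six-node triangles (≈ 21,000 unknowns for the
elastic cases); a generalized Oldroyd-B continuation chain to `Re = 1000`
converges in a few minutes on one core.  The Reynolds sweeps use a coarser
chain mesh (`h_far = 0.45`, `h_lesion = 0.22`, `ny = 10`), and the test suite
exercises the same pipelines on reduced meshes (`h_far = 0.5`,
`h_lesion = 0.25`, `ny = 8`) chosen so the full suite stays in the
tens-of-minutes range.  All meshes, fixtures and runs are generated
programmatically; nothing is read from disk.

## Known limitations

* The published reference values this package re-derives are read off
  figure-level reports whose characteristic scales are not stated; the
  comparison therefore carries a documented scale ambiguity, and
  `paper_report()` exposes side-by-side discrepancies rather than hiding
  them.  In particular the reference axial-pressure extrema between stenoses
  imply stronger jets (larger Bernoulli excursions relative to the outlet
  datum) than this model family produces at the same nominal operating
  point.
* Steady formulation only; the Reynolds range is treated as laminar
  throughout, so high-`Re` results describe steady solutions of the laminar
  equations, not turbulence.
* Straight-sided elements limit geometric fidelity at very coarse `h` on the
  steep quartic bulge flanks; the mesher refuses lesions resolved by fewer
  than four columns.
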