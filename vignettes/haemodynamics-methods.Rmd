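---
title: "Estimating haemodynamic forces in microvascular networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating haemodynamic forces in microvascular networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plexusflow)
```

## The problem

During developmental angiogenesis — classically studied in the neonatal
mouse retina — a primitive capillary mesh remodels into a hierarchical
network of arteries, capillaries and veins, and the wall shear stress (WSS)
that flowing blood exerts on the endothelium is believed to steer which
segments regress and which mature. Vessels a few micrometres across cannot
be probed by flow measurement, so the forces must be computed: reconstruct
the lumen from an image, solve the flow, and read the stresses off the
solution. `plexusflow` implements that chain: 2D mask skeletonization with
maximum-inscribed-circle radii, implicit-surface voxelization of the
circular-cross-section tube model, a D3Q19 lattice-Boltzmann (LB) solver for
steady incompressible generalized-Newtonian flow with sub-grid wall
placement, and wall-traction post-processing — plus the inclined-cylinder
Hagen–Poiseuille suite that quantifies how much of the answer to trust at a
given lattice resolution.

## Blood rheology

Mouse blood is shear thinning. The package models the dynamic viscosity
with the five-parameter Carreau–Yasuda law

$$\eta(\dot\gamma) = \eta_\infty + (\eta_0-\eta_\infty)
  \left[1+(\lambda\dot\gamma)^a\right]^{(n-1)/a},$$

with a low-shear plateau $\eta_0$, a high-shear plateau $\eta_\infty$, a
transition time scale $\lambda$ (s), a transition sharpness $a$ and a
power-law index $n<1$. `fit_cy()` fits the law to viscometry data by
unweighted nonlinear least squares on viscosity (Levenberg–Marquardt), with
seeded multi-start from log-uniform draws because the problem has local
minima. One admissibility bound is imposed: the transition exponent is
restricted to $a \le 10$. On noisy tables the unconstrained least-squares
surface develops a competing, marginally deeper minimum with $a$ diverging
(an effectively discontinuous transition) and a high-shear plateau below
plasma viscosity — numerically valid, haemorheologically meaningless; the
bound removes it, after which every multi-start seed converges to the same
solution. The packaged `mouse_blood_viscosity()` table (11 adult-mouse
measurements from two strains, treated as one unweighted set) yields
$\eta_0 \approx 14.49$, $\eta_\infty \approx 3.27$ mPa s,
$\lambda \approx 0.18$ s, $a \approx 2.7$, $n \approx 0.41$. Fitting on the
viscosity scale (not log-viscosity) and unweighted was a deliberate choice:
it is what a plain least-squares fit of such a table does, and the recovered
plateaus are what the flow solver consumes. Haematocrit-dependent effects
(Fåhræus–Lindqvist, cell suspensions) are out of scope; blood is a
homogeneous fluid here.

```{r}
fit <- fit_cy(mouse_blood_viscosity())
fit
```

## The flow model and its discretization

The solver advances the single-relaxation-time (BGK) lattice-Boltzmann
equation on a D3Q19 lattice with $c_s^2 = 1/3$. Steady state of the LB
dynamics is the incompressible Navier–Stokes solution of a pressure-drop
problem: walls carry no-slip, the inlet and outlet caps carry prescribed
pressures (or, for benchmarks, a prescribed parabolic inflow), and the run
starts from a uniform-density fluid at rest.

Three discretization choices deserve explanation.

**Incompressible (He–Luo) equilibrium.** With density entering the
equilibrium only linearly and the momentum taken as the velocity variable,
the pressure field decouples from the momentum field. This matters more
than it may seem: at a fixed Reynolds number and relaxation time the
lattice-unit pressure drop across a narrow tube grows as the tube narrows
(at three sites across it reaches tens of percent of the reference
density), and with the standard compressible equilibrium that pressure
profile leaks into the velocity field and destroys the flow-rate accuracy
the method is otherwise capable of. A documented consequence: the
flow-rate error does *not* degrade for relaxation times above 1, where
compressible-equilibrium implementations see errors grow again; accuracy
here degrades only toward the stability threshold $\tilde\tau \to 1/2$.

**Interpolated no-slip walls with per-slab mass restoration.** Wall links
use the linear interpolated bounce-back of Bouzidi and co-workers: each cut
link stores the fractional distance $q \in (0,1]$ from the fluid site to
the true wall, the two standard interpolation branches apply for
$q < 1/2$ and $q \ge 1/2$, and at $q = 1/2$ the scheme reduces exactly
(bit for bit) to plain bounce-back. The interpolation is not mass
conserving link-by-link; in a tube three sites across the accumulated
defect reaches ~13% of the flow rate. The package therefore reinjects each
link's defect isotropically — spread over the fluid sites of the
cross-sectional slab the link sits in (per site for networks, which have no
slab structure). Spreading matters: restoring the mass *at* the
wall-adjacent site itself plants a steady point source exactly where the
stress tensor is read, and measurably corrupts the near-wall stress field;
spreading over the slab preserves the axial flux distribution at
machine-level accuracy while leaving the wall dynamics untouched.

**Link-wise velocity inlets.** Benchmark inflow is imposed the way moving
walls are: every link crossing the inlet plane reflects with a Ladd-type
momentum term evaluated from the parabolic profile at the exact crossing
point, and the link terms are normalized so their quadrature carries the
analytic flow rate $Q = v_{max}\pi R^2/2$ exactly (at three sites across a
raw staircase quadrature misses a sizeable fraction of $Q$). A site-overwrite
velocity cap — prescribing equilibrium-plus-extrapolation populations on a
slab of sites — was implemented first and rejected: on an oblique staircase
cut it under-delivers the prescribed flux by tens of percent, because only
half of the interface populations are constrained. Pressure caps hold the
target density with non-equilibrium extrapolation from the interior
neighbour and are robust on one-voxel-thick caps.

### Units and calibration

All user-facing quantities are physical (µm, mmHg, mm/s, Pa); lattice
units are internal. Viscosity maps to the relaxation time through
$\tilde\nu = (\eta/\rho)\,\Delta t/\Delta x^2$,
$\tilde\tau = 3\tilde\nu + 1/2$. The time step is calibrated so that the
high-shear viscosity sits exactly on the empirically best relaxation time,
$\tilde\tau(\eta_\infty) = 0.8$; the low-shear plateau then lands at
$\tilde\tau(\eta_0) = 0.5 + 0.3\,\eta_0/\eta_\infty \approx 1.83$, which is
acceptable because those sites are slow-flow regions. In shear-thinning
mode the shear rate is evaluated locally from the non-equilibrium
populations ($S \propto -\Pi^{neq}$, $\dot\gamma = \sqrt{2S\!:\!S}$, no
finite differences), the viscosity from the fitted law, and the per-site
relaxation time is clamped to a stability window with every clamp counted —
a correctly calibrated run reports zero clamps. Blood density defaults to
1050 kg/m³ (not part of the viscometry data; configurable), and
mmHg-to-Pa conversion uses 133.322.

### Convergence

The run is declared steady when the maximum per-site velocity change per
step, scaled by a reference velocity, falls below a tolerance:
$\max_x |v(x,t) - v(x,t-\Delta t)|/v_{ref} < \epsilon$. The max norm was
chosen over an L2 norm as the stricter of the two. The reference velocity
defaults to 50 mm/s, a typical peak retinal velocity; for weakly driven
test fixtures a commensurate $v_{ref}$ should be supplied, otherwise the
criterion is effectively looser than nominal. The default
$\epsilon = 10^{-5}$ suits physiological runs; the package's own tests
verify that tightening from $10^{-5}$ to $10^{-7}$ moves measured flow
rates by well under 0.5%. The inflow/outflow balance reported for network
runs is computed from the exact link-level mass exchange between each cap
and the fluid, so it reflects the convergence residual rather than the
noise of a Riemann flux estimate.

## Geometry: from mask to lattice

`skeletonize_mask()` reduces a binary lumen mask to a centreline graph by
morphological thinning, with the maximum-inscribed-circle radius read off
the Euclidean distance transform at every centreline pixel — the same
radius semantics as a Voronoi medial axis, but more robust on raster
masks. Terminal spurs shorter than twice the local radius are pruned and
runs of adjacent junction pixels are merged into single branch points; both
rules are configurable because the "right" values depend on mask quality.

`voxelize_network()` samples the implicit union of capped cylinders
(piecewise-constant radius per segment, spheres of the largest incident
radius at the nodes to guarantee watertight junctions) on a regular grid
with voxel centres at $(i+\tfrac12)\Delta x$; no intermediate surface
triangulation is needed, since the solver consumes voxels. Wall distances
$q$ come from bisection on the implicit surface (24 iterations), and for
the analytic cylinder benchmarks from the exact ray–cylinder intersection;
the two agree to $10^{-6}$. Segments thinner than 3 lattice sites are
clamped up to that diameter and flagged — below three sites across the flow
solution is not trustworthy at all.

`choose_voxel_size()` implements the resolution rule used for whole-network
runs: the largest $\Delta x$ such that at least 95% of the total centreline
length lies in vessels at least 3 sites across (a length-weighted
quantile); the thinnest tail is knowingly sacrificed.
`diameter_histogram()` aggregates centreline length per diameter bin and
fits a lognormal by length-weighted maximum likelihood; its mode
$e^{\mu-\sigma^2}$ estimates the typical capillary diameter.

## What the solver is known to get right (and wrong)

The validation suite runs steady Newtonian flow at $Re = 1$ (defined with
the mean velocity, $Re = \bar v D/\nu$, consistent with microcirculation
values) through cylinders whose axis is drawn uniformly from the sphere
subject to a 15° minimum inclination from every lattice plane — the
hostile case for a regular grid. Cylinder length is four diameters with
all error metrics on the middle half, standard entrance-length hygiene.
Flow rate is measured as the mean of per-plane Riemann sums over
lattice-aligned planes in the middle half, since the flux through every
cutting plane is equal at steady state and single staircase cuts carry a
few percent of quadrature noise at three sites across.

At $\tilde\tau = 0.8$ the relative flow-rate error stays below 3% down to
three lattice sites across (about 2.5% there, under 1% from five sites
up). The deviatoric stress tensor, computed locally from non-equilibrium
populations as $T = -(1-\tfrac{1}{2\tilde\tau})\,\Pi^{neq}$ (deviatoric
projected) and compared with the rotated analytic Poiseuille tensor under
the component-wise Frobenius norm, shows the characteristic pattern:
largest error against the wall, overestimation in the inner part of the
near-wall shell ($[0.8R, 0.9R]$) and underestimation at the wall, with a
maximum around 7–9% at seven sites across, improving to about 4% at
fifteen. Flow-rate and stress accuracy are decoupled: at three sites
across the flow rate is fine while the wall stress is not, which is why
network post-processing flags WSS values as `valid` only where the local
vessel is at least 7 sites across, and why WSS magnitudes above 20 Pa —
the upper bound of microvascular WSS reported in vivo — are flagged
`unphysiological` rather than silently reported.

Two published reference behaviours are *not* reproduced, both because this
implementation is cleaner than the solvers the references were measured
with: the flow-rate error does not grow again for $\tilde\tau > 1$ (a
compressible-equilibrium artifact, see above), and the maximum near-wall
stress error at fifteen sites across is ~4% rather than ~7% (a more
isotropic lattice, the incompressible equilibrium and exact mass
restoration all help). The direction of both deviations is toward the
analytic solution.

## The synthetic plexus

`generate_synthetic_plexus()` builds the package's end-to-end fixture: two
parallel trunks (defaults 16 and 20 µm, arterial and venous calibre), `n`
capillary rungs plus a distal arcade anastomosis (so the graph has exactly
`n` independent cycles), rung spacing 30 µm, trunk separation 100 µm, and
lognormal capillary diameters with a mode near 5 µm — numbers chosen once
to match the capillary-scale geometry of a small neonatal plexus region.
It emulates the *topology and calibre statistics* of a plexus, not its
real geometry: no tortuosity, no diameter taper, no sprouting front, a
single inlet and outlet. Passing the end-to-end tests on it demonstrates
that the pipeline conserves mass, produces physiological velocity and WSS
scales under the default arterial/venous pressures (68.2/11.6 mmHg, mean
arterial and intraocular pressure of adult mice), and flags implausible
stresses — it does not demonstrate fidelity to any particular animal's
retina, which requires real image data.

Problem sizes used throughout the tests and the validation scripts: the
benchmark cylinders span 3–15 sites across (roughly 80 to 10,000 fluid
sites), the synthetic plexus discretizes to ~65,000 fluid sites at the
automatically chosen voxel size (~1.2 µm), and full runs converge in a few
thousand steps.

## Degenerate inputs and numerical edges

Zero shear rate evaluates the viscosity law at its plateau exactly; equal
plateaus short-circuit to a Newtonian fluid. A zero pressure difference
converges immediately to rest. Tensor error norms against a zero-norm
reference (the cylinder axis) return `NA` and are excluded from shell
statistics rather than propagating infinities. Masks with several
foreground components keep the largest with a warning; empty masks and
skeletons without designated inlets error out before any computation.
Cut links whose upstream interpolation partner is missing fall back to
plain bounce-back for that link. Prescribed lattice velocities above 0.1
warn (compressibility) and above 0.3 error out.

## Limitations

Steady flow only (no pulsatility — justified for retinal microcirculation
by Womersley numbers around 0.1, but WSS does vary within a cardiac
cycle); rigid walls, no autoregulation; homogeneous fluid (no red-cell
suspension effects, which can raise capillary WSS by ~20%); circular
cross-sections (supported for arteries, weaker for veins); single-threaded
solver intended for vessel-scale problems, not whole-organ meshes.
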