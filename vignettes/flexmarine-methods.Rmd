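---
title: "Numerical methods and design choices in flexmarine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Numerical methods and design choices in flexmarine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`flexmarine` composes a hydrodynamic solver, tracer transport, a
text-configurable equation solver, a surface heat budget, Lagrangian
agents and offline forcing on one spatial substrate: a 2D orthogonal
unstructured mesh with z-layers. This vignette is the package's own
account of the numerics — the assumptions behind each module, the
parameters that matter, the choices made where the design was genuinely
open, and what the test suite does and does not demonstrate.

## The mesh and its dual

A mesh is nodes plus polygon connectivity. Each polygon gets a Voronoi
point — computed as the least-squares circumcenter, the point minimising
the variance of squared distances to the vertices, which is the exact
circumcenter for triangles, rectangles and regular polygons. The segment
joining the Voronoi points of two adjacent cells must be perpendicular to
their shared face; `check_orthogonality()` reports the worst angular
deviation and `build_mesh2d()` rejects meshes beyond a tolerance
(default 0.5°, a conventional mesh-quality bound; the dynamics assume
orthogonality, so a looser tolerance trades accuracy knowingly). A
Voronoi point falling outside its polygon is flagged with a warning
rather than silently accepted — such cells are legal but degrade the
two-point flux approximation.

Vertically, layer interfaces are fixed depths (surface = 0, positive
down). A cell is wet iff the layer's top interface lies above the local
bathymetry; the bottom cell is clipped to the bathymetry (partial bottom
cell) rather than stair-stepped, so the wet volume equals the integral of
depth over area to round-off — a property the suite asserts at 1e-10
relative. If the bathymetry exceeds the deepest interface, the bottom
layer extends down to it.

Polygon orientation is normalised to counter-clockwise on input.
Degenerate polygons (zero area, collinear vertices) are rejected at
construction. Point location uses ray casting with boundary points
counted inside and ties resolved to the lowest polygon index, so location
is deterministic.

## Hydrodynamics

The solver is hydrostatic and semi-implicit. Face-normal momentum gets an
explicit tendency — advection, horizontal and vertical diffusion,
Coriolis, baroclinic pressure, wind, bottom drag — combined with
Adams–Bashforth-2 weights (first step: forward Euler, the standard AB2
seed), plus a θ-weighted free-surface gradient. Substituting into
depth-integrated continuity gives a symmetric positive-definite system in
the new elevation, solved by Jacobi-preconditioned conjugate gradients to
a relative residual of 1e-12 (default; `pcg_tol`). After the velocity
update, the elevation is recomputed from the θ-weighted discrete fluxes —
identical to the linear-system solution in exact arithmetic, but exactly
volume-conservative in floating point, which is why closed-basin volume
drifts are at machine precision rather than at the solver tolerance.

Choices made where more than one discretisation is defensible:

* **Momentum advection** is flux-form first-order upwind applied to the
  cell-centred velocity reconstruction (the same upwind operator the
  tracers use), corrected to advective form so a uniform flow has
  identically zero tendency, and projected back to faces by averaging the
  two adjacent cells. Upwinding face-normal components directly on an
  unstructured dual has no canonical stencil; routing it through the
  reconstruction keeps one upwind operator in the package and preserves
  the free-stream property, which the suite checks to 1e-14. Vertical
  momentum advection is omitted — at the shallow, hydrostatic scales the
  package targets it is negligible against vertical diffusion; this is a
  known limitation.
* **Coriolis** needs the tangential velocity at a face; it is taken from
  the mean of the two adjacent cell-centre reconstructions. The
  reconstruction is a per-cell least-squares fit of a velocity vector to
  the face-normal samples, weighted by face length — exact for any linear
  field on rectangular cells.
* **Viscosity** is laminar (`nu_h`, `nu_v`, user-set, default 0) plus an
  optional Smagorinsky term `(C_smag · sqrt(area))² |S|` with `|S|` the
  strain-rate magnitude of the reconstructed field. The vertical closure
  is a user-set constant; a computed vertical closure is an extension
  point, not present.
* **Equation of state**: linear,
  `rho = rho0 (1 − alpha_T (T − T0) + beta_S (S − S0))` with
  `alpha_T = 2e-4 /K`, `beta_S = 8e-4 /PSU` about (10 °C, 35 PSU) —
  adequate for the density contrasts of the shipped configurations; the
  EOS is a config block so a full nonlinear form can be swapped in.
* **Drag**: quadratic bottom stress `−C_bottom |u| u / h` on the bottom
  wet layer, wind stress `τ/(rho0 h)` on the surface layer.
* **θ**: 0.5 by default (second-order, energy-neutral on the seiche);
  the suite verifies that damping at fixed dt is minimal at 0.5 among
  {0.5, 0.75, 1.0} and that θ ≥ 0.5 runs stay bounded. Fully implicit
  θ = 1 is the practical choice for spinning up steady states, and the
  open-boundary throughflow test uses it for exactly that reason.
* **Degenerate 0D meshes** (no interior faces) evolve a cell-centred
  velocity vector under Coriolis, wind and drag with the same AB2
  machinery, and the surface responds only to volume sources. This is
  the box-model limit; the inertial-oscillation check (period 2π/f to
  1%) runs in this mode.

The free-surface matrix is assembled once and cached per (θ, dt,
boundary-set); face cross-sections are evaluated at the undisturbed level
(linearised free surface), while cell volumes carry the full elevation —
consistent, and exact for the small-amplitude regimes the package
targets.

## Tracer transport

Horizontal advection is first-order upwind (a flux-limited scheme is an
extension point, deliberately not present); at a face with exactly zero
velocity the upwind value is the two-sided mean — irrelevant for the flux
(which is zero) but it keeps the scheme symmetric. Horizontal diffusion
is a centred two-point flux along the Voronoi segment — this is where
mesh orthogonality is assumed. Vertical velocities are diagnosed from
layer-wise continuity (bottom-up), with the surface layer absorbing the
column divergence; when coupled to the hydrodynamics the tracer step uses
the θ-weighted transport velocities and the old/new cell volumes, which
makes a spatially uniform tracer an exact steady state of the coupled
discretisation (asserted to 1e-12).

The explicit scheme enforces an outflow-volume Courant number ≤ 1 and
aborts with the offending value and a suggested dt. The vertically
semi-implicit scheme treats vertical upwind advection and diffusion fully
implicitly (one tridiagonal solve per column; θ-weighting of the vertical
operator was considered and fully implicit chosen — unconditional
stability and the M-matrix sign structure, at the cost of first-order
vertical time accuracy). The M-matrix property means the implicit solve
preserves positivity at any vertical Courant number, where the explicit
update would oscillate; the suite demonstrates both halves.

Negative concentrations arising from round-off in variables flagged
nonnegative are clipped to zero with the clipped mass accumulated in a
`clip_error` attribute — accounting, not hiding. Moving sources snap to
the polygon containing their current position each step; source loads
default to the surface layer (freshwater buoyancy logic), with bottom,
uniform and fixed-layer options.

## The equation DSL

The grammar (EBNF in `R/dsl.R`) covers arithmetic, comparisons (yielding
0/1 and usable as gates), and the functions `exp log sqrt abs sin cos
tanh step pow min max ifelse`. Parsing is recursive descent with
positions in error messages; validation rejects undeclared symbols, wrong
arities and cyclic auxiliaries (reporting the cycle). Compiled
expressions evaluate vectorised over cells, so a 3D field costs one R
expression evaluation per step. Integration is forward Euler at the
module sub-step (RK4 optional); stiffness is the user's responsibility,
with a diagnostic warning when `|dt·RHS/C| > 0.5`. A cell-locality
invariant — identical trajectories in 0D and in a quiescent 3D run — is
part of the suite, as is a 50-expression parser-vs-direct-evaluation
property test at 1e-12.

Settling is upwind between layers with the bottom-cell flux deposited
(per area) into the top benthic layer of the declared target;
resuspension erodes at `E (τ/τ_crit − 1)` capped by the available pool;
interface exchange uses a piston velocity against the porewater-
equivalent concentration `B/h_b`. All three are antisymmetric transfers,
so pelagic + benthic inventories are conserved to round-off (asserted
over 10⁴ steps at 1e-10). The benthic stack is N layers per polygon;
lateral benthic transport is not modelled.

## Heat budget

Two modes. Fick: `Q = k (T_air − T_surf)` into the surface layer; the
closed-basin relaxation toward air temperature has e-folding time
`rho_cp · h / k`, verified to 1%. Bulk: clear-sky shortwave from solar
declination and hour angle times an atmospheric transmission (default
0.7), cloud factor `(1 − 0.62 C)`, albedo 0.06; sensible and latent
fluxes proportional to wind speed and the temperature/humidity gradients
(transfer coefficients 1.3e-3 / 1.5e-3); net longwave from a
Stefan–Boltzmann formula with vapour-pressure and cloud-squared
corrections. Humidity may be given as relative humidity or dew point
(Magnus conversion).

Absorption: flux decays to `e⁻¹` of its value over one penetration depth
(the e-folding convention makes "penetration depth ≈ Secchi depth"
quantitative); at the bottom, the reflected fraction is absorbed
exponentially upward and any residual reaching the surface is spread
uniformly. With bottom reflectivity < 1 the unreflected remainder heats
the bottom layer, so the budget closes *exactly* for every column and
flux sign — the suite asserts closure at 1e-12 and checks that column
heat content tracks the integrated surface budget over 10⁴ steps. Solar
and non-solar fluxes share one penetration depth; a separate solar
extinction is a documented extension point.

## Agents

Velocities are interpolated by linear reconstruction: cell-centre value
plus a least-squares gradient from neighbouring centres — exact for
uniform and linear fields (solid-body rotation), which is what makes the
closed-orbit test meaningful (return distance < 1% of the radius after a
full period with RK2 midpoint sub-steps at Ω·dt = 0.02). Diffusion is a
displacement of uniform random direction and magnitude `sqrt(4 K_h dt)`
horizontally and `sqrt(2 K_v dt)` with random sign vertically; with
spatially varying diffusivity this naive walk is biased (no Visser
correction) — documented limitation, consistent with treating the random
component as uniform.

Boundary handling uses an end-point test: if a sub-step lands outside the
wet domain, the agent returns to the Voronoi point of its last wet cell
at unchanged depth (clipped to the local bathymetry), or is deactivated
when the last wet cell touches an open boundary in sink mode. An
end-point test can step *over* a thin obstacle at very long sub-steps —
the deviation risk of this choice; sub-stepping (`substeps`) is the
mitigation. The vertical walls reflect rather than clamp, which is what
keeps a uniform vertical distribution uniform — the well-mixed condition,
checked with a KS test.

Reproducibility: one seeded RNG stream with draws in fixed agent order
per sub-step; identical seeds give bit-identical trajectories (asserted).
Connectivity is censused at simulation end by default (a DSL deactivation
criterion provides settlement-style censusing); rows span the regions
plus a "lost" column and sum to 1.

## Offline hydrodynamics

Snapshots (full face fields, or uniform speed/direction profiles
broadcast onto face normals) are interpolated linearly in time, exact at
snapshot times, with no extrapolation. Interpolated fields are not
re-projected to discrete non-divergence; the transport step's continuity
diagnosis absorbs column divergence at the surface, and the round-trip
test (online-coupled vs written-out-and-replayed transport) bounds the
temporal-interpolation error instead. The wind-dependent vertical
diffusivity is a power law `a·W^b + K_background` (defaults `a = 1e-4`,
`b = 1.5`, `K_background = 1e-5` m²/s — a conventional magnitude for
wind-mixed coastal surface layers), optionally surface-weighted with an
e-folding depth.

## Runtime, formats, fixtures

Module order within a step is fixed and part of the contract: forcings →
hydro/offline → heat → tracer transport → equation systems (timestep,
settling, resuspension, exchange) → agents → output. Setup validation
reports *all* configuration errors at once (the alternatives rule for
hydrodynamic providers, missing boundary series for advected variables
when open boundaries exist, dangling file references). All formats are
documented delimited text — mesh tables, time series, per-polygon fields,
offline snapshot blocks — chosen for diffability and zero binary
dependencies; `write_mesh_text`/`read_mesh_text` round-trip bit-for-bit.
The single-threaded implementation keeps runs bit-reproducible under a
seed.

The six fixture recipes are the package's study conditions: a 0D NPZD
box; the 50×1 seiche basin (5 km × 10 m, dt = 5 s); an open channel with
a clamped tracer front; a closed 2 km basin with a prescribed solid-body
gyre and three release regions for connectivity; a 1500 × 1050 m farm
domain with 50 m cells, 5 × 1 m layers, a 250 × 200 m farm block
filtering a boundary-supplied food tracer at 2e-4 s⁻¹ in a 5 cm/s
throughflow with 1 m²/s lateral mixing; and a two-fraction sediment plume
(Stokes fall velocities 3.9e-3 and 7.3e-5 m/s for 66 µm and 9 µm grains
at 1650 kg/m³ excess density) released mid-column into a 5 cm/s current.
These emulate the *structure* of real applications — they do not emulate
realistic forcing variability, stratification, tides or real coastlines,
so passing tests demonstrate correct numerics and conservative coupling,
not skill against field data. Pattern checks on the fixtures (farm wake
peak decaying downstream; the coarse fraction depositing nearer the
release than the fine) are qualitative by design.

## Problem sizes and tolerances used by the suite

Conservation checks run 10⁴ steps on small meshes (6×6×2 tracer basin,
10-layer column, 50×1 seiche) and assert drifts ≤ 1e-10 relative;
analytic limits use 1500–3000 steps (seiche period to 2%, inertial period
to 1%, diffusion second moment to 1%, Newton cooling to 1%); the ABM
statistics use 10⁴ agents. These sizes were chosen so each property is
measured well inside its tolerance while the whole suite stays quick to
run during development. `scripts/acceptance.R` recomputes the same
quantities end-to-end and writes them as JSON.

## Known limitations

No non-hydrostatic correction (the hydrostatic predictor is the whole
solver here), no wetting/drying, no waves or sea ice, no tidal-potential
forcing, first-order advection only, constant vertical viscosity, naive
random walk under inhomogeneous diffusivity, benthic pools without
lateral transport, and spherical/lon-lat metrics are out of scope (a
projection to local Cartesian metres is assumed upstream).
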