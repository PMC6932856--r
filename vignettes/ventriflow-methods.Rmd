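---
title: "Simulating ventricular flow and mitral regurgitation with ventriflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating ventricular flow and mitral regurgitation with ventriflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The model

`ventriflow` simulates blood flow inside a beating left ventricle (LV) whose
mitral valve (MV) may fail to seal, and quantifies the resulting
regurgitation. Three coupled components make up the model:

1. **Flow.** Incompressible Navier-Stokes for a Newtonian fluid
   (kinematic viscosity `nu = 0.04` cm²/s, the standard value for blood) on
   a staggered Cartesian grid, advanced with an explicit three-stage
   third-order Runge-Kutta scheme and a fractional-step pressure
   projection. Spatial derivatives are second-order central; advection uses
   the skew-symmetric (divergence + advective average) form, which
   conserves kinetic energy on the staggered grid. The box is periodic in
   x and y, a solid wall at the bottom, and an open (zero-pressure) face at
   the top.

2. **Moving geometry.** The LV endocardium, a basal plate closing the
   valvular plane, the two MV leaflets, an aortic orifice, and straight
   tube surrogates that extend both orifices to the top of the box (so
   inflow and outflow never mix outside the chamber) are all immersed
   boundaries: grid cells cut by a surface become impermeable no-slip cells
   that carry the local surface velocity. When surfaces overlap in a cell,
   the valve takes priority over the basal plate, then the LV wall, then
   the tubes.

3. **Valve dynamics.** Each leaflet has a single degree of freedom, an
   opening angle in `[0, pi/2]` interpolating between the closed and open
   configurations. The leaflets are assumed perfectly flow-following (no
   elastic recall): the angular rates minimize, in the least-squares sense
   over the valvular surface, the mismatch between fluid and leaflet
   velocity normal to the leaflet. This yields a 2x2 linear system whose
   coefficients are surface integrals of the configuration derivatives;
   off-diagonal entries vanish because the two leaflets move independently.
   Clamping at zero angle stands in for the chordae tendineae: the valve
   never opens toward the atrium. The aortic valve is a binary orifice: it
   opens when the MV is closed and flow is directed toward the aorta, and
   is otherwise a wall patch.

A passive scalar marks the blood present in the LV at end-systole
(`C = 1` inside the chamber, `0` elsewhere) and is transported with the
flow; one cycle later the fraction of marked blood still inside the
chamber is the residual volume, a washout measure. The regurgitation suite
integrates, over systole, the flux through the inter-leaflet orifice
(`Vreg`), the flux through the valve annulus (`VregMVa`), their difference
(the *false regurgitation*: blood in the valve cup pushed back to the
atrium by leaflet closure without ever crossing the orifice), and the
concentration-weighted orifice flux (`Vregold`, old-blood regurgitation).

# The synthetic geometry generator

No patient geometries ship with the package; a parametric generator
emulates the study conditions instead.

* **Ventricle.** A truncated prolate spheroid with the base plane at
  z = 0. Two presets: `healthy` (EDV 113.47, ESV 46.52 cm³, EF 59%) and
  `dilated` (EDV 199.31, ESV 142.50 cm³, EF 29%). The cavity volume tracks
  a prescribed waveform *analytically*: contraction scales the short
  semi-axes with an s-dependent weight that vanishes at the basal ring
  (the annulus stays put, as in imaging-derived ventricles) and a
  long-axis shortening carrying a fixed 10% of the volume change. The
  waveform is a raised-cosine systolic ejection (35% of the period)
  followed by an E-wave and an A-wave with a 2:1 filling ratio; the period
  is 1 s. Node velocities are exact time derivatives.

* **Valve.** Two leaflets spanning an annulus whose area matches the
  study values (healthy 6.20, P3-like 4.83, P2-like 4.26 cm²). The closed
  configuration is a coapting funnel; a Gaussian-shaped displacement of
  the posterior trailing edge creates a coaptation defect whose location
  mimics the Carpentier scallop (near the commissure for `P3like`,
  mid-leaflet for `P2like`) and whose amplitude scales with a `severity`
  parameter in `[0, 1]`, giving an effective orifice area (EOA) that grows
  continuously from zero. `severity_for_eoa()` inverts the map when a
  target EOA is wanted. The open configuration hangs the leaflets toward
  the apex; intermediate shapes rotate each node about the commissural
  hinge axis by the angle fraction plus a linear blend of the residual
  displacement, so the stored endpoints are reproduced exactly.

What the generator does **not** emulate: papillary muscles and chordae
geometry, annulus motion beyond a small long-axis drift, leaflet
thickness and elasticity, and the irregular wall shapes of real
ventricles. Passing tests on these shapes therefore validate the
numerics and the metric definitions, not patient-specific predictions.

# Numerical choices that matter

* **Fluid-only pressure projection.** The Poisson solve is restricted to
  fluid cells (zero-gradient closure at faces shared with cut or exterior
  cells, Dirichlet-0 above the tube mouths at the open top), solved by
  conjugate gradients preconditioned with an FFT(x,y) + tridiagonal(z)
  full-box solve. Only faces between two fluid cells receive the
  correction, so forced faces keep the boundary velocity exactly and an
  expanding chamber can draw fluid only through its orifices, never
  through its walls. A plain full-box FFT projection (which several
  immersed-boundary codes use) lets a sealed moving cavity exchange mass
  through the one-cell wall; with the fluid-only solve the global
  diastolic balance between the transmitral influx and the prescribed
  volume change closes to about 1-2% of the stroke volume on desk-scale
  grids. The default CG tolerance (`poisson_rtol = 1e-4`) leaves a
  residual compressibility orders of magnitude below that balance.

* **Wall tagging.** The LV wall is classified analytically: a cell is
  cavity if its center lies inside the axisymmetric radius profile, and
  the boundary band is the set of outside cells face-adjacent to inside
  cells. Rasterizing the surface instead (marking every cell the surface
  touches) biases the discrete cavity volume by O(h) and showed up
  directly as a ~15% stroke-volume deficit at h = 0.3 cm. Thin surfaces
  (leaflets, plate, tubes) are rasterized with sub-cell facet sampling;
  they are genuinely two-sided walls, so no volume bias arises.

* **Sub-grid valve aperture.** While both valves are discretely closed the
  chamber is a sealed fluid pocket and the prescribed wall motion is
  incompatible with incompressibility; the solver removes the mean defect
  over each sealed pocket (identified by connected-component labeling) and
  the leaflets are carried kinematically at the angular-rate cap
  (40 rad/s): opening while filling is prescribed, closing while ejection
  is prescribed. As soon as the aperture spans grid cells the flow-driven
  least-squares dynamics take over. Without this treatment the
  velocity-matching model deadlocks: a sealed valve sees no fluid motion
  and therefore never opens. The same reasoning opens the aortic valve at
  ejection onset, when the still-sealed chamber cannot yet produce the
  outflow its velocity criterion asks for.

* **Valve sampling offset.** The fluid velocity entering the valve system
  is sampled at one grid spacing on both sides of each leaflet quadrature
  point and averaged; sampling on the surface itself mostly reads back the
  leaflet's own forced velocity from the cut cells, making the dynamics
  self-referential and sluggish.

* **Tube sponge.** The top two or three grid layers damp tangential
  velocity strongly. The tubes are numerical surrogates; without the
  sponge the open-top inflow develops a tangential instability during the
  E-wave.

* **Scalar transport.** Second-order MUSCL (minmod) upwind advection with
  explicit diffusion, clipped to `[0, 1]`; the marker diffusivity defaults
  to `nu` (Schmidt number 1), matching the transport equation as the study
  states it, and is configurable because physical marker diffusivities are
  far smaller. The washout fraction is normalized by the marked volume at
  release time rather than the analytic ESV, which removes the O(h)
  cut-cell share from the ratio.

* **Orifice metrics.** The inter-leaflet orifice is built by
  arclength-proportional pairing of the trailing edges; the gap-segment
  velocity average uses 5 Gauss points per station; the edge-velocity term
  defaults to the mean of the two edge velocities (the half-difference
  reading is available via `edge_velocity = "half_diff"`). Flux toward
  the atrium is positive. The systolic window is wherever the prescribed
  dV/dt is negative, with boundary sampling intervals assigned by the sign
  at their midpoints.

* **Time stepping.** Adaptive dt at a CFL cap (default 0.5; the bundled
  verification and acceptance runs use 0.9, which the skew-symmetric RK3
  scheme tolerates) with the boundary-cell velocities included in the CFL
  rate. Simulations start from rest at end-systole with both valves
  closed — the E-wave then opens the valve and the systolic flow reversal
  closes it, which is far more benign than starting mid-ejection.

* **Upwind blend for under-resolved jets.** A regurgitant jet squeezed
  through a two-cell orifice at cell Reynolds numbers in the hundreds
  drives a grid-scale oscillation that the energy-conserving central
  scheme cannot damp; prolapse runs on coarse grids then crash. The
  momentum fluxes accept a local Lax-Friedrichs blend
  (`upwind_blend`, default 0 = pure central): the bundled prolapse runs
  use 0.05, the smallest value found to stabilize the jet across the
  severity range. Larger blends (0.15 and up) visibly damp the diastolic
  vortex and corrupt both the washout and the regurgitation signal, so
  the washout comparisons run with the blend off.

# Problem sizes

The bundled tests and the acceptance script run at desk scale, chosen so
the full suite completes on one CPU: coupled heartbeats on 24x24x36 to
32x32x48 grids (h around 0.23-0.31 cm), one cycle per case starting at
end-systole, valve surfaces 24x8 nodes per leaflet, LV surface 36x18 to
48x24. Verification cases (Taylor-Green decay, manufactured Poisson
solutions) run up to 64 cells per side. At these resolutions a coaptation
defect narrower than about two cells is blocked by the leaflets' cut
cells, so regurgitation studies are meaningful for normalized orifice
areas upward of roughly 10% of the valve area; the severity sweep bundled
with the package therefore spans the pathological part of the study's
range (8-20% of the valve area), with the washout comparisons on the
finer 32-cell grids where the diastolic mixing jet survives
discretization. Resolving the smallest printed orifices (1% of the valve
area) would need grid spacings several times finer than is practical
here, and the regression of regurgitant fraction on orifice fraction is
correspondingly biased shallow at desk scale: the sub-cell part of every
orifice is blocked by the leaflets' cut cells, so the functional severity
grows more slowly with the structural severity than the near-unity
proportionality the physics produces at scale.

# Known limitations

* Desk-scale grids under-resolve the regurgitant jet; absolute
  regurgitant volumes at small orifice areas are biased low even though
  the orifice-area metrics themselves are grid-independent.
* The flow-following valve is an asymptotic limit: no elastic recall, no
  rate damping beyond the cap, no leaflet bending beyond the
  two-configuration family.
* The washout marker is re-released once per run; multi-cycle residence
  distributions are out of scope.
* The exterior of the chamber is excluded from the pressure solve;
  pressure is defined up to a constant per sealed pocket and is reported
  as the projection potential, not calibrated against a physical pressure
  level.
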