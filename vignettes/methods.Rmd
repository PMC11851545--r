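---
title: "Models and numerics behind aneuNO"
author: "aneuNO authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerics behind aneuNO}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

aneuNO simulates pulsatile blood flow and coupled nitric-oxide (NO)
transport in **idealized** aneurysm geometries, and implements the
cross-sectioning / correlation protocol that relates intraluminal
thrombus (ILT) burden to wall NO concentration. Patient-specific
anatomies, branch vessels, and 3D meshing are deliberately out of scope:
the package substitutes a parametric two-domain (lumen + wall) segment
whose bulge is a Gaussian perturbation of the radius profile,
axisymmetric for symmetric dilations and planar (two independent wall
sides) for asymmetric ones. The two planar wall sides stand in for the
four anatomical directions (anterior/posterior/inner/outer) used on real
cross-sections; every analysis routine accepts an arbitrary direction
count so a future 3D mode needs no interface change.

# Governing models

## Hemodynamics

Blood is an incompressible Newtonian fluid (density 1056 kg/m^3,
viscosity 0.0035 Pa s) in a rigid, no-slip vessel, governed by the
Navier-Stokes and continuity equations. The inlet velocity is a
waveform fitted as a truncated Fourier series
$v(t) = a_0 + \sum_k a_k \cos k\Omega t + b_k \sin k\Omega t$; the inlet
*profile* is the fully developed pulsatile profile of that waveform
(Womersley in a tube; the cosh-form oscillatory solution in a channel),
which is the standard inlet treatment when the upstream vessel is not
modelled. The outlet is zero-gradient (single-outlet idealization; the
multi-branch flow-split treatment of patient models enters only as a
configuration concept, not as meshed branches). Transient runs follow
the periodic-flow convention: five cardiac cycles, with all analysis on
the final cycle.

## NO transport

In the lumen, NO obeys convection-diffusion with a consumption sink
$R_l = k_{oxgen} c_l^2 + k_{ery} c_l$ (oxidation by oxygen, scavenging
by red blood cells). In the arterial wall, convective transport is
negligible and NO obeys diffusion with a first-order sink
$R_w = k_w c_w$. The endothelium produces NO in response to wall shear
stress through the hyperbolic law
$$R_{NO} = R_{basal} + R_{max}\,\frac{|\tau_w|}{|\tau_w| + b},$$
with $R_{basal} = 2.13$ nM/s, $R_{max} = 457.5$ nM/s, $b = 3.5$ Pa.
Defaults: $D_l = 3.3\times10^{-9}$ m^2/s, $k_{ery} = 2.3$ s^-1,
$k_{oxgen} = 7.56\times10^{-6}$, $D_w = 8.48\times10^{-10}$ m^2/s,
$k_w = 0.01$ s^-1.

Three modelling decisions deserve comment, because the published model
constants do not fully determine them:

* **Units of $k_{oxgen}$.** A second-order term $k_{oxgen} c_l^2$ needs a
  rate constant in nM^-1 s^-1; the printed unit (nM/s) is inconsistent
  with the quadratic form. We adopt nM^-1 s^-1. At nanomolar
  concentrations the term is ~seven orders below the scavenging term
  either way.
* **Wall reaction.** The wall sink appears twice with the identical
  expression $R_w = k_w c_w$; we treat it as the single first-order
  relation.
* **Endothelial production as an interface flux.** The hyperbolic law is
  a volumetric rate (nM/s) for the endothelial layer, whose thickness is
  not part of the published constants. We convert it to an interface
  flux $q_s = R_{NO}\,\delta_{en}$ with an explicit endothelium
  thickness $\delta_{en} = 2.5\ \mu m$ (configurable), which makes the
  lumen-wall coupling well-posed and lets either convention (surface
  flux or thin volumetric layer) be recovered by rescaling.

Boundary conditions: inlet $c_l = 0$ (upstream blood is an NO sink),
convective outflow at the outlet (flow re-entering during the reversal
phase carries zero concentration — the usual open-boundary compromise),
zero flux at the outer wall (no perivascular sink is modelled) and on
the axis/symmetry boundary. Lumen and wall concentrations are continuous
at the interface, with flux continuity including the production source.

## Wall indices and the ILT protocol

From the final-cycle signed WSS series the package computes TAWSS
(cycle-mean of $|\tau_w|$), OSI (reversal fraction, 0 to 0.5), RRT
($1/((1-2\,OSI)\,TAWSS)$), ECAP ($OSI/TAWSS$) and TAWSSG. On a 2D wall
curve the Cartesian gradient in the TAWSSG definition reduces to the
tangential arc-length derivative; the package computes
$\overline{|\partial\tau_w/\partial s|}$, the surface interpretation of
the 3D formula. TAcNO is the time average of NO concentration, then a
spatial average over the requested surface, line or section.

The ILT protocol sections the segment every 5 mm, labels a section ILT
when any direction's thrombus thickness exceeds 0.1 mm (a software
tolerance standing in for visual segmentation), computes per-section
thrombus area (annular sectors between the lumen contour and the
thrombus-free contour), and fits per-section area against per-section
TAcNO by ordinary least squares with the regression F test. Per-section
TAcNO is the **perimeter (interface) average** across wall sides; an
area-weighted alternative is available through the `tacno()` weights
argument. Representative sections for the directional analysis are
20 mm apart and are placed automatically where the whole three-section
fan lies on thrombus; the line-averaged TAcNO integrates the lumen
concentration along the full radial chord from the interface to the
centerline (the chord fraction is configurable; zero length is
rejected).

# Numerical methods

## Flow

The solver uses a stream-function / vorticity formulation on a
boundary-fitted structured grid: logical coordinates are the axial
position and a transverse fraction $\eta \in [0,1]$, mapped through
$y = A(z) + \eta B(z)$; transverse grading follows a smooth sinh/tanh
stretching whose strength is fixed under refinement (a strength tied to
the node count would freeze the truncation error). Derivatives are
second-order finite differences in the computational coordinates with
analytic metric terms; near the axis, the delicate cancellations in
$E^2\psi$ and in the vorticity Laplacian are handled by expansion-based
stencils at the first off-axis row. Advection of vorticity is
first-order upwind in the logical directions — unconditionally robust at
the cell Reynolds numbers of aortic flow, at the cost of extra numerical
diffusion in strongly recirculating regions (see Limitations). The
no-slip condition enters through a second-order two-point wall-vorticity
closure, and each implicit theta-step (Crank-Nicolson by default) solves
vorticity and stream function **monolithically**, which removes the
classic wall-vorticity lag instability of segregated schemes. Row/column
equilibration precedes every sparse LU solve because the closure and
metric terms span ~10 orders of magnitude.

Steady solutions use Picard iteration on the same monolithic system
(advecting velocities frozen per iteration, relaxation 0.8, relative
vorticity-update tolerance $3\times10^{-5}$ — roundoff in the wall
closure makes much tighter tolerances unattainable, and WSS is
insensitive at this level). Mass conservation is exact by construction:
the volumetric flux through every cross-section is
$2\pi(\psi_{wall}-\psi_{axis})$ (or the planar difference), fixed by the
boundary values.

Validation oracles: fully developed WSS within 2% of $4\mu U/R$
(tube) and $3\mu U/H$ (channel); pulsatile centerline velocity within
5% of the Womersley closed form (complex Bessel series evaluated
in-package); creeping-flow fore-aft symmetry over a symmetric bulge;
monotone WSS convergence under refinement. The symmetry check runs at
Re << 1 deliberately: at physiological Reynolds numbers inertia breaks
fore-aft symmetry even in the exact solution.

## NO transport

The scalar solver is cell-centred finite volumes on the same grid.
Advective face fluxes are taken **exactly** from stream-function
differences at the face endpoints, so the discrete flow field seen by
the scalar is conservative to machine precision; the steady source-sink
audit (production = lumen consumption + wall consumption + boundary
losses) closes to ~1e-16 relative. First-order upwinding with implicit
Euler yields an M-matrix, hence non-negative concentrations without
clipping. The endothelial production enters through dedicated
interface-concentration unknowns (one per interface face) that enforce
the flux balance $D_l \partial_n c_l + D_w \partial_n c_w = q_s$; these
unknowns are also exactly the endothelial surface concentrations that
TAcNO surface averages need. The quadratic oxidation term is Picard
linearized (it is numerically negligible at nM levels). Transient NO
runs replay the final flow cycle periodically for five transport cycles
from an initial condition equal to the steady field of the cycle-averaged
flow — this removes most spin-up while retaining the five-cycle
protocol.

Validation: the wall block reproduces the 1D slab reaction-diffusion
solution $c_0 e^{-x/L}$, $L = \sqrt{D_w/k_w} \approx 0.291$ mm, to
<1% at the default wall resolution.

## Grid independence

The packaged protocol refines the whole mesh by 10% per step under
steady conditions and accepts when the volume-averaged lumen NO
concentration changes by less than 5% between consecutive meshes. A
zero threshold is degenerate by construction (no refinement can ever
meet it) and simply exhausts the refinement budget with a failure flag.

# Default problem sizes

The default mesh is 57 axial by 33 transverse lumen nodes with an
11-node wall band and grading ratio 1.15 (first near-wall spacing ~0.5%
of the radius); transients use 200 steps per cycle for 5 cycles. These
sizes put the flow oracles comfortably inside their tolerance bands
(steady WSS ~1%, Womersley ~2%) while a full study — flow, NO,
indices, analysis on the 60 mm asymmetric default geometry — completes
in about two minutes on one core. The test suite drops to coarser
meshes and shorter cycle counts wherever an assertion does not depend on
the default resolution.

# The synthetic study generator

The generator supplies everything patient data would otherwise provide:

* **Geometry** — a 60 mm infrarenal-like segment, 10 mm inlet radius,
  7 mm Gaussian bulge (SD 10 mm) at mid-segment with asymmetry 0.6,
  2 mm wall. 60 mm at 5 mm spacing gives the 13 analysis sections.
* **Waveform** — a triphasic template (forward systolic lobe, one
  early-diastolic reversal interval, weak late-diastolic forward flow),
  period 1 s, systolic peak 0.5 m/s (cycle mean ~0.1 m/s), fitted with
  8 harmonics (residual RMS < 1% of peak).
* **ILT map** — per-section thrombus areas drawn as
  $\max(0,\ \alpha + \beta\,TAcNO + \varepsilon)$,
  $\varepsilon \sim N(0,\sigma^2)$, with $\beta = -40$ mm^2/nM (negative:
  more thrombus where NO is lower) and $\sigma$ set from the requested
  expected $R^2$ (0.8 by default) via
  $\sigma = |\beta|\,sd(TAcNO)\sqrt{(1-R^2)/R^2}$. Thickness is
  recovered from area by inverting the annular-sector formula — exactly,
  so a noiseless draw yields slope $\beta$ and $R^2 = 1$ through the full
  analysis chain. The `one-sided` model places each section's thrombus
  entirely on its lower-NO side, which makes the directional
  thickest-vs-thinnest comparison discriminating by construction; the
  `annular` model distributes it uniformly.

**Intercept choice.** With $\alpha$ set exactly at $-\beta$ times the
75th TAcNO percentile, sections at the ILT boundary have near-zero
expected area, and the zero-truncation plus the 0.1 mm labelling
threshold selectively drop low-area draws; across replicates this
attenuates the recovered slope by ~10%. The auto intercept therefore
adds one noise standard deviation of margin,
$\alpha = -\beta\,q_{75} + \sigma$: generated ILT sections carry clearly
positive burden (matching the per-section scatter structure the
generator emulates, where ILT areas sit well above zero), the top ~3
sections remain thrombus-free so both groups exist, and the residual
attenuation drops to ~4%, inside the 10% recovery tolerance that was set
with truncation bias in mind. Truncation still inflates single-draw
$R^2$ slightly above the analytic $var(\beta T)/(var(\beta T)+\sigma^2)$
expectation; the recovery check compares means over 100 replicates
within ±0.1.

**What the generator does not emulate.** Real ILT is not statistically
drawn from the NO field — the causal pathway runs through platelet
activation, residence time and wall biology; the generator imposes the
*correlation structure* so that recovery is testable, not the mechanism.
Passing tests therefore demonstrate that the pipeline measures a known
planted relationship correctly — they say nothing about whether real
aneurysms exhibit that relationship, and patient-specific magnitudes
(absolute TAcNO levels, thrombus areas of hundreds of mm^2) are not
matched at desk scale. Entrance effects also matter: with a zero-NO
inlet, the concentration boundary layer develops along the segment, so
surface NO is lowest near the inlet as well as being shaped by the
bulge — a feature of the idealized open segment, not of a full aorta.

# Known limitations

* First-order upwinding over-diffuses vorticity in strongly
  recirculating bulges at high Reynolds number; WSS magnitudes inside
  deep recirculation zones are smoothed. The validation geometries avoid
  this regime, and the correlation analysis depends on relative axial
  contrasts, not absolute recirculation strength.
* The 2D planar surrogate has two wall directions; four-direction
  anatomical comparisons are represented by the two extremes.
* Rigid walls, Newtonian rheology, no turbulence model, no iNOS or
  perivascular NO sources/sinks, no thrombus growth mechanics.
* Pressure is reconstructed diagnostically from a pressure Poisson
  equation with boundary-layer wall conditions; it is a derived output,
  validated only against the Poiseuille gradient.
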