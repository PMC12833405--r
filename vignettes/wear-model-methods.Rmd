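---
title: "Methods: adaptive wear simulation of a medial unicompartmental knee"
author: "ukawear"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: adaptive wear simulation of a medial unicompartmental knee}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Fixed-bearing medial unicompartmental knee arthroplasty (UKA) replaces the
medial tibiofemoral compartment with a cobalt-chromium femoral component
articulating on an ultra-high-molecular-weight polyethylene (UHMWPE)
insert. Two linked questions drive this package:

1. how much polyethylene is removed over millions of gait cycles, and
2. how the resulting change in insert geometry redistributes load onto the
   *lateral* compartment, whose cartilage is the usual site of
   osteoarthritis progression after UKA.

`ukawear` answers both at desk scale with two scenarios sharing one wear
engine: `UKA` (the isolated prosthesis carries the whole ISO-14243-style
axial load, as in a single-station wear simulator) and `UKAK` (a whole-joint
configuration in which the axial load is applied 5.0 mm medial of the
femoral axis centre and splits between the medial implant and the lateral
cartilage through a force/moment balance, so progressive wear can shift
load laterally).

## Geometry: analytic height fields

All articular surfaces are regular-lattice height fields (`surface_grid`):
x = anterior (+), z = medial (+), height = proximal (+), lengths in mm. The
femoral condyle is a biconvex spherical-arc (torus-like) surface,

$$h(x, z) = h_0 - \left(R_s - \sqrt{R_s^2 - x^2}\right)
                - \left(R_c - \sqrt{R_c^2 - z^2}\right),$$

and the insert dish is the concave analogue with its own radii, its height
measured above the baseplate so that the stored height doubles as the local
remaining material thickness (8 mm at the dish bottom by default). Because
the generator is analytic, femoral heights are evaluated *exactly* at any
translated in-plane position during contact, and refining the lattice
reproduces coarse-lattice heights bit for bit.

Nominal footprints follow ISO 7207-1-style sizes of a small medial
component: femoral 45 x 20 mm (AP x ML), insert 41 x 26 mm, 8 mm thick.
Articular radii are not published for commercial implants; the defaults
(femoral sagittal 28 mm / coronal 22 mm, insert 45 / 30 mm) give the low
sagittal conformity typical of fixed-bearing UKA and are config-overridable.
The lateral compartment is a shallow cartilage dish (38 x 28 mm, radii
70 / 55 mm) under a lateral condyle of the same radii class; its deformable
layer lumps the articular cartilage (4 mm) with an effective meniscus
contribution (4 mm). The two compartments are "balanced" at setup by
shifting the lateral datum so both reach first contact at the same femoral
height — the surrogate of a restored joint line.

## Contact: elastic (Winkler) foundation

The penalty-contact FE this package emulates is replaced by the standard
desk-scale surrogate for conformal polymer/cartilage contact, an elastic
foundation: each bearing node responds independently with pressure
$p = k\,\max(0, \delta)$, where $\delta$ is the local penetration of the
rigid femoral surface and

$$k = \frac{E\,(1-\nu)}{(1+\nu)(1-2\nu)\,t}$$

is the bonded-layer stiffness (thickness $t$). Material constants are
UHMWPE $E = 940$ MPa, $\nu = 0.46$ ($k \approx 543$ N/mm^3 at $t = 8$ mm)
and cartilage $E = 15$ MPa, $\nu = 0.475$. The cartilage value is used
directly; near-incompressibility amplifies the confined modulus
(factor $\approx 9.5 E$), which is accepted and can be replaced by an
effective confined modulus through the configuration. This is the central
fidelity trade-off of the package: foundation pressures carry no lateral
coupling, so free-edge gradients and subsurface stresses of a continuum FE
are not represented, and all cartilage-stress outputs are treated as
trends, not magnitudes.

A one-compartment solve finds the femoral height at which the pressure
integral equals the target load (monotone, piecewise-linear in the height;
safeguarded Newton, relative force tolerance 1e-9). On a sphere-on-flat
configuration the solver is checked against the thin-layer closed form
$p_0 = \sqrt{kF/\pi R}$, $a = (4FR/\pi k)^{1/4}$, and node-for-node against
a brute-force evaluation of $k\,\max(0,\delta)$ on a toy lattice.

## Gait: waveforms and quasi-static restraints

One representative ISO-14243-style cycle (100 samples by default) drives
everything. The axial force is a sum of periodic von-Mises-shaped bumps
over a 168 N swing baseline; the two stance-peak amplitudes are solved so
the curve passes exactly through 2600 N at 13% cycle and 2433.5 N at 45%.
Flexion follows a periodic cubic spline through ISO-shaped control points
(stance peak ~14 deg, mid-stance dip, steep late-stance rise to a 58 deg
swing peak) — the late-stance rise matters, because it supplies the
sliding that beds in the second-peak contact site. AP force and internal-
external (IE) torque are stance-dominated bursts with amplitudes inside
the ISO soft-tissue envelope; positive AP force is anterior on the tibia,
which places the loaded femoral contact posteriorly on the insert
(rollback) and, with it, the wear patch.

The tibia's released degrees of freedom (AP translation, IE rotation) are
resolved quasi-statically per sample: applied load + Coulomb friction
traction + lumped soft-tissue restraint = 0. Restraints act only beyond
neutral zones (+/-2.5 mm AP, +/-3 deg IE; linear-plus-cubic AP law, 0.6
N m/deg IE torsion spring). Friction ($\mu = 0.04$) is handled with
stick-slip logic: inside the Coulomb cone static friction closes the
balance and the tibia holds position; beyond it the monotone restraint law
is inverted exactly, so equilibrium residuals sit at machine precision.
Without stiction, every torque sign change would snap the tibia across the
whole neutral zone — an unphysical chatter that roughly quadruples the
sliding path. The friction normal force uses a fixed nominal medial share
of the axial waveform (0.6 in `UKAK`, 1.0 in `UKA`) rather than the
evolving solved share: friction is a small perturbation, and fixing it
makes the gait trajectory a property of the loading alone, computed once
per run.

## Whole-joint load sharing

In `UKAK` the femoral axial position and varus-valgus (VV) tilt are solved
jointly so that (i) both compartments' pressure integrals sum to the
applied load and (ii) the VV moment about the femoral load point vanishes
— no load-sharing ratio is imposed. The force solve at fixed tilt is
monotone; along that constraint the moment is strictly increasing in tilt
(a Schur-complement argument on the foundation stiffness), so the outer
solve is also a safeguarded Newton. Tolerances: 1e-6 relative on force,
1e-4 N m on moment.

A pure two-point moment balance, however, pins the split to the lever arms
of the two centres of pressure; wear then acts only through slow
centre-of-pressure migration, which runs *medially* in this geometry and
would raise the medial share. The physical joint does not behave that way
because the retained ligaments (ACL, PCL, MCL, LCL) carry VV moment. Their
desk-scale surrogate here is a lumped VV restraint spring (default 30
N m/deg, configurable; 0 recovers the pure balance) acting about a
*balanced reference tilt* — the unworn free-equilibrium tilt at the first
axial peak in that instant's gait posture, computed at setup. The soft
tissue is thus tension-balanced in the unworn loaded posture, mirroring
how ligament pre-strains are prescribed to a baseline physiological state;
only wear-induced deviation (the femur settling varus into the worn medial
pocket) draws a restoring moment, which sheds medial load laterally. The
redistribution *magnitude* scales with the spring stiffness between 0
(free) and the contact Schur stiffness (locked) and is therefore reported
as a trend; its *direction* is robust for any positive stiffness. A
passive tilt limit (10 deg) bounds the solve when a degenerate
configuration (e.g. a vanishing lateral foundation) cannot balance the
moment; the tilt is then pinned and the residual moment reported.

Lateral cartilage stress is summarized per sample as the peak foundation
pressure and its confined-compression von Mises surrogate
$\sigma_{vM} = p\,(1-2\nu)/(1-\nu)$ — about 0.095 p at $\nu = 0.475$, well
below continuum-FE peaks that arise from edge gradients; again a trend
metric.

## Wear: Archard law with adaptive geometry

Linear wear depth follows Archard's law $H = K_w\,\sigma\,S$ with
$K_w = 3.3\times 10^{-7}$ mm^3/(N m) (conventional UHMWPE on polished
CoCrMo) under the unit contract Kw [mm^3/(N m)] x sigma [MPa] x S [m] ->
mm. Per cycle, each insert node accumulates $\sum_i K_w\,p_i\,s_i$ over
the time increments (pressure at the increment start; sliding magnitude
composed vectorially from the flexion arc at the local sagittal radius,
the AP shift and the IE lever). The schedule is 10 analysis steps of 0.5
million cycles (MC): each step evaluates one cycle on the current
geometry, scales the depth field by the step's cycle count, and recedes
the insert surface along its current outward normal (on a height field, a
height drop of recession divided by the normal's vertical component).
Volume increments are recession times surface nodal area; mass is volume
times 0.93 mg/mm^3, so mass = 0.93 x volume holds exactly by
construction, and the nodal bookkeeping is independently checked against
triangulated mesh-volume integrals of the solid before and after a step.
Pressures are frozen at step-start geometry (one iteration per step); the
step-refinement test (20 x 0.25 MC vs 10 x 0.5 MC) bounds the resulting
error on total mass. An optional Laplacian smoothing pass on the per-step
depth field (default off, off in all shipped checks) is available for
noisy configurations. A step that would consume the remaining insert
thickness halts the simulation with a diagnostic.

## Numerical and design choices at a glance

| Parameter | Default | Note |
|---|---|---|
| lattice resolution | 1 node/mm | peak pressure changes < 5% on doubling |
| samples per cycle | 100 | contains the 13% / 45% peak phases exactly |
| force balance tolerance | 1e-9 relative | per compartment solve |
| joint moment tolerance | 1e-4 N m | outer Newton with analytic slope |
| friction coefficient | 0.04 | stick-slip, enters tangential balance only |
| VV restraint | 30 N m/deg about balanced tilt | 0 = pure moment balance |
| VV tilt limit | 10 deg | degenerate configurations only |
| wear factor | 3.3e-7 mm^3/(N m) | conventional UHMWPE |
| schedule | 10 x 0.5 MC | geometry update per step |

Degenerate inputs: zero target load returns an empty contact; loads
unreachable within twice the layer thickness raise a travel-bound error;
Poisson ratios at or above 0.5 are rejected (foundation formula singular);
mismatched cycle field shapes raise consistency errors.

## What the synthetic conditions do and do not emulate

The generator reproduces the *published conditions* of the benchmark this
package mirrors: component footprints, insert thickness, the two printed
axial-force peaks, the 0.6 N m/deg IE spring, neutral-zone restraints, the
5.0 mm medial load offset, material constants, the wear factor, density
and the 10 x 0.5 MC schedule. It does not emulate subject-specific bone
and cartilage anatomy, the commercial implant's true articular profile,
continuum menisci and ligaments, the 5 deg posterior tibial slope, or FE
penalty contact. Consequently the package's *exactly reproducible* outputs
are the benchmark's derivable arithmetic and its own unit contracts, while
simulation outputs are validated as trends (bedding-in pressure drop and
area growth, monotone mass accumulation, medial-to-lateral load shift with
wear, rising stance-phase lateral cartilage stress, isolated-prosthesis
wear exceeding whole-joint wear, a central-posterior wear patch) plus
scale plausibility of the isolated-prosthesis gravimetric rate. Passing
trends on these synthetic conditions does not certify magnitudes for any
real implant or patient.

## Known limitations

- No cross-shear dependence, creep, bedding-in or thermal effects in the
  wear law; a single wear factor throughout.
- Foundation contact cannot reproduce edge-stress concentrations; cartilage
  von Mises values undershoot continuum-FE peaks by design.
- The lateral meniscus is an effective layer, not a structure; no hoop
  mechanics or extrusion.
- The VV ligament surrogate's stiffness sets the redistribution magnitude;
  it is a declared parameter, not a fitted one.
- One representative cycle per step assumes within-step stationarity of
  gait.

## Problem sizes

The shipped checks run the default grids: 42 x 27 insert nodes (1 node/mm),
100 samples/cycle, 10 + 1 cycle evaluations per scenario, plus a 20-step
refinement run — a few seconds each on one CPU, so the full suite and the
reproduction script complete in well under their stated budgets.

```{r example}
library(ukawear)
res <- run_simulation(default_config("UKAK"))
print(res)
res$history
```
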