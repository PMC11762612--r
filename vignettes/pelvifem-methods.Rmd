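---
title: "Modelling sacroiliac screw fixation of fragility fractures on a voxel phantom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling sacroiliac screw fixation of fragility fractures on a voxel phantom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Fragility fractures of the pelvis (FFP) occur in osteoporotic bone under
low-energy loads. The type IIc pattern combines a non-displaced vertical
fracture of the sacral ala (Denis zone II) with ipsilateral superior and
inferior pubic ramus fractures, interrupting both the posterior and the
anterior ring on one side. Percutaneous sacroiliac screws are the standard
fixation; the open clinical question is whether a unilateral screw (USI),
bilateral screws (BSI) or a single transsacral screw spanning both
sacroiliac joints (TSI) best limits fracture dislocation and protects the
uninjured side of the sacrum from adjacent-fracture stress.

`pelvifem` implements the full finite-element comparison as a tested,
reusable pipeline. Because patient-specific CT geometry is not
redistributable, the pipeline runs on a parametric synthetic pelvis
phantom that preserves the mechanically relevant topology of the ring;
everything downstream of the geometry — material mapping, ligaments,
solver, load cases, outcome measures — is the generic machinery a
CT-derived mesh would use, and labeled tetrahedral meshes with HU tables
can be imported through the MSH/VTU readers instead.

## The phantom

The phantom is a mirror-symmetric union of axis-aligned blocks rasterised
onto a uniform voxel lattice; each voxel is split into six positively
oriented tetrahedra (the micro-FE idiom of bone mechanics). Voxels left of
the mid-sagittal plane use the mirrored splitting pattern so the discrete
model, not just the surface, is exactly symmetric — under a symmetric load
the left/right stress difference is solver noise, which is how the
pipeline attributes any asymmetry in fixed runs to the fracture and
construct rather than to the mesh.

Regions: sacrum (S1/S2, left/right), two iliac blocks, sacroiliac
cartilage layers, superior and inferior pubic ramus bars, pubic bodies and
a midline symphysis — fifteen labeled solids closing two load paths from
the S1 endplate to the acetabula. The sacral half-width tapers inferiorly
(`si_wedge`, default 10 mm over a 50 mm height, stepped at five levels):
the bonded, aggregately oblique joint layers convert vertical settling of
the sacrum into lateral thrust on the iliac wings. This nutcracker load
transfer is what gives the lateral–medial fracture-gap measure a
mechanical signal; with parallel vertical joints the measure only sees
Poisson ratios of the vertical motion.

The synthetic Hounsfield field assigns `hu_cortical` (default 1400 HU) to
surface voxels and `hu_trabecular` (400 HU) to interior ones, adds
Gaussian noise (`hu_noise_sd`, default 50 HU — CT-like heterogeneity) and
clamps to the segmentation window [220, 2000] HU. The RNG seed governs
only this noise; geometry is deterministic. What the phantom does *not*
emulate: curved cortical shells, the true auricular joint surfaces, muscle
and fascia, and the compliance of a thin iliac blade. Passing tests on the
phantom therefore demonstrate correct mechanics and reproduce the
*orderings* of the fixation comparison, not patient-scale displacement
magnitudes (phantom gaps are of order 0.01–0.03 mm versus millimetres on
real geometry: the blocky ring is roughly two orders of magnitude
stiffer).

## Material mapping

Apparent density is linear in HU, `rho = 0.00032362*HU + 1` (g/cm³),
capped at 1.8 g/cm³ — the cap is the reading of "the maximum HU value was
sorted by the apparent density 1.8 g/cm³" as a density ceiling. Young's
modulus follows the Dalstra power law `E = 1958.6 * rho^2.33` (MPa),
clamped to [200, 6530] MPa to represent elderly bone. The clamped range is
discretised into bins whose centres define the material catalogue. The
default bin width is 5 MPa, giving 1266 materials; a 50 MPa width would
give ~127. The two conventions (printed increment vs printed material
count) are mutually inconsistent at source; the package defaults to the
width that reproduces the 1266-material catalogue and leaves both
configurable. Poisson's ratio is not specified at source; bone uses
ν = 0.3, configurable. Cartilage and symphysis get a linear-elastic
surrogate (E = 50 MPa, ν = 0.45) valid at the small strains of these load
cases; a hyperelastic symphysis is out of scope. Implants are titanium
alloy (E = 110 000 MPa, ν = 0.3).

Whether the source mapping used element-mean or element-max HU is
ambiguous; the phantom attaches one HU value per voxel and maps it
directly, which is the element-mean convention.

## Ligaments

The eight pelvic ligament groups (ASL, SPSL, LPSL, ISL, SS, ST bilateral;
SP, IP midline) are tension-only springs between attachment patches. Three
stiffness sources are available: constant values after Shi et al. or Yao
et al., and elongation-defined ranges after Eichenseer et al.; the default
uses the Eichenseer ranges with SP and IP from Shi. "Defined by the
percentage elongation" is under-specified at source; it is implemented as
a secant stiffness rising linearly from the low to the high value over
0–10 % strain (breakpoint configurable) and constant beyond — smooth,
monotone and bounded by the published range. Each ligament is one spring
by default (bundles of up to four parallel springs with evenly split
stiffness are available to spread attachment loads).

## Solver

Linear elasticity on constant-strain tetrahedra, small displacements,
assembled sparse and solved by Cholesky factorisation (CHOLMOD) with a
relative-residual check at 1e-8; a failed factorisation is reported as
insufficient constraints. Bonded (tie) contact is master–slave node
elimination, exact by construction. Screws are voxel-relabelled regions —
bonded to bone by mesh continuity, matching the threadless bonded implant
model — and where a screw crosses a fracture plane the duplicated
interface node pairs inside its cross-section are re-tied, which is what
makes a construct stabilise the fracture. Two discretisation guards
matter at coarse lattices: separate implants never share mesh nodes
(otherwise the two BSI screws weld into a pseudo-transsacral rod at the
midline), and the BSI convergence tilt sits on the contralateral screw
only, so the injured-side fixation is the identical implant across USI
and BSI.

Tension-only behaviour uses an active-set fixed point: solve, deactivate
springs in compression, reactivate springs whose gap closes, update
secant stiffnesses, repeat until stable (cap 50 iterations; a converged
solution carries no compressive spring force). Fracture faces are free,
untied surfaces — negative gap values mean the fragments translate past
one another, which the source model also exhibits; an optional penalty
contact is deliberately absent from the default pipeline.

## Load cases and outcome measures

Validation protocol: 294 N on the S1 endplate along each of the four
anatomical directions, both acetabula fixed; the reported quantity is the
mean S1 endplate displacement. Stance cases: the 2048 N maximum walking
force applied inferiorly on the S1 endplate; bipedal stance fixes both
acetabula (1024 N per side — half the maximum), one-legged stance fixes
only the stance-side acetabulum. The source text states both "load through
the sacrum, fixed at the acetabula" and "force applied in each
acetabulum"; for linear statics the two are the same problem in a
different frame, and the package uses the first form.

Fracture gap: mean over paired interface nodes of the relative face
displacement projected on the lateral–medial axis, positive = opening.
The posterior face is probed at its superior and inferior cortical
margins (top and bottom 20 % of the face height, away from the mid-S1
implant corridor); the headline posterior value is the superior band.
Averaging over the whole face would cancel the face-rotation signal
against the welded screw corridor.

Regional stress: signed extremum (largest magnitude, sign kept) of the
lateral–medial normal stress over a sacral region, excluding elements
touching loaded/fixed patches and bonded implant interfaces — constraint
and bonding singularities must not masquerade as bone stress. Von Mises is
deliberately not the headline quantity: bone fails brittle, so normal
stresses along anatomical directions are reported.

Convergence protocol: uniform 6000 MPa bone, ring fixed at the S1
endplate, bipedal hip reactions; the mesh is accepted when the maximum
principal tension and compression each change by less than 5 % between
refinements. Two numerical choices: the refinement sequence is 5 → 2.5 mm
because the phantom's feature sizes are multiples of 2.5 mm — any other
edge length re-rasterises a *different* staircase geometry, which is not a
refinement of the same problem; and the stress extrema exclude a fixed
8 mm physical band around constrained/loaded patches, because a
one-element exclusion band shrinks with refinement and creeps into the
constraint-edge singularity. On the default phantom the 5 → 2.5 mm
changes are below the 5 % gate.

## The comparison

```{r}
library(pelvifem)
cmp <- compare_constructs()   # 3 constructs x 3 stance cases, one phantom
cmp$gaps                      # lateral-medial fracture gaps [mm]
cmp$stresses                  # lateral-medial normal stress at S1/S2 [MPa]
```

One phantom is built, cut as an FFP IIc (default injured side: right, so
the report rows map directly onto the published table layout), fixed with
each construct in turn, and solved under the three stance cases — nine
solves at the default 5 mm lattice (~12 700 elements each), about half a
minute in total; the convergence study adds one ~102 000-element solve.
These problem sizes are the package's default study conditions; all are
configurable.

On the default phantom the comparison reproduces the published rankings:
posterior-ring gap magnitude TSI < BSI < USI in bipedal and injured-side
stance, anterior gap smaller for BSI than USI, and the uninjured-side S1
stress during uninjured-side stance highest for USI (the adjacent-fracture
argument for bilateral or transsacral fixation). The stress pattern is
driven by load sharing: a screw across the intact joint carries load in
parallel with the S1 bone, so the bone sees less; the gap pattern by the
construct's stiffness against sacral settling between the wings.

## Known limitations

Voxel staircase surfaces concentrate stress at re-entrant corners, which
is why probe rules carry explicit exclusion bands; magnitudes at single
elements should not be over-interpreted. The phantom's gap magnitudes are
two orders below patient scale (geometry, not mechanics). Screw threads,
contact separation at bonded interfaces, geometric nonlinearity,
viscoelastic ligaments and muscle forces are out of scope, matching the
source model's own assumptions.
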