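# pelvifem

Finite-element comparison of sacroiliac screw fixation strategies for
fragility fractures of the pelvis (FFP), on a desk-scale synthetic pelvis
phantom.

## The problem

FFP type IIc — a unilateral vertical fracture of the sacral ala (Denis
zone II) plus ipsilateral superior and inferior pubic ramus fractures —
interrupts one side of the pelvic ring in osteoporotic bone. Three
percutaneous fixations compete: a **unilateral sacroiliac screw (USI)**, a
screw crossing only the injured-side SI joint; **bilateral screws (BSI)**,
one per side with non-collinear axes; and a **transsacral screw (TSI)**
spanning both SI joints. The biomechanical questions are (i) which
construct best limits fracture dislocation, and (ii) how much stress each
construct leaves on the *uninjured* side of the sacrum — the
adjacent-fracture risk.

`pelvifem` builds the whole analysis as a tested R pipeline:

* a parametric, mirror-symmetric voxel-lattice pelvis phantom (sacrum,
  iliac blocks, SI cartilage, rami, pubic bodies, symphysis) with a
  synthetic Hounsfield-unit field, an FFP IIc cutter and parametric
  screw/washer constructs — no external imaging data needed;
* CT-style material mapping: apparent density `ρ = 0.00032362·HU + 1`
  (capped at 1.8 g/cm³), Dalstra power law `E = 1958.6·ρ^2.33`, clamped
  to 200–6530 MPa (elderly bone) and binned into a 1266-material
  catalogue;
* the eight pelvic ligament groups as tension-only springs with published
  stiffness catalogues (Shi, Yao, or elongation-defined Eichenseer
  ranges);
* a linear tetrahedral elasticity solver (sparse Cholesky, tie
  constraints, active-set iteration for tension-only elements) with a
  verification battery: patch test, rigid modes, reaction balance, dense
  oracle, Euler–Bernoulli cantilever;
* the published load protocol (294 N validation loads; 2048 N walking
  force for one-legged stance, half per side for bipedal), fracture-gap
  and regional normal-stress reports, and the <5 % mesh-convergence gate;
* Gmsh MSH / VTK VTU / ascii STL / CSV I/O so meshes and solutions can be
  inspected in ParaView or imported from external meshing tools.

## Worked example

```r
library(pelvifem)
cmp <- compare_constructs()   # one phantom, FFP IIc on the right,
print(cmp$gaps)               # 3 constructs x 3 stance cases
```

```
Fracture-gap distance, lateral-medial direction [mm]
               load_case                  site       USI      BSI      TSI
          Bipedal stance Posterior pelvic ring -0.015755 -0.01556 -0.01450
          Bipedal stance  Anterior pelvic ring -0.015816 -0.01559 -0.01226
 Right one-legged stance Posterior pelvic ring  0.029416  0.02920  0.02790
 Right one-legged stance  Anterior pelvic ring -0.010643 -0.01087 -0.00610
  Left one-legged stance Posterior pelvic ring -0.000633 -0.00159 -0.00215
  Left one-legged stance  Anterior pelvic ring  0.087378  0.08407  0.07055
```

Positive gaps are opening, negative gaps are fragments sliding past each
other (fracture faces are free surfaces). Reading the posterior-ring rows:
the transsacral screw dislocates least and the unilateral screw most
(|TSI| < |BSI| < |USI|) under bipedal and injured-side stance — the
published ranking, at phantom scale (the blocky phantom is ~100× stiffer
than a real pelvis, so magnitudes are hundredths of a millimetre rather
than millimetres).

```r
print(cmp$stresses)
```

```
Normal stress, lateral-medial direction [MPa]
               load_case        region     USI     BSI     TSI
  ...
  Left one-legged stance  S1 left side  17.590   9.801   8.082
  ...
```

The key row: standing on the *uninjured* (left) leg, the uninjured-side
S1 stress is 17.6 MPa with a USI but only 9.8/8.1 MPa with BSI/TSI — the
contralateral screw carries load in parallel with the bone, which is the
biomechanical argument that bilateral or transsacral fixation lowers the
risk of an adjacent fracture.

Other entry points: `build_phantom()`, `cut_ffp2c()`, `place_screws()`,
`assign_materials()`, `make_springs()`, `run_load_case()`,
`validate_loads()` (the 294 N protocol), `convergence_study()`, and
`run_pipeline()` for the config-driven end-to-end run
(`inst/scripts/pelvifem.R` wraps these as shell subcommands).

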