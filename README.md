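# pocusalign

Automatic alignment of paired point-of-care ultrasound (POCUS) views of a
pediatric forearm bone.

Distal forearm fractures are the most common pediatric fracture. Wrist POCUS
can detect them without radiation, but a single longitudinal view shows only
one cortex (dorsal *or* palmar), so angulation — the key quantity for
management decisions — cannot be read off one image. Merging the dorsal and
palmar views into a lateral-radiograph-like picture solves this, and doing it
by hand is too slow for emergency care. `pocusalign` implements the automatic
version of that merge for anyone working with segmented bone-boundary masks:
it extracts anatomical landmarks from each boundary, estimates the
flip-plus-rigid transform between the views by energy minimization, fuses the
views, and measures fracture angulation against the growth-plate
perpendicular.

## The model

Each view contributes three landmarks: the physis point `L_p` (lower-left
extremity of the boundary), and two diaphysis points `L_d0`, `L_d1` on the
long near-horizontal shaft segment. With the dorsal view fixed (`f`) and the
palmar view moving (`m`), the transform `T` (horizontal mirror, then rotation
`theta` and translation `t`, all in mm) is found by minimizing

```
E(T) = w_a * C_a + w_o * C_o + w_p * C_p
```

with three anatomical constraints:

* **Latitudinal** `C_a = w_x |L_p,x^f - T(L_p^m)_x| + w_y |d - L_p,y^f + T(L_p^m)_y|`
  — the two physes line up horizontally and sit at a vertical offset `d`;
* **Orientation** `C_o = || i_d^f - i_d^m ||` with `i_d` the unit diaphysis
  directions — the two shafts are parallel (0 when parallel, 2 when
  antiparallel);
* **Position** `C_p = | |(T(L_mid^m) - L_d0^f) . n^f| - w |` — the moving
  shaft midline sits one bone width `w` from the fixed shaft line, which
  rules out the degenerate collinear solution.

Minimization is plain gradient descent (learning rate `5e-2`, 10,000
iterations) with central finite-difference gradients, started from a
closed-form initialization (rotation from the diaphysis directions,
translation from the physis correspondence). Everything is deterministic.

The package also ships the contour-distance metrics used to evaluate such
alignments (directed Hausdorff, symmetric Chamfer), the reader-study
statistics for comparing angulation readings on merged POCUS against X-ray
(reference means, per-reader MAE, pooled Pearson correlation, majority-vote
accuracy), and a synthetic phantom generator that produces paired
dorsal/palmar boundary masks with known landmarks, transform and angulation
for validation.

## Worked example

Align a simulated dorsal/palmar pair with a 12° dorsally angulated fracture:

```r
library(pocusalign)

p <- generate_pair(phantom_config(seed = 42, angulation_deg = 12))
res <- run_align(p$fixed$mask, p$moving$mask,
                 cfg = alignment_config(d = 10, w = 10),
                 lm_cfg = landmark_config(horizontal_tol = 35),
                 pre_flip = TRUE, out_dir = "out")
res$transform
#> rigid_transform: theta = 16.6456 deg, t = (81.1579, 1.7091) mm, pre_flip = TRUE
p$true_transform
#> rigid_transform: theta = 16.5922 deg, t = (81.2196, 1.6360) mm, pre_flip = TRUE
```

The recovered pose matches the phantom's hidden ground truth to ~0.05° and
~0.1 mm; `out/` now holds `transform.json`, the optimizer trace, both
landmark files and the red/green fused overlay. Measuring angulation from the
extracted landmarks against the growth-plate perpendicular:

```r
lm <- extract_landmarks(mask_to_polyline(p$fixed$mask))
inp <- axes_from_landmarks(lm, p$fixed$plate_dir)
measure_angulation(inp$growth_plate, inp$distal_axis)
#> [1] 12
```

Reader-study statistics from the shipped angulation table (11 samples, three
readers, both modalities):

```r
run_study(system.file("extdata", "reader_angulation.csv", package = "pocusalign"),
          system.file("extdata", "reader_accuracy.csv", package = "pocusalign"))
#> Morphology study report
#>   references (deg): s00=3.9 s01=- s02=- s03=8.7 s04=9.3 s05=5.3 s06=- s07=7.4 s08=- s09=9.6 s10=10.4
#>   MAE (deg): P1/POCUS=4.4 P1/XRAY=2.8 P2/POCUS=3.7 P2/XRAY=1.8 P3/POCUS=5.0 P3/XRAY=2.0
#>   mean discrepancy: 2.2 deg
#>   Pearson r (POCUS |err| vs reference): 0.18
#>   mean accuracy: POCUS 0.76, X-ray 0.97
```

The per-reader MAEs on merged POCUS (4.4°, 3.7°, 5.0°) exceed the X-ray ones
(2.8°, 1.8°, 2.0°) by 2.2° on average, and the pooled correlation of 0.18
indicates the error does not grow with fracture severity.

A thin command-line wrapper with subcommands `align`, `angulate`,
`eval-contours`, `study` and `simulate` is installed at
`system.file("cli", "pocusalign", package = "pocusalign")`.

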