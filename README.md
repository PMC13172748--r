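# ccev — equivalent-volume concordance coefficients for radiotherapy target volumes

`ccev` compares co-registered 3-D radiotherapy structure delineations
(GTVs, PTVs, auto-segmentation outputs) with **equivalent-volume
concordance coefficients**, for medical physicists and radiation
oncologists evaluating delineation variability or new segmentation
methods.

The classic Jaccard and Dice coefficients,

```
JC  = V_I / (V_Std + V_Ref − V_I)        DSC = 2 V_I / (V_Std + V_Ref)
```

treat every non-overlapping voxel the same, no matter where it lies. But a
discrepancy hugging the other structure sits inside the steep dose
fall-off of a modern VMAT plan and is clinically almost benign, while the
same volume a couple of centimetres out is a real miss. `ccev` weights
each non-overlap sub-volume by a power of its physical distance `d_i` to
the other structure,

```
EV_Std-I = Σ V_Std-I_i (d_i / d_r)^n     EV_Ref-I = Σ V_Ref-I_i (d_i / d_r)^n

JC_EV  = V_I / (V_I + EV_Std-I + EV_Ref-I)
DSC_EV = 2 V_I / (2 V_I + EV_Std-I + EV_Ref-I)
```

with defaults `d_r = 1 cm`, `n = 1` calibrated from the near-linear dose
fall-off of whole-body VMAT DVHs (fitted as `PCT = B0 + B1·d_PCT` via
equivalent-sphere radii). With `n = 0` the EV coefficients reduce exactly
to JC/DSC. Concordance thresholds 0.90 (JC_EV) and 0.95 (DSC_EV) follow
from a 95%-overlap equal-volume construction.

The package provides:

* `mask_volume` containers with exact anisotropic Euclidean distance
  transforms (compiled), uniform expansion, and distance-banded
  decomposition of non-overlap regions (`band_nonoverlap`, banded or
  continuous mode);
* the EV model (`ev_params`, `equivalent_volume`, `concordance`,
  `cc_ev_from_components`, `classic_coefficients`,
  `agreement_thresholds`);
* DVH gradient calibration (`read_dvh`, `equivalent_radius`,
  `falloff_distances`, `fit_gradient`, `summarize_cohort`,
  `evaluate_model`);
* digital sphere phantoms with closed-form oracles and a seeded DVH
  generator (`make_sphere_pair_uniform`, `make_sphere_pair_displaced`,
  `shell_ev_oracle`, `synthesize_dvh`);
* NIfTI (`.nii`, `.nii.gz`) and NRRD mask I/O, YAML configuration, JSON/CSV
  reports, and a CLI (`inst/cli/ccev.R`) with `compare`, `dvh` and
  `phantom` subcommands.

## Worked example

Two phantoms share identical volumes, intersection, and therefore
identical JC/DSC: a standard 2.0 cm sphere against (a) a concentric
2.6 cm reference and (b) an equal-volume reference shifted 0.5 cm (still
containing the standard). Only the EV coefficients separate them:

```r
library(ccev)
ph_c <- make_sphere_pair_uniform(r0 = 2.0, margin = 0.6, spacing = 0.1)
ph_d <- make_sphere_pair_displaced(r0 = 2.0, r_ref = 2.6, offset = 0.5,
                                   spacing = 0.1)
concordance(ph_c$std, ph_c$ref, ev_params())
#> Equivalent-volume concordance (d_r = 1 cm, n = 1 , banded mode)
#>   V_Std = 33.40  V_Ref = 73.53  V_I = 33.40 cm^3
#>   EV_Std = 33.40  EV_Ref = 48.90 cm^3
#>   JC    = 0.454  DSC    = 0.625
#>   JC_EV = 0.683  DSC_EV = 0.812
concordance(ph_d$std, ph_d$ref, ev_params())
#>   ...
#>   JC    = 0.454  DSC    = 0.625
#>   JC_EV = 0.632  DSC_EV = 0.774
```

The concentric pair scores JC_EV 0.683 — most of its excess lies within
0.6 cm, so roughly half of it is forgiven — while the displaced pair drops
to 0.632 because part of the same excess sits farther from the standard.
Both stay below the 0.90 threshold: a 0.6 cm margin everywhere is a
significant difference.

The bundled 20-case NPC/VMAT gradient cohort reproduces the dose-distance
calibration behind the defaults:

```r
tab <- gradient_cohort()
summarize_cohort(tab, tab$ptv_volume_cc)
#> cohort of 20 gradient fits
#>   mean model: PCT = 101.637 -28.369 * d_PCT
#>   CV(B1) = 8.85%
#>   Pearson r(B1, PTV volume) = 0.834
```

so a sub-volume 0.2 cm out still sees ~96% of the prescription dose, and
one at 1.0 cm ~73% — the rationale for the linear penalty.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli/ccev.R", package = "ccev"))')
Rscript "$CLI" compare --std a.nii.gz --ref b.nii.gz --dr 1.0 --n 1 --band 0.3 --json report.json
Rscript "$CLI" dvh --dir dvh_exports/ --ptv ptv_volumes.csv --json gradients.json
Rscript "$CLI" phantom --config phantom.yaml --out phantoms/
```

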