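# mwivol

Microwave-imaging quantification of microlitre fluid inclusions in ex vivo
long bones.

Bone-marrow edema raises the dielectric permittivity of trabecular bone
strongly, because free water (relative permittivity ≈ 80 at microwave
frequencies) contrasts with marrow fat and mineral (single digits). A 4×4
open-ended coaxial probe (OECP) array stepped over a flat bone face, with
four 90° rotations, yields a 16×16 effective matrix of one-port reflection
sweeps per condition. `mwivol` implements the complete analysis chain for
such data and its validation against CT and injected references:

* **Calibration & inversion** — one-port error model (directivity,
  reflection tracking, source match) solved per frequency from open / short
  / two Debye reference liquids; the Stuchly capacitive aperture model
  `Y = jω(C₀ε + C_f)`, `Γ = (1 − YZ₀)/(1 + YZ₀)` inverted in closed form,
  extracting ε′ at 2.5 GHz. Touchstone `.s1p` I/O included.
* **Probe footprints** — radial sensing kernel from a center-to-edge
  cylinder experiment (annular inversion of the cumulative response),
  sigmoidal lateral profile from side-to-side scans, exponential depth
  decay `w(z) = e^{−z/δ}` from a visibility–thickness curve, giving an
  effective sensing depth `d_eff = δ(1 − e^{−H/δ})` for holes of depth `H`.
* **Mapping & volumetry** — sensitivity-weighted upscaling of coarse grids
  to 0.5-mm permittivity maps; two-phase complex refractive index mixing
  (CRIM), `φ = (√ε_post − √ε_pre)/(√ε_fluid − √ε_pre)`; automatic ROI
  (3σ threshold, 8-connected components); depth-weighted integration to μL.
* **CT reference** — cylindrical VOI extraction on Hounsfield-unit grids,
  hole positivity (≥ 50% of voxels ≥ 250 HU), nominal-volume assignment
  (25.13 μL/hole), and depth rescaling of all references by
  `ρ = d_eff/H = 0.16875` for the 8-mm holes.
* **Agreement statistics** — Pearson with Fisher and bootstrap CIs, Lin's
  CCC with bias-correction factor, Bland–Altman on percent differences,
  Deming regression, paired t and exact Wilcoxon, MAPE, ICC(2,1).
* **Synthetic phantoms** — a seeded generator reproducing the
  seven-specimen study design (hole matrices, baseline permittivity fields,
  per-antenna gains, rotation coupling variability, synthetic CT), so the
  entire pipeline runs and is tested without hardware.

## Worked example

Reproduce the published agreement panel from the packaged per-specimen
volume table:

```r
library(mwivol)
panel <- reproduce_results()
panel$injected
#> <agreement_report>
#>   r = 0.811 (Fisher CI 0.15..0.97, p = 0.027)
#>   CCC = 0.70 (Cb = 0.86)
#>   Bland-Altman bias +12.4% (SD 15.2%, LoA -17.4%..42.2%)
#>   mean diff +9.28 uL (t(6) = 2.42, p = 0.052; Wilcoxon p = 0.016)
#>   MAPE 12.4%; Deming slope 0.89, intercept 18.72
```

The microwave estimates track the depth-scaled injected volumes with high
precision (r = 0.81) and a small consistent overestimate (+12.4%), and the
exact Wilcoxon confirms the shift (p = 2/2⁷ = 0.016).

Run the full pipeline on a synthetic seven-specimen study:

```r
out <- run_pipeline(study_config(seed = 1))
round(out$volumes[, c("scaled_injected_ul", "mwi_ul", "mwi_cv_percent")], 2)
#>   scaled_injected_ul mwi_ul mwi_cv_percent
#> 1              67.86  74.44           3.80
#> 2              67.86  74.48           2.26
#> 3             106.03 110.99           3.29
#> 4             106.03 107.46           1.51
#> 5              84.82  90.64           3.07
#> 6              84.82  88.68           1.25
#> 7              67.86  68.36           2.78
out$agreement_injected$r
#> [1] 0.99
```

Each row is one specimen: the depth-scaled ground-truth injected volume,
the recovered microwave estimate (mean over four rotations), and the
rotation-to-rotation coefficient of variation — in the study's observed
1.2–5.4% range.

A thin CLI wrapper ships in `inst/cli/mwivol.R`
(`simulate | agree | reproduce-table2`).

## Tests

```r
testthat::test_dir("tests/testthat", package = "mwivol",
                   load_package = "installed")
```

The suite covers algebraic round trips (Stuchly forward/inverse,
calibration embed/de-embed), oracle comparisons (annular kernel inversion
against quadrature, ROI components against flood fill, simulated antenna
readings against brute-force integration), the printed statistical panel,
and stochastic recovery properties under fixed seeds.
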