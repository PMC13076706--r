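---
title: "Quantifying microlitre fluid inclusions in bone with an OECP microwave array"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying microlitre fluid inclusions in bone with an OECP microwave array}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mwivol)
```

## The measurement problem

Bone-marrow edema — abnormal fluid in trabecular bone — raises the local
dielectric permittivity of the marrow strongly, because water at microwave
frequencies (relative permittivity near 80) contrasts sharply with marrow fat
and mineralized bone (single digits). An open-ended coaxial probe (OECP)
pressed against a flat bone face measures a one-port reflection coefficient
S11 that encodes the permittivity of the material within a small sensing
volume below the aperture. `mwivol` implements the full analysis chain that
turns arrays of such raw reflection sweeps into specimen-level fluid volumes
in microlitres, validated against CT and injected references:

1. **Calibration and inversion** (`solve_error_terms()`, `de_embed()`,
   `invert_permittivity()`): a one-port error model with directivity,
   reflection-tracking and source-match terms is solved per frequency from
   open (air), short (foil) and two Debye reference liquids; corrected
   reflection coefficients are inverted to complex permittivity with the
   Stuchly capacitive aperture model `Y = j w (C0 eps + Cf)`, and the real
   part at 2.5 GHz is the working value.
2. **Footprint characterization** (`invert_radial_kernel()`,
   `fit_sigmoid()`, `fit_depth_profile()`): the probe's lateral sensing
   kernel is recovered from a center-to-edge cylinder experiment, its
   lateral profile from a side-to-side scan, and its depth decay from a
   visibility–thickness curve.
3. **Mapping** (`assemble_grid()`, `rotate_to_common()`, `upscale()`): a
   4×4 antenna array stepped through a 4×4 offset pattern interleaves to a
   16×16 effective grid at 4-mm spacing; four 90° rotations are replicates.
   Grids are upscaled to 0.5-mm maps by sensitivity-weighted interpolation.
4. **Volumetry** (`estimate_specimen_volume()`): pre/post permittivity maps
   are converted to an areal fluid fraction with the two-phase complex
   refractive index mixing (CRIM) rule, integrated over an automatically
   derived region of interest with exponential depth weighting.
5. **References and agreement** (`ct_reference`, `agreement_report()`): CT
   hole positivity by Hounsfield-unit thresholding with nominal-volume
   assignment, depth rescaling of all references to the probe's sensing
   slab, and the complete method-comparison battery.

A synthetic phantom generator (`make_phantom()`, `generate_study()`)
reproduces the seven-specimen ex vivo study design so that every stage runs
and is testable at desk scale.

## Conventions that matter

Several small conventions decide whether the published panel is reproduced
exactly; they are fixed once, here:

* **Time-harmonic convention** `e^{+j w t}` with lossy permittivity written
  `eps' - j eps''`, `eps'' >= 0` for passive media. A lossless load gives
  `|S11| = 1`, a lossy one `|S11| < 1`.
* **Sample moments** (n−1 denominators) everywhere in the agreement
  battery. With population moments Lin's CCC on the study table drops from
  0.70 to 0.68 and the accuracy factor from 0.86 to 0.84.
* **Percent differences use the reference as denominator**, not the pair
  mean. The pair-mean convention gives a bias of +10.9% instead of the
  published +12.4%.
* **Deming regression with error-variance ratio 1** (orthogonal
  regression) reproduces the published slope 0.89.
* **Repeatability CIs use Student-t with df = 3** (`t_{0.975,3} = 3.182`);
  a normal-quantile interval does not reproduce the printed `[71.9, 79.1]`
  for specimen A.
* **Exact Wilcoxon by full sign enumeration** for n ≤ 16 (the study's
  `p = 2/2^7 = 0.016` with seven positive differences); beyond that the
  exact signed-rank distribution (no ties) or the normal approximation.

## The depth model and its calibration

The depth sensitivity is a single exponential `w(z) = exp(-z/delta)`; a slab
of thickness `H` then contributes an *effective depth*
`d_eff = delta (1 - exp(-H/delta))`, and references measured over the full
hole depth are rescaled by `rho = d_eff/H` to the slab the probe actually
interrogates. The exponential is the simplest saturating family consistent
with a visibility–thickness curve and gives `d_eff` in closed form.

The default decay constant solves `rho(8 mm) = 0.16875`, i.e.
`delta ≈ 1.3537 mm`. That ratio is the constant factor between the scaled
and unscaled reference volumes of the study table (67.86/402.12 =
106.03/628.32 = 0.16875) and is the only depth-scaling information the
published record pins down; all depth weighting and rescaling in the
package defaults to it, and `fit_depth_profile()` replaces it whenever a
measured visibility curve is available.

```{r}
prof <- default_depth_profile()
prof
depth_rescale(402.12, prof)
```

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| target frequency | 2.5 | GHz | mid-sweep working frequency for permittivity extraction |
| sweep | 101 pts, 2.25–3.00 | GHz | study band; point count a free choice |
| `z0` | 50 | ohm | coaxial reference impedance |
| `C0`, `Cf` (simulation) | 25, 20 | fF | plausible small-OECP capacitances; estimated from liquid standards in analysis (`fit_probe_params()`) |
| antenna pitch | 16 | mm | 4-mm effective spacing matches the 4-mm hole lattice |
| pixel size | 0.5 | mm | refinement-converged: halving changes volumes < 1% |
| `r_eq` quantile | 0.9 | – | cutoff defining the equivalent lateral radius |
| ROI threshold `k` | 3 | × noise SD | conventional 3-sigma detection |
| ROI `min_pixels` | 4 | px | suppresses single-pixel noise components |
| `eps_fluid` | 62 | – | water-based gel loaded with iodinated contrast; lower than pure water |
| hole geometry | Ø2 × 8 | mm | drill design; 25.13 uL nominal volume |
| CT threshold | 250 | HU | inside the empty/filled separation gap (132, 388) |

## The synthetic study

`generate_study()` emulates the experimental design: seven specimens (A–G)
with 16/25/20-hole matrices at 4-mm centers, per-specimen baseline
permittivity fields matching the published means and SDs (1.13–1.79, Gaussian
random field with 8-mm correlation length), a gel fill of permittivity 62,
16 per-antenna gains drawn at 8% CV, additive permittivity noise with
SD 0.02, and pre/post CT volumes whose empty and filled hole populations
follow N(25, 73²) truncated below 132 HU and N(482, 132²) truncated above
388 HU, honoring the published non-overlapping extremes.

Three generator choices deserve explanation:

* **Readings average refractive index, not permittivity.** Each simulated
  antenna reads the kernel-weighted average of the column `sqrt(eps)`,
  squared back to permittivity. Under the CRIM rule mixing is linear in
  `sqrt(eps)`, so this is the convention in which superposition of
  overlapping footprints holds exactly; it also makes the inverse problem
  the estimator solves well-posed. Hole footprints are integrated with
  exact annulus/disc lens areas rather than raster membership, because a
  1-mm raster overestimates the area of a 2-mm circle by ~60%.
* **Per-rotation coupling factor** (SD 5.5%, multiplicative): each rotation
  is a physical re-landing of the array, and contact repeatability — not
  electronic noise — dominates rotation-to-rotation variability. The SD is
  calibrated so the four-rotation volume CV sits at the study's observed
  mean (≈ 2.8%, range 1.2–5.4%); with electronic noise alone the simulated
  CV would be an unrealistic ~0.2%.
* **Empty holes hold air in the pre-injection condition**, so pre maps show
  the drilled matrix as permittivity dips, as the published pre-injection
  images do.

The estimator consequently has to survive a pre/post *global* level shift
(different coupling draws for the two sessions). `estimate_specimen_volume()`
removes it robustly by median-centering the difference map before
thresholding — the hole signal occupies a minority of pixels, so the median
tracks the background offset.

What the generator does **not** emulate: full-wave electromagnetic
scattering (readings are linear kernel averages in `sqrt(eps)`), CT beam
hardening and partial-volume blur (hole voxels are drawn directly from the
published group distributions), marrow heterogeneity beyond a smooth random
field, and specimen-to-specimen depth-profile variation. Passing recovery
tests therefore demonstrate that the *analysis chain* is consistent and
unbiased under its own observation model — not that the physical instrument
achieves this fidelity.

## Numerical choices and degenerate inputs

* Calibration solves the bilinear error model per frequency after
  rearrangement to a form linear in `(e_d, e_r - e_d e_s, e_s)`: exact for
  three standards, complex least squares for four (the study used four;
  how it handled the over-determination is not stated).
* `fit_probe_params()` seeds a nonlinear reflection-domain refinement with
  the exact linear admittance-domain solution.
* Radial-kernel inversion floors negative annuli (noise) at zero and
  renormalizes; curves are first cleaned by isotonic regression and
  rejected if the cleanup exceeds 0.05.
* Noise-free difference maps (robust SD exactly 0) fall back to a 1e-6
  threshold floor so the whole signal support enters the ROI.
* A short (`Gamma = -1`) is outside the capacitive model's domain and is
  rejected by `invert_permittivity()`; de-embedding errors name the first
  singular frequency.
* Degenerate agreement inputs (zero variance, all-zero differences,
  overlapping CT groups) raise errors rather than returning NaN; the
  assembled `agreement_report()` records an NA Wilcoxon p for identical
  columns instead of failing the whole panel.

## Problem sizes

The shipped tests and the acceptance script use 7–20 synthetic specimens
with 16×16 grids, 0.5-mm maps (~150×150 pixels) and 10⁴ bootstrap
resamples; a 20-specimen study generates and analyses in well under a
minute on one core. These sizes keep every stage comfortably exercised
while the statistics of interest (recovery correlation, MdAPE, CVs) are
stable across seeds at the stated tolerances.

## Known limitations

* The depth kernel is a single exponential fixed across antennas and
  permittivities; the characterization experiments used eps_r = 4 targets
  only, and any permittivity dependence of the kernels is ignored.
* Specimen-level totals only: per-hole attribution is out of scope, as in
  the validation design.
* The published per-specimen MWI volumes themselves are hardware-specific
  and not re-derivable from desk-scale physics; the package reproduces the
  printed statistics exactly from the packaged tables and validates the
  measurement chain property-wise on synthetic data.
* Sub-90° registration, tomographic reconstruction, and S21/multistatic
  configurations are out of scope.
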