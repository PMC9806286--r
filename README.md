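# splenometry

Stereological spleen volumetry from abdominal MR sections, for medical
imaging scientists and radiographers who need organ volumes with a stated
precision rather than a single-slice surrogate.

The spleen's size and shape vary too much between individuals for length
or single-slice measurements to pin down its volume. The package
implements the full measurement chain used in MRI volumetry studies:

- **Cavalieri volume estimation** — with parallel sections a distance
  `d = thickness + gap` apart and a uniformly random start,
  `V = d * Σ aᵢ` is unbiased for the organ volume, where each section
  area `aᵢ` is the segmented pixel count times the pixel dimensions.
- **Precision via the coefficient of error** — the
  Gundersen–Jensen/Cruz-Orive predictor
  `CE = sqrt((3A − 4B + C)/12) / Σ aᵢ` from the lag-0/1/2 products of
  consecutive section areas (`≤ 0.05` is the conventional adequacy
  bound; below three sections the CE is honestly undefined).
- **Single-slice morphometry** at the first lumbar (L1) level —
  one-pixel-contour circumference, AP/transverse bounding-box diameters,
  region areas, craniocaudal spleen length.
- **Cohort statistics** — dual-rater averaging, splenomegaly
  classification against an explicit threshold, descriptives (mean, SD,
  SEM), and a from-first-principles OLS of spleen volume on nine
  predictors with standardized betas, t, p, R² and the ANOVA F.
- **Ground truth to test it all** — analytic phantoms (ellipsoid,
  superellipsoid, lobulated) voxelized at MRI-like spacing with random
  slice offsets, and a gender-stratified synthetic cohort (110 male /
  235 female; volumes 223.5 ± 122.9 / 170.27 ± 89.25 cm³) with known
  per-subject volumes, plus DICOM/NIfTI/CSV I/O and a CLI.

## Worked example

Measure a phantom with known volume through the full chain:

```r
library(splenometry)

sp <- phantom_spec("ellipsoid", semi_axes = c(3.2, 3.2, 5.5))
analytic_volume(sp)
#> [1] 235.9127

v <- voxelize(sp, voxel_config(seed = 7), subject_id = "demo")
measure_volume(v$mask, v$series)
#> Cavalieri volume 235.55 cm^3 from 14 sections (d = 0.80 cm), CE 0.0082 (acceptable)

spleen_length(v$mask, v$series)
#> [1] 11.2
```

The estimate lands within 0.2% of the analytic 235.91 cm³, the CE says a
14-section systematic sample determines this volume to about 0.8%, and
the slice-extent length is within one slice spacing of the true 11 cm.

Regress volume on length and the single-slice predictors for a full
synthetic cohort:

```r
cohort <- generate_cohort(cohort_config(seed = 1))
d <- cohort$truth
names(d)[match(c("true_volume", "true_length"), names(d))] <-
  c("spleen_volume", "spleen_length")
ols_fit(d)
#> Linear regression: n = 345 (0 dropped), R Square = 0.64, ANOVA F = 65.08, P = 3.22e-68
#>           term         B     SE     beta      t        p
#>     (Constant) -199.1308 63.955       NA -3.114 2.01e-03
#>            age   -0.0268  0.225 -0.00398 -0.119 9.05e-01
#>  spleen_length   35.1579  1.569  0.77313 22.413 1.29e-68
#>  ...
#>         abd_tv    1.9613  0.892  0.07789  2.198 2.86e-02
#>  ...
```

Spleen length dominates (standardized beta 0.77) and the abdominal
transverse diameter is the only single-slice measurement reaching
significance — single-slice surrogates carry little independent volume
information.

The same pipeline runs from a shell:

```sh
Rscript inst/cli/splenometry.R end-to-end --config cfg.json --seed 7 \
        --threshold-volume 350 --out rundir
```

writing `table3.csv`–`table6.csv` and `report.txt` under `rundir/results`.

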