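# photoloc

Radiometric and visual modelling of **diurnal active photolocation**: can a
small triplefin fish perceive the retroreflective eyeshine that its own
"ocular spark" — downwelling sunlight focused by the lens onto the lower
iris — induces in the pupil of a nearby cryptic scorpionfish?

The package is for visual ecologists and sensory modellers who want to run
(or rerun, with their own measured spectra) the full chain from light field
to detection distance:

1. **Radiometry.** Photon flux at the observer's pupil along two paths —
   the target pupil's baseline radiance (`baseline_flux()`, exact d⁻²) and
   the spark → retroreflection return (`spark_radiance()`, `retro_flux()`,
   exact d⁻⁴), with the spark treated as a Lambertian reflector
   (L = R·E/π), retroreflectance expressed relative to a diffuse white
   standard (values > 1 allowed), and small-angle solid angles A/d².
2. **Vision.** Per-cone quantum catches
   qᵢ = Σ_λ Φ(λ)·T(λ)·Sᵢ(λ)·Δλ over 400–700 nm; achromatic Michelson
   contrast C = (Q₁−Q₂)/(Q₁+Q₂) on the summed double-cone channel
   (threshold 0.008); receptor-noise-limited chromatic contrast in JND with
   eᵢ = ω·√(η_max/ηᵢ), ω = 0.05, cone ratio 1:4:4 (threshold 1.0 JND).
3. **Detection.** `detection_scan()` evaluates both contrasts at every
   millimetre from 1–15 cm and reports the maximum distance still at or
   above threshold; `sensitivity_grid()` maps that distance over spark
   reflectance × pupil retroreflectance; `iris_comparison()` repeats the
   calculation for the (non-retroreflective) iris.
4. **Behaviour.** `proximity_table()` + `fisher_exact()` give the exact
   2×2 analysis of "came within ~7 cm at first measurement" by hat
   treatment: two-sided hypergeometric p, conditional-MLE odds ratio, and
   exact conditional 95 % CI.
5. **Synthetic data.** `make_ambient()`, `make_pigment_sensitivity()`,
   `make_reflectance()` and `simulate_behavior()` generate all inputs
   (blue-green 10 m ambient light, A1 pigment templates, blue-peaked spark,
   arena trajectories), so everything runs with no downloads.

See `vignettes/photoloc-methods.Rmd` for the model, its assumptions and the
design choices.

## Worked example

```r
library(photoloc)

scene <- default_scene()   # documented default synthetic world
detection_scan(scene$L_base, scene$L_spark, scene$R_retro,
               scene$geometry, scene$vsp)
#> <detection_scan>
#>   distances: 10-150 mm (141 points)
#>   max achromatic detection (C >= 0.008): 95 mm (9.5 cm)
#>   max chromatic detection (>= 1 JND): none

fisher_exact(c(9, 33, 18, 20))   # 9/42 clear-hatted vs 18/38 shaded within 7 cm
#> <exact_test_result: Fisher's exact test, 2x2>
#>      within beyond
#> row1      9     33
#> row2     18     20
#>   p = 0.01853, OR (CMLE) = 0.3078, 95% CI = (0.1006, 0.8847)
```

The scan says that under the default synthetic scene the spark-induced
brightening of a scorpionfish pupil stays above the triplefin's achromatic
detection threshold out to 9.5 cm, while the chromatic (colour) channel
never reaches a discriminable difference at any distance — detection is
carried by brightness, not hue. The exact test says clear-hatted fish
(functional sparks visible) had about 0.31 times the odds of approaching
within 7 cm compared with fish whose sparks were shaded, a significant
hesitation (p ≈ 0.019) consistent with the modelled detection range.

An end-to-end run —

```r
run_pipeline(photoloc_config(seed = 1), "photoloc-out")
```

— writes the generated spectra, behaviour records, per-distance contrasts,
north/south sensitivity maps, `summary.json` and a checksummed manifest to
`photoloc-out/`. A thin CLI wrapper lives at `inst/scripts/photoloc.R`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from scratch against the installed package, the exact 2×2
contingency analysis of the observed first-measurement counts (p-value,
conditional-MLE odds ratio and CI bounds, the within-treatment
percentages, and the wall time of the exact test), and also exercises the
full synthetic pipeline under the given seed. Results are written as JSON
to `--out`.
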