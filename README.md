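# vaangle

Automated measurement of the **fundus vascular arcades angle (VAA)** from
colour fundus photographs, with the cohort-level statistics that relate the
angle — and its longitudinal change — to choroidal thickness in high myopia.

## The problem

Choroidal thinning accompanies the progression of high myopia, but measuring
choroidal thickness requires OCT, which many screening settings lack. As the
eye elongates, the superior and inferior temporal vascular arcades are drawn
toward each other, so the angle they subtend at the optic disc is a candidate
fundus-photograph surrogate for choroidal thickness. This package is for
researchers in ophthalmic image analysis and myopia epidemiology who want a
fully inspectable, classical implementation of that measurement plus the
associated statistical pipeline — and a synthetic test bed that makes every
stage verifiable without clinical data.

## The measurement

With `O` the optic-disc centre and `PD` the papillary (disc) diameter, all
distances are in disc diameters:

1. **Preprocess** — extract the circular fundus region, median-denoise,
   normalize each channel to a fixed mean/SD, CLAHE on luminance.
2. **Disc** — locate the disc (brightest large blob + vessel convergence),
   segment its boundary by a derivative-of-Gaussian edge detector in polar
   coordinates around the candidate centre, and fit the **minimum enclosing
   circle**: its centre is `O`, its diameter is `PD`.
3. **Arcades** — multiscale Hessian (Frangi-type) vesselness, hysteresis
   binarization, skeletonization; on a ring at `0.75 PD` the two widest
   skeleton crossings per side are the arteriovenous arcade pair, traced
   along the skeleton to the `3 PD` circle.
4. **Key points** — `B` (inferior) and `C` (superior) are the midpoints of
   the pair's crossings with the `3 PD` circle.
5. **Angle** — a quadratic Bezier is fitted to each traced arm with fixed
   endpoints `O` and `B` (or `C`); its crossings with the `2 PD` circle give
   `D`, `E` and with the `1 PD` circle give `F`, `G`. Then

   `VAA(1PD) = ∠FOG` and `VAA(2PD) = ∠DOE`.

The cohort statistics mirror the standard analysis around such a biomarker:
spherical equivalent `SE = sphere + 0.5 · cylinder`, high myopia
`SE ≤ −5.0 D`, paired baseline/follow-up change tests with Shapiro–Wilk
driven test choice, Pearson/Spearman correlation and age/gender-adjusted OLS,
p-for-trend across VAA quantile groups, and a multivariable model of
peripapillary choroidal-thickness change with a VIF collinearity screen.

## Worked example

```r
library(vaangle)

# a synthetic right-eye fundus scene with analytic ground truth
sc <- generate_fundus_scene(scene_params(seed = 7))
sc
#> <fundus_scene 512px right eye> PD=64px true VAA(1PD)=128.92 deg VAA(2PD)=109.76 deg

m <- measure_vaa(sc)
m
#> <vaa_measurement> VAA(1PD)=128.41 deg VAA(2PD)=109.53 deg PD=64.47 px
```

The measured angles are within about half a degree of the analytic truth and
the papillary diameter within a pixel; `autoplot(m, image = sc)` draws the
annotated overlay (fitted curves, the 1/2/3 PD circles, points O–G).

The cohort side works from tibbles in a fixed CSV schema:

```r
coh <- generate_cohort(cohort_params(n_subjects = 277, seed = 7))
fit <- change_model_vif(compute_changes(coh$baseline, coh$followup))
tidy(fit)[8, c("term", "beta", "ci95_low", "ci95_high", "p_value", "vif")]
#> vaa_1pd_deg_change  0.758    0.305      1.21    0.00113  1.11
```

The generator's true slope is 0.855 µm of peripapillary choroidal-thickness
change per degree of VAA(1PD) change; a single n = 277 cohort recovers it
within its confidence interval, and across 200 replicates the mean estimate
is within 1% (see below). A trend analysis on the baseline visit:

```r
trend_by_group(coh$baseline, "vaa_1pd_deg", "mcht_um")
#> <vaa_trend> mcht_um across 4 groups of vaa_1pd_deg: p for trend = 2.967e-08
```

A thin command line sits over the same functions:

```sh
Rscript inst/cli/vaa generate --out-dir scenes --n 5 --seed 1
Rscript inst/cli/vaa measure --out-dir results scenes/*.png
```

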