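---
title: "Measuring the vascular arcades angle: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the vascular arcades angle: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vaangle)
```

This vignette explains what the package computes, the assumptions behind
each stage, the parameters that matter, and the choices made where the
design was genuinely open. The README shows usage; here the emphasis is on
*why* the pipeline is built the way it is.

## The quantity being measured

The vascular arcades angle (VAA) is the angle at the optic-disc centre `O`
subtended by the superior and inferior temporal arcades where they cross a
circle of radius one papillary diameter (1 PD) or two (2 PD). The papillary
diameter — the diameter of the smallest circle enclosing the segmented disc
boundary — is the method's internal length unit, which is what makes the
angle comparable across cameras, magnifications and eye sizes. Because the
arcades converge temporally, the angle measured at 2 PD is smaller than at
1 PD; progressive "pinching" of the arcades, the geometric correlate of
myopic elongation, lowers both.

The angle is reported unsigned in (0°, 180°]. Values in highly myopic eyes
sit far from both poles (roughly 80°–155°), so the arctangent-of-cross/dot
formulation in `angle_at_O()` is numerically comfortable; it is still used
in preference to `acos` of a normalized dot product because it degrades
gracefully near 0° and 180°.

## Pipeline stages and their assumptions

**ROI extraction** (`extract_roi`) assumes the photograph is a bright
circular aperture on a near-black surround. Pixels whose maximum channel
exceeds `preprocess.border_threshold` (default 20/255 — low enough to be
robust to JPEG ringing around the aperture) are foreground; the largest
connected component, closed and hole-filled, is the mask. The operation is
idempotent and invariant to extra black padding, which the tests check.

**Normalization and enhancement** (`normalize_enhance`) maps inside-mask
pixels per channel to mean 128 and SD 40 on the 8-bit scale. These targets
are a conventional, deliberately mid-range choice; the useful property is
not the specific numbers but that two photographs of the same fundus at
different exposures become nearly identical afterwards (tested to < 1%).
Denoising is a 3×3 median — chosen over Gaussian smoothing to preserve
vessel edges, and implemented as a sorting network because a generic median
filter dominated the pipeline's runtime. Contrast enhancement is CLAHE on
the luminance channel (8×8 tiles, clip limit 2, the standard fundus
recipe), with the colour ratio preserved. All three sub-steps can be
switched off individually for ablation.

**Disc segmentation** (`segment_disc`) replaces a trained detector with a
classical one, on the grounds that the detector is an interchangeable
front-end to the geometry: the score map is z-scored blurred luminance plus
0.5 × z-scored blurred vesselness (the vascular tree converges on the
disc). Two refinements matter in practice and were added after inspecting
failure modes on synthetic scenes: the bright component at half-height
around the peak is re-centred by its centroid, because vessels entering the
disc darken it asymmetrically and bias the blurred argmax; and the vessel
suppression before edge detection uses a median window of about twice the
expected vessel width (radius `0.016 ×` image width), since a narrower
window fails to remove a vessel crossing the disc margin. The boundary
itself comes from a polar resampling around the candidate centre (360
angular bins, 0.5 px radial step over [0.2, 1.4] × the box half-width), a
derivative-of-Gaussian operator (σ = 2 px) along the radius whose
most-negative response marks the bright-to-dark disc edge, sub-pixel
parabolic refinement, and circular median smoothing (window 7) over angle.
Bins whose gradient magnitude falls below `disc.edge_floor` (0.02 in
normalized units) are interpolated from their neighbours; if more than half
the bins fail, the stage raises a boundary-failure error rather than
guessing. A second polar pass centred on the first minimum-enclosing-circle
fit decouples the final geometry from any residual detection offset. The
minimum enclosing circle is Welzl's randomized incremental algorithm (with
a fixed internal permutation so results are deterministic); an exhaustive
O(n⁴) oracle stays in the test suite. By default `O` is the fitted circle's
centre, which is more stable than the detection-box centre; the box centre
remains available via `disc.center_mode = "bbox"`.

**Vessels and arcades** (`compute_vesselness`, `binarize_and_skeletonize`,
`trace_arcades`). Vesselness is the classic Hessian-eigenvalue ridge filter
on the inverted green channel at four scales (1–4 px at a 512-px image,
scaled with image width — the assumption being that vessel calibre scales
with the field of view). The second-derivative kernels are demeaned so a
constant image yields exactly zero, and a small absolute floor on the
structureness scale prevents noise amplification on near-flat inputs.
Binarization is hysteresis (high 0.30 / low 0.12 of the normalized
response), followed by small-component removal and Zhang–Suen thinning;
vessel width is twice the Euclidean distance transform sampled on the
skeleton. Arcade selection takes, on a ring of radius 0.75 PD (just outside
the disc, before the arcades branch), the two widest skeleton crossings per
side — "side" meaning above or below `O` in image coordinates. Ties break
by larger width, then smaller horizontal distance to `O`. A/V
discrimination is deliberately not implemented: the key points are
midpoints over the arteriovenous pair, so only "the two widest vessels per
side" is ever needed. Tracing is a greedy walk along the skeleton — first
inward to the disc margin (r = 0.5 PD), then outward, always taking the
unvisited neighbour that most increases radial distance — with a visited
set guaranteeing termination. Greedy-radial is simpler than shortest-path
search and sufficient for arcade-shaped vessels; it is isolated behind the
`trace_arcades` interface and swappable.

**Curve fitting and intersections** (`fit_bezier_arc`,
`circle_arc_intersection`). Each arm is a quadratic Bezier with endpoints
fixed at `O` and the key point: quadratic is the minimal degree with the
required endpoint structure, it makes the least-squares control point a
closed-form solve, and a restriction of a quadratic to a sub-interval is
again a quadratic, so an exact fit to an ideal arcade exists. Chord-length
parameterization alone biases that solve, so the control point is refined
by minimizing true orthogonal point-to-curve distance: a Nelder–Mead search
over the two control-point coordinates (the alternating
projection/re-solve scheme proved able to stall in a shallow side valley
when started from the chord-length estimate), then a projection/solve
polish that reaches machine precision on noiseless input (verified to
< 1e-6 px in the tests). Circle crossings are found by a 256-sample sign
scan of |P(t) − O| − r followed by bisection to 1e-9 × radius; if a curve
crosses a circle more than once, the outermost crossing (largest t) is
used, reading the intersection as lying on the outbound path. Since
P(0) = O, a crossing exists exactly when the arc exits the circle, and its
absence is surfaced as the `no_2pd_crossing` flag rather than an invented
angle — the pipeline never emits an angle whose geometric preconditions
failed.

## The synthetic scene generator

`generate_fundus_scene()` emulates exactly the scene content the pipeline
relies on: black surround outside a circular aperture (0.95 of the
half-width), an orange background with mild quadratic vignetting (strength
0.15), a bright circular disc on the nasal side (default right-eye
geometry, disc at x = 0.72 of the image width), two dark arcade trunks
rendered exactly along quadratic Beziers (full width 7 px at 512 px), thin
distractor vessels confined to the nasal half (starting outside the
selection ring, widths 3 px), a slight optical blur (σ = 0.7 px, so edges
are sub-pixel like real optics) and additive Gaussian sensor noise
(σ = 5 gray levels). The default arcade geometry — control point at 1.5 PD
along the 75° half-angle, endpoint at 3.3 PD along the 45° half-angle —
was chosen once so that the true angles (about 129° at 1 PD and 110° at
2 PD) sit near the middle of the range reported for highly myopic eyes.
Ground truth (disc centre, PD, true angles) is computed analytically from
the generating Beziers, never from rendered pixels, so generator
correctness and segmentation error stay decoupled.

What the generator does **not** emulate — and what passing tests therefore
do not establish about clinical photographs: uneven illumination fields,
pathology (haemorrhage, atrophy, tessellation), tortuous or branching
arcades, arteriovenous pairs rendered as two separate trunks, crossings of
distractors through the measurement annulus (available via
`hard_mode = TRUE` but not part of the clean-scene contract), camera
colour profiles, and compression artefacts. The geometric accuracy
numbers on clean scenes are an upper bound on what the same code would do
on clinical data.

## The synthetic cohort generator

`generate_cohort()` draws each ocular parameter as a loading on a latent
severity factor; the loading of parameter *j* is r_j / 0.6, with 0.6 the
angles' own loading, so that the angle–parameter correlations hit their
targets (e.g. 0.297 for macular choroidal thickness). Both angle variants
share a second factor (loading 0.55) so they correlate with each other.
One-year changes load on a progression factor with signs matching the
cross-sectional structure, and the change of peripapillary choroidal
thickness is generated from an explicit linear model whose slope on the
chosen angle's change (0.855 µm/° for the 1 PD variant, 0.719 for 2 PD)
is the recovery target of the statistical tests. The residual SD of that
model (10.2 µm) was derived once from the targeted marginal SD (≈ 10.9 µm)
by subtracting the variance explained by the generated predictors. The
generator is honest about what is unknowable: only pairwise correlations
with the angles are targeted, the full joint distribution (e.g. the strong
axial-length/refraction correlation) is not, and the baseline-age /
follow-up-interval structure is simplified to independent draws.

## Statistical pipeline choices

Test choice follows normality: Shapiro–Wilk on the paired deltas, paired
t-test if normal, otherwise Wilcoxon signed-rank. The signed-rank default
is a deliberate deviation from protocols that name the Mann–Whitney U test
in a paired setting — U is an unpaired test — but `paired_test =
"auto-mannwhitney"` preserves the literal choice for strict fidelity.
Correlation falls back from Pearson to Spearman on the same criterion and
reports which method ran. The trend analysis bins by quantiles (quartiles
by default; group count configurable since the grouping used in practice
is rarely stated) and regresses the thickness on the ordinal group score.
The change model screens collinearity in two stages: perfectly aliased
columns are treated as infinite-VIF and dropped first, then predictors with
VIF above `stats.vif_ceiling` (default 10, a conventional ceiling) are
removed iteratively worst-first before the final fit. Standardized
coefficients are β·SD(x)/SD(y) on the model-matrix columns. No
multiple-testing correction is applied anywhere, matching the
single-comparison p < 0.05 convention of the analysis this mirrors.
Degenerate inputs are handled explicitly: all-zero deltas report p = 1, a
perfect fit collapses its CI onto the estimate, zero-variance inputs raise
errors rather than NaNs.

## Problem sizes and tolerances used in verification

The test-suite and acceptance-script sizes were chosen as the smallest that
make each check statistically meaningful: 50 seeded scenes at 512 px for
end-to-end geometric accuracy (mean |error| ≤ 2°, max ≤ 5°, both radii);
1000 random circle–curve instances against a 10⁵-sample dense-scan oracle
(agreement within 1e-3 × radius); 200 random 10-point sets against the
exhaustive enclosing-circle oracle (1e-9 relative); 20 scenes for the disc
diameter (within 5%, scale-equivariant within 2% across ×0.5–×2); rotation
by 5° and rescaling ×0.5–×2 changing the angles by ≤ 1°; five
progressively pinched scenes for strict monotone decrease; and 200
replicate cohorts at n = 277 for slope recovery (mean within 10%, 95% CI
coverage in 93–97%) plus 200 null replicates for the trend test's size
(3–8% at nominal 5%).

## Known limitations

The disc detector assumes the disc is the brightest large structure; discs
obscured by severe peripapillary atrophy or photographs with bright
artefacts would need the external-bbox escape hatch
(`measure_vaa(..., disc_bbox = )`). The tracer assumes each arcade is
radially monotone after smoothing; hairpin vessel courses would defeat the
greedy walk. The quadratic arch cannot represent an inflected arcade; the
fit residual (`residuals` in the measurement) is the diagnostic to watch.
The "vertical-line" reading of the superior key point is implemented
(`vaa.point_c_rule = "vertical"`) but secondary: the default keeps B and C
symmetric, consistent with annotated examples that place C on the upper
arcade near 3 PD, and the two rules are never silently merged. Whether
"the 3 PD range" means radius 3 PD or 1.5 PD is likewise configurable
(`vaa.radius_3pd`), with radius 3 PD — the literal reading — as default.
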