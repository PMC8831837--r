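---
title: "Measuring temporal vessel width and angle with the Radon transform"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring temporal vessel width and angle with the Radon transform}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesselrt)
```

## The measurement problem

In retinopathy of prematurity (ROP) screening, the geometry of the major
temporal retinal vessels carries diagnostic signal: as the disease
progresses, fibrovascular traction narrows the angle between the superior
and inferior temporal arcades, while the vessels themselves dilate. Both
effects are subtle — a few degrees and fractions of a pixel — and fundus
photographs of preterm infants are noisy, low-contrast, and show
incompletely developed vasculature. Threshold-based segmentation followed
by skeletonization is fragile under these conditions, because a
mis-segmented boundary biases both the centerline and the caliber.

`vesselrt` instead builds every measurement on *line integrals* of image
intensity. Integration averages pixel noise away, so a detector based on
integrals along candidate lines (the Radon transform) degrades gracefully
as image quality drops. Four quantities are produced per image, matching
standard clinical reading: the temporal artery and vein angles (TAA, TVA,
degrees) and the temporal artery and vein widths (TAW, TVW, pixels).

## The model

The Radon transform of an image $g(x,y)$ is

$$R(\rho, \theta) = \iint g(x, y)\,
  \delta(\rho - x\cos\theta - y\sin\theta)\,dx\,dy,$$

the integral of intensity along the line whose normal makes angle
$\theta$ with the $x$ axis at signed distance $\rho$ from the origin. A
straight, bright structure produces a sharp maximum at its orientation
and offset. The package uses this machinery in three roles:

1. **Centerline tracking** (`track_centerline`). From a manual seed near
   the optic-disc margin, 179 directional line integrals (1°–179° in 1°
   steps; 180° would duplicate 0°) are formed through the current point.
   Samples along each segment come from Keys bicubic interpolation and are
   weighted by a Gaussian of distance from the point, so nearby pixels
   dominate. Each candidate direction is scored by
   $(1-\beta)\,\hat R + \beta\cos\gamma$, where $\hat R$ is the
   min–max-normalized integral response, $\gamma$ the angle to the distal
   target point, and $\beta$ (`target_bias`, default 0.3) resolves
   ambiguity at crossings without overriding image evidence. The point
   advances `step_length` (2 px) along the winning direction, restricted to
   the forward half-plane of the previous step so the track cannot
   reverse, and is then re-centred at the sub-pixel maximum of the
   perpendicular intensity profile. Tracking stops within one step of the
   target. The trace is finally smoothed with a Gaussian along the point
   index (`smoothing_sigma` = 2 points), which enforces the spatial
   smoothness of real vessels without shortening the trace (endpoints are
   pinned).

2. **Width estimation** (`vessel_width`). At positions every 2 px of
   arclength over the proximal 100 px of the trace (widths are read near
   the disc, where the angle is also defined), intensity is integrated
   along short segments *parallel* to the local vessel direction, one per
   perpendicular offset. The two steepest transitions of this
   offset-profile — the extrema of its first derivative, refined by a
   parabolic fit — are the vessel edges; the width at that position is the
   Euclidean distance between the reconstructed edge points, which lie on
   the same perpendicular. The vessel width is the mean over positions;
   low-contrast positions are skipped and counted. A half-maximum edge
   criterion is available behind `edge_method = "halfmax"` and agrees with
   the gradient criterion within 0.5 px on ideal band profiles; the
   gradient form is the default because it needs no background-level
   estimate.

3. **Angle estimation** (`vessel_angle`). Each arm's proximal 50 px of
   arclength (`fit_span`) is fitted with a total-least-squares line,
   oriented distally. The two arms' lines are intersected — the
   intersection need not fall at the optic-disc centre, and often does
   not — and the angle is the inverse cosine of the dot product of the
   distal unit directions, reported on (0°, 180°) without folding, since
   normal eyes have obtuse temporal angles. A disc-centre chord baseline
   (`disc_chord_angle`) is retained for comparison; when the true
   intersection is displaced from the disc centre the chord method is
   measurably more biased, which is why the intersection method is the
   default.

Fundus vessels are darker than the background, so images are inverted to
bright-vessel polarity once at ingest (`read_fundus_image`, which also
reduces RGB to the green channel — the standard high-contrast channel for
retinal photography). Edge detection is polarity-agnostic.

The temporal widths aggregate the two arms: TAW/TVW is the mean of the
superior and inferior arm widths. When a superior artery is overlapped by
an adjacent vein, its width cannot be measured reliably; the annotation's
`overlapped` flag makes the pipeline fall back to the inferior width
alone, and the result carries an `inferior_only` flag, mirroring how such
images are handled in clinical datasets.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `step_length` | 2 | px | tracking advance per iteration; small enough to follow arcade curvature |
| `target_bias` | 0.3 | – | weight of target alignment vs Radon response in direction scoring |
| `profile_half_length` | 10 | px | directional integral half-span; spans the widest expected caliber |
| `weight_bandwidth` | 4 | px | Gaussian distance weighting; about half a typical arteriole caliber |
| `recenter_halfwidth` | 3 | px | maximum perpendicular correction per step |
| `smoothing_sigma` | 2 | points | trace smoothing scale |
| `tangent_window` | 7 | px | parallel-integration segment length for edge profiles |
| `max_offset` | 15 | px | perpendicular edge search range |
| `min_contrast` | 0.1 | fraction | minimum centre-to-background contrast for an edge sample |
| `max_arclength` | 100 | px | proximal span used for width |
| `fit_span` | 50 | px | proximal span of the straight-ray fit |

The re-centering probe window extends 4 px beyond `recenter_halfwidth` so
that the perpendicular profile always reaches background on both sides of
the caliber; without this, the profile across a vessel wider than the
window is flat and the maximum is undefined. The probe profile is also
matched-filtered with a 1.5 px Gaussian before the maximum is taken:
flat-topped calibers otherwise present two interpolation humps (bicubic
overshoot at the edges) and the raw argmax alternates between them,
zigzagging the trace by about a pixel.

`fit_span` sensitivity: on straight-armed phantoms the recovered angle is
flat in `fit_span` between 30 and 100 px (changes < 0.1°). On curved
vessels the parameter defines *which* angle is being measured — the
tangent angle at the disc margin versus a chord angle over the proximal
arcade — so it is exposed rather than hard-coded. Values below ~20 px
make the fit sensitive to residual tracking jitter.

## The phantom generator

Real fundus images with expert annotations cannot ship with the package,
so validation runs on synthetic phantoms (`render_phantom`,
`phantom_eye_spec`) whose geometry is known exactly: dark straight or
curvilinear vessels of chosen width and inter-arm angle on a brighter
background, a mock optic disc, Gaussian blur (0.5 px), and i.i.d.
Gaussian pixel noise. The "rect" cross-section is an anti-aliased band
whose half-coverage edges are exactly the nominal width apart, used for
exact-width assertions; the "gaussian" cross-section (FWHM = nominal
width) exercises robustness on soft profiles. Default canvas is 600 × 800
px — half the native capture scale of the screening images, which keeps
the full test suite fast; rendering at full scale is only a parameter.
Noise levels in tests are quoted as fractions of vessel contrast, with 5%
as the standard stress level.

The generator also emulates the *statistical* layer: `sample_cohort`
draws per-eye TAA/TVA/TAW/TVW values from per-stage normal distributions
whose means, SDs and group sizes are the published per-stage summary
rows shipped in `rop_reference_tables()` (66 / 28 / 33 / 49 images for
no-ROP / stage 1 / stage 2 / stage 3), optionally with a joint
correlation structure across variables.

What phantoms do *not* emulate: choroidal texture, vessel branching and
crossings inside the measured span, the bright nerve-fibre reflexes of
infant fundi, and motion blur from unsedated imaging. Passing the phantom
suite therefore demonstrates that the estimators are unbiased and stable
under noise on clean geometry; it does not certify performance on
degraded clinical images, where seed placement and the `overlapped`
fallback carry more of the load.

## Numerical choices

* Bicubic interpolation uses the Keys kernel ($a = -1/2$), which
  reproduces constants exactly; boundary samples are clamped to edge
  values. The sinogram accumulator (`radon_transform`) is pixel-driven:
  each pixel's intensity is split linearly between the two offset bins
  bracketing its exact normal offset, making the transform exactly linear
  and mass-preserving per orientation.
* Sub-sample refinement of profile extrema uses a three-point parabolic
  fit, clamped to half a sample; exact plateaus fall back to the plateau
  centroid so symmetric inputs give symmetric answers.
* Equal-scoring tracking directions are broken toward the previous step's
  direction (at the first step, toward the seed→target direction).
* Degenerate inputs fail loudly: blank images raise a no-vessel error at
  the seed, flat edge profiles a low-contrast error, coincident fit
  points a degenerate-fit error, near-parallel arms (< 0.5°) a
  parallel-lines error, and an ANOVA whose groups share a single mean
  returns $F = 0,\ p = 1$ explicitly rather than a 0/0 artifact.
* The one-way ANOVA and Tukey HSD on raw data delegate to
  `stats::aov`/`stats::TukeyHSD`; the summary-statistics routes
  (`anova_from_summary`, Tukey–Kramer via `stats::ptukey`) recover the
  identical decomposition from $(n_i, \bar x_i, s_i)$ alone, which is
  what makes published tables testable without raw data. The two routes
  agree to 10⁻⁹ on any raw cohort.
* Normality is reported (`normality_report`, Shapiro–Wilk per cell) but
  never used as a gate.

## Design decisions on open ground

* **Curvature handling.** Curvature is handled by Gaussian trace
  smoothing plus the forward-cone restriction on candidate directions. An
  alternative along the lines of a Gaussian-process curvature classifier
  (separating signed curvature by zero-mean thresholding) was considered
  and set aside as underdetermined: no formulation we could state
  precisely improved on smoothing in phantom tests.
* **Width cap.** The 100 px proximal cap is applied along the trace's
  *arclength* (not the axial extent of its bounding box); for the nearly
  straight proximal arcade the two differ by well under a pixel, and the
  choice is configurable.
* **Edge criterion.** Steepest-gradient rather than half-maximum, because
  it requires no estimate of the (possibly asymmetric) background level;
  the half-max variant is kept as a cross-check.
* **Correlation sample.** Images whose TAW is an inferior-only fallback
  are kept in correlation analyses by default (`exclude_inferior_only =
  FALSE`), since the fallback value is still an unbiased caliber estimate
  of one arm; excluding them is one flag away.
* **Coordinates.** All geometry uses continuous 1-based pixel coordinates
  (x = column rightward, y = row downward), including annotation JSON
  (`coords: "1-based"`). One convention everywhere beats a 0-based
  boundary layer in an otherwise 1-based language.

## Problem sizes used in validation

The shipped tests and the acceptance script validate on: 600 × 800
phantoms (31 × 31 for sinogram-oracle comparisons); calibers 3–8 px;
design angles 90°–130°; 5% contrast noise; 10,000 null replicates for
ANOVA type-I calibration; and 200 seeded cohort replicates at the
published group sizes for the staging pattern. At those group sizes the
strict four-group ordering of the TAA means reproduces in roughly three
quarters of replicates — the published stage-1/stage-2 mean gap (2.36°)
is smaller than its own sampling error (3.37°) — while the headline
no-ROP vs stage-3 decrease reproduces essentially always. The test suite
asserts the analytically expected rates, not an inflated one.

## Known limitations

* Seeds and targets are manual inputs by design; there is no automatic
  seed detection or vessel-tree segmentation.
* Arteries and veins are distinguished only by the annotation labels, as
  in expert-annotated screening datasets.
* Widths are reported in pixels; no micrometre scale factor is applied
  because none is available for the target imaging geometry.
* Bifurcations and crossings inside the measured span are not modelled;
  the `overlapped` flag is the supported mitigation.
* The cohort simulator draws eyes independently; inter-eye correlation
  within a patient is not modelled.

## A worked phantom example

```{r example, eval = FALSE}
spec <- phantom_eye_spec(angle_artery = 110, angle_vein = 120,
                         width_artery = 4, width_vein = 6,
                         noise_sigma = 0.0225, seed = 7)
rp <- render_phantom(spec)
ann <- truth_annotation(rp$truth)
measure_eye(rp$bright, ann)
#> eye measurement
#>   TAA: 110.02 deg  TVA: 119.90 deg
#>   TAW: 4.01 px   TVW: 6.00 px
```

The recovered angles are within 0.1° and the widths within 0.02 px of the
design values under 5% contrast noise.
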