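# vesselrt

Radon-transform measurement of retinal vessel width and angle in fundus
photographs of preterm infants screened for retinopathy of prematurity
(ROP).

## What it does, and for whom

ROP progression leaves a geometric signature on the major temporal
vessels: the angle between the superior and inferior arcades narrows and
the vessels dilate. `vesselrt` is for image-analysis researchers and
screening groups who want those four quantities per image — temporal
artery angle (TAA) and vein angle (TVA) in degrees, temporal artery width
(TAW) and vein width (TVW) in pixels — from a fundus photograph plus a
lightweight per-image annotation (a seed point near the optic disc and a
distal target per vessel arm, with artery/vein labels and the ROP stage).

Infant fundus images are noisy and low-contrast, which defeats
segmentation-plus-skeletonization pipelines. Every measurement here is
instead built from **line integrals** of intensity, which average noise
away. The Radon transform of an image *g(x, y)*,

    R(ρ, θ) = ∬ g(x, y) δ(ρ − x cos θ − y sin θ) dx dy,

peaks where a line matches a linear structure. The pipeline:

1. **Centerline tracking** — from the seed, 179 weighted directional line
   integrals (1° spacing, cubic interpolation) score candidate
   directions together with alignment toward the target; the point steps
   forward 2 px, is re-centred on the perpendicular intensity maximum,
   and the finished trace is Gaussian-smoothed.
2. **Width** — at each position on the proximal ≤ 100 px of centerline,
   integrals *parallel* to the vessel at varying perpendicular offsets
   localize the two edges at the steepest transitions (sub-pixel refined);
   width is the Euclidean distance between corresponding edge points, and
   TAW/TVW average the superior and inferior arms (with an inferior-only
   fallback when a vein overlaps the superior artery).
3. **Angle** — each arm's proximal 50 px is fitted with a total
   least-squares ray; TAA/TVA is the inverse cosine of the distal
   directions' dot product at the rays' intersection, on (0°, 180°).

Because clinical images cannot ship with the package, a phantom generator
renders synthetic fundus-like images with exactly known geometry, and a
cohort simulator draws per-stage measurement tables from published
summary statistics; both drive the test suite. The statistics layer
(one-way ANOVA from raw data *or* summary rows, Tukey–Kramer multiple
comparisons, Pearson correlation) reproduces the analyses such a study
reports.

## Worked example

```r
library(vesselrt)

spec <- phantom_eye_spec(angle_artery = 110, angle_vein = 120,
                         width_artery = 4, width_vein = 6,
                         noise_sigma = 0.0225, seed = 7)   # 5% contrast noise
rp  <- render_phantom(spec)           # image + ground truth
ann <- truth_annotation(rp$truth)     # seeds/targets per vessel arm
measure_eye(rp$bright, ann)
#> eye measurement
#>   TAA: 110.02 deg  TVA: 119.90 deg
#>   TAW: 4.01 px   TVW: 6.00 px
```

The phantom was designed with a 110° artery pair (widths 4 px) and a 120°
vein pair (widths 6 px); the pipeline recovers the angles within 0.1° and
the widths within 0.02 px under 5% contrast noise.

Cohort-level statistics from a simulated measurement table:

```r
cohort <- sample_cohort(cohort_spec(seed = 5))   # published per-stage params
rep <- cohort_report(cohort)
rep$anova$TAA
#> one-way ANOVA: F(3, 172) = 44.43, p = 2.594e-21
writeLines(format_cohort_report(rep)[1:12])
```

A command-line interface wrapping these functions lives at
`inst/cli/vesselrt.R` (`measure`, `simulate`, `stats` subcommands; each
takes `--seed`, `--out`, and `measure` takes `--config`).

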