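# retinotort

Quantifies the tortuosity of retinal blood vessels — how much, and how many
times, a vessel bends — and provides the multi-rater validation workbench
needed to judge such measurements against clinical graders. Increased
vascular tortuosity is a candidate biomarker for diabetic retinopathy,
hypertension and other vascular disease, but manual grading is subjective;
this package implements the objective measurement side and the statistical
machinery for comparing it with panels of human raters.

## What it computes

Four reference tortuosity metrics on a vessel centerline with arc length
`L_c` and chord length `L_x`:

| metric | formula | units |
|---|---|---|
| arc-to-chord (`hart`) | `L_c / L_x − 1` | dimensionless |
| constant-sign subdivision (`grisan`) | `((n−1)/L_c) Σᵢ (L_csi/L_xsi − 1)` over the `n` constant-sign-curvature subsegments | 1/px |
| integrated curvature (`trucco`) | `(Σⱼ |k(j)|^p)^(1/p)` with `k` the signed derivative curvature | (1/px)-aggregate |
| chain-code curvature density (`onkaew`) | `((n−1)/n) (1/L_c) Σᵢ |K(pᵢ,k)|` with `K` from smoothed 8-direction chain codes | 1/px |

Per-vessel values integrate into one score per retina by arc-length-weighted
additivity `τ = Σ L_ci τ_ci / Σ L_ci`.

Around that core:

- **Vessel extraction** from fundus-style rasters: multiscale
  structure-tensor-regularized ridge (valley) detection, Otsu binarization,
  topology-preserving thinning to a 1-px skeleton, spur pruning, and
  deterministic decomposition into segments at junction pixels.
- **Rater agreement**: four-grade (none/mild/moderate/severe) and binary
  (tortuous/non-tortuous, asymptomatic/symptomatic) rating tables, Cohen's
  kappa for every rater/round pair, majority-vote consensus labels,
  consensus percentages, and the standard kappa interpretation bands.
  Marginal rating counts from a five-expert, 60-image, two-round grading
  study ship as fixtures.
- **Prognostic validation**: ROC curves and trapezoid AUC of continuous
  tortuosity scores against binary consensus labels (with an exact
  Mann-Whitney pairwise oracle as a second route), and single ROC points
  for binary expert predictions.
- **Synthetic generators**: parametric vessels with closed-form tortuosity
  annotations, rendered phantom images with ground-truth centerlines, and
  multi-rater ordinal panels with analytically known agreement.
- **Study workbench**: `run_study()` chains measurement, agreement analysis
  and ROC validation over an image/ratings bundle and writes a
  bit-reproducible report.

## Worked example

Measure a synthetic vessel with a known shape:

```r
library(retinotort)
v <- make_vessel(vessel_spec("sinusoid", length = 200, amplitude = 15,
                             half_waves = 4, n_points = 400), id = "demo")
vessel_tortuosity(v)
#>   vessel_id length_px     hart      grisan   trucco     onkaew
#> 1      demo  238.8876 0.194438 0.009564304 6.050852 0.01900578
```

The vessel's path is 238.9 px long against a 200 px chord, hence
arc-to-chord tortuosity 0.194; the four half-waves give n = 4 constant-sign
subsegments, which the subdivision and chain-code densities (0.0096/px,
0.0190/px) reward and a straight or single-arc vessel would not.

Extract and measure a rendered two-vessel phantom:

```r
ph <- render_phantom(list(
  vessel_spec("line", length = 150, origin = c(20, 40), n_points = 200),
  vessel_spec("sinusoid", length = 150, amplitude = 12, half_waves = 3,
              origin = c(20, 100), n_points = 300)),
  shape = c(150, 190), width = 3, noise_sd = 0, seed = 1)
rep <- measure_image(ph$raster)
rep$per_vessel
#>   vessel_id length_px      hart      grisan   trucco     onkaew
#> 1        V1  148.0000 0.0000000 0.000000000 0.000000 0.00000000
#> 2        V2  168.9138 0.1260922 0.004345012 3.838047 0.01487685
rep$totals
#>       hart     grisan     trucco     onkaew
#> 0.06720660 0.00231587 2.04566000 0.00792930
```

The straight vessel scores zero on every metric; the integrated totals are
the arc-length-weighted means, lying between the two per-vessel values.

Agreement between two raters:

```r
k <- cohen_kappa(c(0,0,1,1,0,1,0,0), c(0,1,1,1,0,1,0,0))
k
#> [1] 0.75
interpret_kappa(k)
#> [1] "substantial"
```

A thin command-line front end over the same functions lives at
`inst/cli/retinotort.R` (subcommands `measure`, `agree`, `roc`, `simulate`,
`study`).

## Scope

The bundled study fixtures are marginal counts only: the per-image expert
labels behind them were never published, so that study's per-image kappa
matrix and expert ROC points are not reproducible and are not attempted.
The phantom generator validates geometry, not photorealism; see the methods
vignette (`vignettes/retinal-tortuosity.Rmd`) for estimator details, design
decisions and known limitations.
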