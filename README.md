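# voxplp

Geometric analysis of functional language assessments with multiaxial
radar charts.

A verbal operant experimental (VOX) analysis probes the same
speaker-selected verbal responses under four pure sources of stimulus
control — **tact** (labeling a present stimulus), **mand** (requesting an
absent one), **echoic** (imitating a verbal model), and **sequelic**
(answering a fill-in or Wh- question) — and records, trial by trial,
whether each response was emitted. Behavior analysts and speech-language
researchers use such assessments to quantify how balanced a speaker's
verbal repertoire is across sources of control, notably for children with
autism spectrum disorder.

`voxplp` turns those trial-level records into **polygonal language
profiles** (PLPs): the four per-operant totals are plotted on the axes of
a four-axis radar chart (+x echoic, +y mand, −x sequelic, −y tact) and
connected into a closed polygon, which the package then describes
geometrically:

- **Area** — with axis values v₁…vₙ on n evenly spaced axes,
  A = ½ Σᵢ vᵢ vᵢ₊₁ sin(2π/n) (cyclic; for n = 4 the quadrant
  product-sum, identical to the shoelace formula). Larger areas mean more
  overall stimulus control.
- **Maximal total area** Ã — the maximum of A over the (n−1)!/2 distinct
  cyclic axis orderings, found by exhaustive search.
- **Centroid** (x̄, ȳ) — the area-weighted mean of the origin-anchored
  triangle centroids, x̄ = ΣAᵢxᵢ / ΣAᵢ (and likewise ȳ): the repertoire's
  locus of control. A perfectly balanced repertoire has centroid (0, 0).
- **Centroidal distance** R = √(x̄² + ȳ²) — smaller is more balanced.
- **First moment of area** Q = A·(C − R), where C is the radius of the
  circle circumscribing the property space (the maximum attainable axis
  score). Q combines size and balance into one scalar.
- **Quadrant convergence** — the share of the PLP lying between each pair
  of adjacent axes, a measure of convergent multiple control (quadrant 1:
  echoic∧mand, 2: mand∧sequelic, 3: sequelic∧tact, 4: tact∧echoic).

It also tests the functional independence of the operants with Cochran's
Q over the related binary samples (each response form probed under every
condition), builds longitudinal descriptor series and cross-speaker
comparisons, renders radar charts and Q time-series plots (deterministic
SVG, plus PNG via ggplot2), generates seeded synthetic assessments, and
ships a command-line pipeline.

## Worked example

Score a built-in single-session assessment (six response forms probed
under all four conditions) and describe the resulting profile with a
property radius of C = 12:

```r
library(voxplp)

totals <- operant_totals(vox_fixture("table2"))
totals
#> <axis values> tact=5  mand=2  echoic=5  sequelic=1

describe_profile(vox_fixture("fig4"), radar_config(property_radius = 12))
#> <shape descriptors>
#>   A  = 220.00   (A~ = 220.00)
#>   centroid = (1.33, -0.67)   R = 1.49
#>   Q  = 2312.04   (C = 12)

related_samples_test(vox_fixture("table2"))
#>  Cochran's Q test for related binary samples (asymptotic chi-square)
#> data:  6 response rows x 4 conditions
#> Q = 8.0526, df = 3, p-value = 0.04494
```

The `fig4` profile (tact 12, mand 10, echoic 12, sequelic 8) encloses an
area of 220 squared axis units; its centroid sits at (1.33, −0.67), i.e.
in the tact–echoic quadrant, 1.49 axis units from the origin, so the
repertoire is large but slightly tilted toward extraverbal-formal
control. For the scored assessment, Cochran's Q rejects equal emission
percentages across the four conditions at the .05 level — the operants
are disproportionately strong, which is exactly what the profile's
lopsided shape (totals 5, 2, 5, 1) shows visually:

```r
render_radar(totals, radar_config(property_radius = 6), "profile.svg")
```

The same pipeline from a shell:

```sh
./exec/voxplp compute -i inst/extdata/table2_trials.csv -C 6 -o out/
./exec/voxplp test    -i inst/extdata/table2_trials.csv -o out/
./exec/voxplp plot    -i inst/extdata/table2_trials.csv -C 6 -o out/
```

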