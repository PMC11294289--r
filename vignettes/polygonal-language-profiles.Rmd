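---
title: "Polygonal language profiles: model, descriptors, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polygonal language profiles: model, descriptors, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxplp)
```

## The measurement model

A verbal operant experimental (VOX) analysis samples a speaker's verbal
repertoire as *related* observations: the same speaker-selected response
forms (at least three per session) are each probed under four pure
sources of stimulus control — tact, mand, echoic, sequelic — and emission
is recorded as 0/1. Two continua organize these operants: extraverbal
control (tact–mand, the presence vs. absence of a nonverbal stimulus) and
intraverbal control (echoic–sequelic, verbal stimuli with vs. without
point-to-point correspondence). Placing the two continua on perpendicular
axes gives a four-axis radar chart whose canonical layout is fixed in
this package as **+x echoic, +y mand, −x sequelic, −y tact**. That
orientation is forced by the quadrant semantics: the region between two
adjacent axes depicts convergent multiple control of those two operants,
and the conventional reading is quadrant 1 = echoic∧mand, 2 =
mand∧sequelic, 3 = sequelic∧tact, 4 = tact∧echoic.

Plotting the per-operant totals on their axes and joining adjacent points
yields a closed polygon, the polygonal language profile (PLP). All
descriptors are computed from its vertices and the origin.

## Shape descriptors

With axis values $v_1,\dots,v_n$ on $n$ evenly spaced axes
($n = 4$ for VOX):

- **Area**: $A = \tfrac12 \sum_i v_i v_{i+1} \sin(2\pi/n)$ (cyclic).
  For $n = 4$, $\sin(2\pi/n) = 1$ and each term is the right triangle
  spanned by one quadrant, so $A$ is the quadrant product-sum and agrees
  with the shoelace formula on the vertices — the test suite checks that
  equivalence on thousands of random profiles. The published worked
  example (12, 10, 12, 8 on echoic, mand, sequelic, tact) gives
  $A = \tfrac12(120+80+96+144) = 220$.
- **Maximal total area** $\tilde A$: the maximum of $A$ over all
  $(n-1)!/2$ cyclic orderings of the axes, up to rotation and
  reflection, found by exhaustive enumeration (bounded at $n \le 10$).
  Ties — which occur whenever values are symmetric, including in the
  worked examples — are broken toward the ordering lexicographically
  closest to the canonical one, so results are deterministic and the
  canonical semantic layout is preferred whenever it attains the
  maximum.
- **Centroid**: the polygon is decomposed into $n$ origin-anchored
  triangles; each triangle's centroid is the mean of its three vertices
  (signed coordinates), and the polygon centroid is the area-weighted
  mean $\bar x = \sum A_i x_i / \sum A_i$, likewise $\bar y$. This equals
  the true polygon centroid; the tests verify it against Monte-Carlo
  rejection sampling inside the polygon.
- **Centroidal distance**: $R = \sqrt{\bar x^2 + \bar y^2}$; equal
  axis values give centroid $(0,0)$ and $R = 0$.
- **First moment of area**: $Q = A\,(C - R)$, where $C$ is the radius of
  the circle circumscribing the property space.

## The property radius C

$C$ is the only tunable parameter with real leverage, and it is
deliberately **required, with no default**. Its natural value is the
maximum attainable score per axis for the instrument at hand (e.g. the
number of response forms times rounds, for raw sums). The package
validates $C \ge$ every axis value (warning) and $C \ge R$ (error, or a
warning with negative $Q$ in permissive mode), and records $C$ in every
output so that $Q$ values are only ever compared at a common $C$.

The published descriptor tables this package's fixtures reproduce never
print their $C$; every printed $(A, R, Q)$ triple, however, is
simultaneously consistent with $Q = A(C-R)$ at $C = 12$, and the test
suite asserts that consistency within the rounding of the printed inputs.
The value 12 is therefore used in the worked examples but is an
inference, not a constant of the method. Relatedly, the longitudinal
table's area row is typeset as a run-on string in the source; the reading
(4, 84, 80, 220, 288) adopted by `vox_fixture("table3")` is the unique
one consistent with the printed $R$ and $Q$ rows at $C = 12$, and two of
its $Q$ cells (times 2 and 3) disagree with recomputation from the
*rounded* printed inputs by up to 0.3, so the tests check those cells as
intervals rather than exact targets.

Note that $Q$ is not scale-equivariant unless $C$ is rescaled with the
data: multiplying all axis values by $k$ scales $A$ by $k^2$ and $R$ by
$k$, but $C - R$ only tracks if $C$ is also multiplied by $k$.

## Aggregation across rounds

Repeated assessments can be scored either as raw summed frequencies
(`aggregate = "sum"`, the default, matching single-session worked
examples) or as per-session means (`aggregate = "mean"`), which keeps
multi-round profiles on a single round's scale; published cross-speaker
tables with fractional areas (e.g. 146.67) are consistent with mean-type
aggregation. The choice is explicit in both the R API and the CLI and is
recorded in the provenance block, because the two scalings are not
comparable at a common $C$.

## The functional-independence test

The related-samples design (every response form probed under every
condition) calls for a test of equal emission percentages across
conditions. The package implements **Cochran's Q**,
$Q_c = (k-1)\,(k\sum_j C_j^2 - N^2) / (k N - \sum_i R_i^2)$, the
standard such test for binary related samples, referred to the
$\chi^2_{k-1}$ upper tail. Rows that are all 0 or all 1 are
uninformative and provably leave the statistic unchanged; when *every*
row is constant the statistic is undefined and the package reports `NA`
with `p = 1` and a degeneracy flag rather than a spurious 0. Because the
asymptotic reference is dubious at the tiny sizes of a single assessment
(six rows), an exact **within-row permutation** p-value is available
(`p_method = "permutation"`, seeded); the suite checks that it converges
to the asymptotic value on moderate designs. On binary data Cochran's Q
coincides algebraically with the Friedman rank statistic, which the test
suite uses as an independent cross-check, alongside exhaustive
enumeration of every 2- and 3-row design.

## The synthetic generator

`generate_synthetic()` emulates the *structure* of a real assessment — a
complete response-form × condition × session grid of binary emissions —
with independent Bernoulli draws at one fixed probability per operant.
Its defaults (6 response forms, 1 session, probabilities 0.8, 0.3, 0.8,
0.2 for tact, mand, echoic, sequelic) mirror the lopsided single-session
assessment of the worked example: strong extraverbal-formal and
weak mand/sequelic control, the profile shape typical of the clinical
population the assessment was designed for. What the generator does
**not** model: within-form dependence (a form a child knows well is
likely emitted under several conditions), session-to-session learning or
motivation drift, and examiner/prompting effects. Passing tests
therefore demonstrate correctness of the scoring, geometry, and test
statistics under the stated sampling model — not robustness of the
assessment itself to those real-world dependencies.

## Numerical and rendering choices

- Axis directions use `cospi`/`sinpi`, so quarter-turn coordinates are
  exact and the worked areas (220, 288, 21) are reproduced exactly in
  double precision, not merely to tolerance.
- All internal computation is full double precision; rounding to two
  decimals happens only at the reporting layer (printed tables, CSV
  descriptor files). JSON descriptor files keep full precision and
  round-trip exactly.
- Degenerate profiles: $A = 0$ yields an undefined centroid (`NA` with a
  degeneracy flag), $R$ = `NA`, and $Q = 0$ under any convention. A
  profile with a single nonzero quadrant is valid and handled by the
  triangle decomposition.
- SVG charts are serialized directly from the chart geometry (axes,
  polygons, property circle, centroid, text labels) rather than through
  a rasterizing device, so output bytes are fully determined by the
  input, polygon coordinates in the document are the profile vertices
  under the affine plot transform, and structural tests can parse the
  document. PNG export rasterizes the ggplot2 version of the same chart.
  Grid rings and fill styling are deliberately minimal and undocumented
  territory — they may change without notice; only the tested structure
  (polygons, labels, markers, determinism) is contract.
- Radar overlays soft-limit at five series (a warning, not an error),
  encoding the readability guidance that more than four or five
  overlapping profiles are hard to compare; centroid markers are drawn
  only for single-profile charts since overlapping displays prohibit
  them.

## Validation problem sizes

The suite validates the shoelace equivalence on 1,000 random profiles,
centroid correctness against Monte-Carlo integration with 40,000–60,000
samples, ordering optimality by full enumeration up to 6 axes, the test
statistic by exhaustive evaluation of all 2- and 3-row binary designs
and by 100-replicate power simulation at 1,000 response forms, and
generator calibration at 500–600 forms against 3-sigma binomial bounds.
These sizes were chosen to make sampling error negligible relative to
the asserted tolerances while keeping the full suite fast.

## Known limitations

- The geometry is defined for non-negative axis values on evenly spaced
  axes; unequal axis spacing (differently weighted continua) is not
  supported.
- Higher-order descriptors (moment of inertia, convexity, compactness)
  are natural extensions of the same triangle decomposition but are out
  of scope; the decomposition is exported so they can be built on top.
- The independence test treats rows as exchangeable blocks; it does not
  model session effects in multi-round data beyond blocking by
  (session, response form).
- Clinical interpretation — treatment selection from profile shapes — is
  outside the package's remit; it computes, tests, and draws.
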