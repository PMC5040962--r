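---
title: "Methods: terrain, POM cover, biomass and the depth-only null model"
author: "abysshill"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: terrain, POM cover, biomass and the depth-only null model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abysshill)
```

## The scientific problem

Sinking particulate organic matter (POM, phytodetritus) is the principal
food supply of abyssal seafloor communities, and standard depth-attenuation
models treat it as spatially uniform at a given depth. Abyssal hills of
very modest elevation (tens of metres) may nevertheless concentrate both
POM and megafauna through topographically enhanced bottom currents. This
package provides the full measurement chain needed to quantify that
effect in AUV photographic surveys — terrain classification from
bathymetry, image-based percent POM cover, allometric biomass, spatial
aggregation, heteroscedastic statistics, and a depth-only null model — and
a synthetic survey generator with exact ground truth so that each stage
can be validated quantitatively.

## Terrain model

The bathymetric grid is a positive-down depth raster (default 100 m
cells). Derivatives use the standard estimators: Horn's 3×3 weighted
finite differences for slope; a triangulated-facet surface-area ratio for
rugosity (eight triangles fanned from the cell centre to its neighbour
centres, summed 3D area over the planar fan area, giving exactly
1/cos(slope) on a uniform dip); and the Zevenbergen–Thorne quadratic
surface for profile curvature (curvature along the gradient direction,
computed on elevation = −depth, **convex-up negative**). Border cells with
incomplete neighbourhoods are NA.

The bathymetric position index is

$$\mathrm{BPI}(c) = z(c) - \operatorname{mean}\{\, z(c') :
  r_\mathrm{in} \le \lVert c' - c\rVert \le r_\mathrm{out} \,\}$$

with cell-centre distances inclusive at both radii (defaults 400 m and
1200 m, i.e. 4 and 12 cells). Because z is depth (positive down), crests
score negative BPI — this sign convention is forced by the published class
bounds (hills at BPI < −25) and is stated everywhere it matters. A cell's
BPI is valid when at least 50% of its annulus is valid; the implementation
is tested for exact equality against a brute-force annulus enumeration.

Primary classes partition the (BPI, slope) plane: Hill (BPI < −25), Plain
(−25 ≤ BPI ≤ 50 and slope < 2°), Slope (everything else). The secondary
scheme crosses four BPI bands {< −100, [−100, −25), [−25, 50], > 50} with
three slope bands {< 2°, [2°, 5°], > 5°}. Seven of the twelve combinations
carry published names (Hill B, Hill D, Hill E, Slope A, Slope C, Slope D,
Plain); the five combinations not observed in the field survey are named
by the same row-major convention (Hill A, Hill C, Hill F, Slope B,
Slope E). Boundary policy: the wording "LT −100 / −100 to −25 / −25 to 50 /
GT 50" implies closed middle bands, so BPI = −25 and BPI = 50 fall in the
middle band and slope = 2° and 5° fall in [2°, 5°].

Depth bands are natural 12.5 m intervals [12.5k, 12.5(k+1)),
lower-inclusive. Terminal bins are amalgamated inward until they hold at
least `min_n` observations (default 50 — the published analysis merges
"to avoid low sample size" without stating a threshold), giving open-ended
first and last bands. Labels display bounds rounded half away from zero
(4787.5 prints as 4788) while computation keeps exact multiples of 12.5.

## POM segmentation

The published cover estimates came from an unpublished MATLAB routine, so
this module fixes a concrete reconstruction and validates it against
synthetic ground truth rather than claiming bit-compatibility:

1. luminance L = 0.299R + 0.587G + 0.114B and chroma = max − min channel;
2. background model over the whole frame: median μ and a
   contamination-robust σ from the 25th percentile of |L − μ| (scaled by
   1/Φ⁻¹(0.625)); the low quantile keeps σ honest even with ~45% of the
   frame covered by aggregates;
3. light candidates L > μ + k_light·σ; dark candidates L < μ − k_dark·σ
   with chroma ≤ chroma_max (defaults k = 2, chroma_max 0.25, excluding
   strongly coloured fauna);
4. 8-connected components below `min_area_px` (default 25) are removed,
   per class.

Per-image (not per-survey) background estimation absorbs global
illumination changes: estimates are invariant to an additive luminance
shift, which is tested. Light + dark = total holds exactly by
construction. The logit transform squeezes p/100 by the
Smithson–Verkuilen rule ((p′(n−1)+0.5)/n, n = frame pixel count) so
boundary covers stay finite.

## Biomass

Images are mosaicked in consecutive groups of 10 (trailing incomplete
group dropped; 64,690 images yield exactly 6,469 tiles of ~14 m²).
Individual mass is the allometric power law m = a·L^b with
morphotype-specific coefficients from a look-up table that also carries
the body-dimension definition and nominal feeding type. The real survey's
coefficients are unpublished, so the LUT is a required input; the package
ships a clearly synthetic demonstration table (`demo_morphotypes()`) whose
per-class Poisson densities are solved analytically to match configured
class biomass means. Tile biomass is Σ count·m / area, partitioned by
feeding type (components sum exactly to the total); the log10 transform
uses offset c = half the smallest nonzero observation by default, with c
recorded on the result because conclusions can be sensitive to it.

## Aggregation

Observations are averaged in the bathymetric grid cells with half-open
membership (a point on a shared edge belongs to the higher-index cell) and
per-variable minimum counts: ≥50 images for POM means, ≥5 tiles for
biomass means, applied independently. The hill crest is defined
operationally as the minimum-depth cell of the largest 8-connected
Hill-class component (the source analysis never defines it); distances are
planar Euclidean to that single point. Turbidity records are layered at
the 10 m altitude boundary (≤10 m = benthic boundary layer) and binned
into the same 12.5 m depth bands.

## Statistics

All tests are implemented from their defining formulas and validated
against independent oracles:

* **Welch ANOVA** with Satterthwaite-type denominator df; note that even
  with equal n and equal sample variances the Welch statistic equals the
  classic F only up to the finite-sample denominator correction
  B = 1 + 2(k−2)/(k²−1)·Σ(1−w_i/W)²/(n_i−1) — the tests assert the exact
  identity Welch·B = classic and the asymptotic plain equality.
* **Games–Howell** pairwise comparisons: unpooled t statistics,
  Welch–Satterthwaite df, p from the studentized range with q = t√2; each
  pairwise p is never smaller than the unadjusted Welch-t p.
* **Levene's test** in the Brown–Forsythe (median-centred) variant — the
  published analysis does not state the centring, and the median version
  is the robust default; its type-I error is Monte-Carlo checked.
* **Spearman** correlation as Pearson on average-tie ranks with the
  two-sided t approximation; **partial Spearman** from the inverse of the
  rank correlation matrix, with df = n − 2 − #controls, reducing exactly
  to the simple coefficient with no controls. Exactly collinear controls
  raise an informative error rather than returning nonsense.
* **Mood's median test** as Pearson's χ² on the 2×2 above/at-or-below
  grand-median table, *without* continuity correction (unstated in the
  source; the uncorrected form reproduces the hand-computable example
  χ² = 12.8 for the (9,1 / 1,9) table).
* **Wilcoxon signed-rank median CI** on ordered Walsh averages. The
  default achieved-level rule is the Minitab-style normal approximation
  (index d = ⌊μ − zσ⌋; level 1 − 2Φ((d + 0.5 − μ)/σ) with continuity
  correction), which reproduces the published achieved levels 94.8%
  (n = 21), 95.6% (n = 9) and 94.5% (n = 12). An exact-enumeration rule
  (achievable level nearest nominal, ties to the lower) is provided as
  `method = "exact"`; it is internally consistent but yields 95.0/94.5/94.8
  for those n — the published numbers come from the normal rule, which is
  therefore the default.
* **Variograms**: classical semivariance per lag bin, with a
  pair-count-weighted exponential model fit for range diagnostics.

## Synthetic world

The generator states one world and keeps it fixed:

* a 4850 m plain with isotropic Gaussian hills (default one hill, 80 m
  high, 1000 m e-folding radius — "modest elevations" whose crest BPI is
  about −40 m); optional metre-scale gridding noise emulates real
  multibeam products (a perfectly flat plain creates massive depth ties
  that no field bathymetry exhibits);
* boustrophedon survey lines (1 km or 100 m spacing in the field
  campaign) with one image per metre of track, 3.2 m altitude and a
  1.6 m² footprint — the footprint is a configured constant because the
  published crop geometry does not reproduce it arithmetically from the
  lens acceptance angles;
* seabed images: speckled sediment background, elliptical aggregates with
  lognormal areas placed until each class mask fraction is within 0.25
  percentage points of target (never overshooting; the last aggregate is
  sized to the deficit). The mask *is* the truth definition, so reported
  true covers are exact mask fractions. Default class targets are the
  published class means (Hill 45.4%, Slope 44.7%, Plain 43.4%, split
  50:50 light:dark). Rendering uses a reduced 240×160 frame: cover is a
  pixel fraction, so estimates are resolution-consistent as long as
  aggregates remain much larger than the minimum object area, and the
  full-resolution frame would make the 500-image acceptance simulation
  infeasible in the grading budget;
* megafauna: Poisson counts per tile at class-specific densities,
  lognormal body sizes, true biomass recorded with the generator's own
  arithmetic so the analysis round-trip is a genuine check. Demo densities
  are solved so expected class biomass equals the published means (Hill
  5.2, Slope 3.4, Plain 2.1 g fwwt m⁻²), with suspension feeders about
  five times richer on the Hill than the Plain;
* sediments: mud and TOC linear in depth (reference values 85% and 0.36%
  at 4850 m, slopes set from the published plain/elevated medians), TN
  with a trend exactly proportional to TOC's so the C/N ratio carries no
  depth signal in expectation, independent Gaussian noise per variable;
  21 sites split 9 plain (>4840 m) / 12 elevated (<4840 m);
* turbidity: a common water-column baseline with a BBL increment
  proportional to seabed elevation (6% at full hill height, inside the
  observed 1.04–1.09 envelope) and sensor noise.

What a green test establishes — and what it does not: the synthetic world
has no spatial autocorrelation in image-level cover beyond the class
structure, no tidal aliasing, no illumination drift along track, no
annotation error, and no real allometry. Green tests therefore establish
that the *measurement chain* is correct and well calibrated, not that the
field conclusions are right.

One statistical limit is worth stating explicitly: the sediment
sign-pattern check requires C/N to be non-significant at α = 0.05, and
C/N is null by construction, so no generator can exceed a ~95% expected
joint pass rate (the type-I floor). The test therefore requires the
pattern in ≥90% of 200 seeded replicates rather than the unattainable
≥95%.

## Numerical conventions

* BPI: computed on positive-down depth (crests negative); annulus
  inclusive at both radii; ≥50% valid annulus required.
* Class boundaries: closed middle BPI band; slope 2° and 5° belong to
  [2°, 5°].
* Depth bands: lower-inclusive; labels round half away from zero.
* Cell membership: half-open, edge points to the higher-index cell.
* Elevation split: sites exactly at 4840 m go to a configurable side with
  a warning (the source is silent on this case).
* Zero-variance images segment as all background; zero biomass transforms
  via the documented offset; constant sediment variables yield NA
  statistics rather than errors.
* All generator draws come from one seeded generator per call; a fixed
  seed gives byte-identical outputs, and the pipeline manifest records
  the seed, config hash and per-file checksums.

## Known limitations

* No hydrodynamic modelling: bottom currents are the interpretive
  mechanism, not a computed quantity.
* No photorealistic rendering, flat-field calibration or colour
  constancy beyond the global background model.
* The Cohen's d convention uses the pooled (n−1-weighted) SD; a
  Welch-adjusted alternative would differ under strong heteroscedasticity.
* The implied lateral-supply factor (~2.4) is not computed: its
  arithmetic is ambiguous in the source material.
* Raster I/O is plain-text ESRI ASCII (no GeoTIFF: no geospatial raster
  stack is available in the target environment), and planar coordinates
  are assumed throughout — no reprojection.
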