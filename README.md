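# vertphen

Vertical phenotyping of rice from front-view images.

Conventional shoot traits (height, tiller count, mean leaf angle) collapse a
plant to scalars that ignore *where along the stem* structure sits, yet
drought and rehydration reshape rice architecture vertically: panicle
emergence raises the plant's mass centre, water stress keeps lower leaves
spread, rewatering compacts the canopy. `vertphen` extracts
vertically-resolved architectural traits from a single front-view RGB image
of a potted plant, for phenotyping researchers relating shoot form to water
treatment and growth status.

## Traits

From a binary plant mask obtained by HSV colour thresholding:

* **RHC** — relative height of the plant centroid,
  `RHC = Centroid Height / Plant Height`, the height of the silhouette's
  binary-moment centroid above the plant bottom as a fraction of the
  droop-filtered plant height. Locates the plant's growth focus; 0.5 for a
  vertically uniform silhouette.
* **Vertical leaf-angle distribution** — each leaf line segment (skeleton +
  progressive Hough transform) yields an inclination `A` (degrees from
  horizontal, folded into [0, 90]) and a relative height
  `RH = 100 · H / PH` of its midpoint; the pairs are fitted with

      A = a · ln(RH + 1) + b

  where `b` is the basal angle (at RH = 0) and `a` the rise of inclination
  per ln-unit of height — the canopy's vertical heterogeneity. Typical
  ranges at most growth stages: `a` in 0–20, `b` in −20–90; negative `a`
  (late-heading compaction) is flagged, not rejected.
* **ALA** (mean segment inclination), **GPAR** (green fraction of plant
  pixels, a senescence indicator) and **PAR** (perimeter/area of the
  silhouette, tiller compactness).

Downstream statistics: one-way ANOVA with Tukey HSD across treatment
groups, and multivariate linear regression of trait combinations against
measured growth responses (above-ground dry matter; canopy extinction
coefficient, always consumed as a measurement, never computed from images).

A fully ground-truthed synthetic plant generator (straight leaf strokes
with known angles, midpoints, organ labels and pixel mass) makes every
stage testable without photographs.

## Worked example

```r
library(vertphen)

g   <- generatePlant(syntheticPlantSpec(aTrue = 10, bTrue = 30, seed = 1))
res <- analyzePlantImage(g$image)
res$geometry
#> PlantGeometry
#>   extent rows : 32 .. 353  (PH = 321 px)
#>   centroid    : (200.1, 191.6)  height 161.4 px
#>   RHC         : 0.5029
#>   area        : 4499 px   perimeter 2384.3 px (+75.5 holes)
res$fit
#> AngleModelFit: A = 10.033 * ln(RH + 1) + 30.540
#>   n = 16, r = 0.951, RMSE = 2.19 deg, converged = TRUE
```

The plant was rendered from `a = 10, b = 30` with 2° of angular noise; the
pipeline re-measures `â = 10.03, b̂ = 30.54` from the image alone, and the
RHC of 0.503 matches the generator's pixel-mass truth of 0.496. The ground
truth for this image (`g$truth`) carries every per-leaf angle and midpoint,
which is how the test suite scores stroke-level recovery.

Batch processing and the statistics stage:

```r
traits <- runPipeline(c("day1.png", "day2.png"), pipelineConfig(),
                      outputDir = "out/")          # writes out/traits.csv
anovaTukey(traitTable, "rhc", "group")             # F, p, Tukey pairs, stars
mlrFit(traitTable, c("fit_a", "fit_b", "rhc"), "adm")
```

A thin command-line wrapper with subcommands `segment`, `traits`,
`fit-angles`, `synth` and `stats` is installed at
`inst/scripts/vertphen.R`.

## Documentation

The methods vignette (`vignettes/vertical-phenotyping.Rmd`) describes the
model and its assumptions, every tunable parameter with units and defaults,
what the synthetic generator does and does not emulate, and the package's
numerical design choices.
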