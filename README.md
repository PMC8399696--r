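# seedgeom

Quantitative description and classification of seed silhouettes in the
grape family (Vitaceae) using algebraic curve models.

Seed outlines in this family resemble a small repertoire of closed planar
figures — lenses, superellipses, water drops and heart curves. All of the
factor-product models derive from the ellipse written as the product of its
two semi-ellipse branches,

    (sqrt(1 - x^2) - b*y) * (sqrt(1 - x^2) + b*y) = 0,

modified by rational shape kernels `K(x) = amp / D(x)` that add an apical
beak or a basal entry; lenses and superellipses use
`|x/a|^p + |y/b|^q = 1`. Similarity between a segmented seed silhouette and
a model is measured by the **J index** — the percentage ratio of shared to
total surface area of the two superimposed silhouettes
(`J = 100 |A∩B| / |A∪B|`), maximized over a similarity transform — and a
silhouette is assigned to one of ten morphological groups (or left
*UNDEFINED*) according to its best-scoring model. The package also ships
the published registries (named models with parameters, the ten groups with
member species, the taxonomy and observed-species tables) and a
synthetic-silhouette generator with controlled radial deformation for
validation without real images.

Intended users: plant morphologists and archaeobotanists quantifying seed
shape, and anyone needing reproducible silhouette-to-model scoring.

## Worked example

Render a registered model, rasterize it, and classify the mask:

```r
library(seedgeom)

s  <- rasterize(build_polygon(get_model("PPE1"), 1024), 256)
ga <- classify_seed(s)
glance(ga)
#> # A tibble: 1 × 5
#>   group best_model best_J   tau n_models
#>   <chr> <chr>       <dbl> <dbl>    <int>
#> 1 VIII  PPE1        100.0    80        8

tidy(ga)
#> # A tibble: 8 × 5
#>   model group     J scale      theta
#>   <chr> <chr> <dbl> <dbl>      <dbl>
#> 1 PPE1  VIII  100.0 108.  -0.0000283
#> 2 PHI1  V      95.0 110.   0.00406
#> 3 AAR1  III    92.4 108.   0.00666
#> 4 VAM1  IV     92.3 111.   0.00520
#> 5 ACO1  V      90.7 112.  -0.0106
#> 6 AGL1  IV     89.7 115.   4.20
#> 7 SE1   II     87.1 104.   1.57
#> 8 LENS1 I      79.1  92.4 -0.182
```

The render of model PPE1 (the flat-based heart curve of *Pseudocayratia*)
scores J ≈ 100 against its own model and is assigned group VIII; the next
best model, the broad-beaked heart PHI1, reaches J = 95. `scale` is the
fitted scale in pixels per model unit and `theta` the fitted rotation
(radians). Shape descriptors summarize a model's outline:

```r
shape_descriptors(get_model("VAM1"))
#> # A tibble: 1 × 4
#>   model aspect_ratio beak_height entry_depth
#>   <chr>        <dbl>       <dbl>       <dbl>
#> 1 VAM1          1.15       0.208           0
```

(a water drop: 15% taller than wide, a 0.21-unit beak, no basal entry).

Real images enter through `binarize("seed.png")` (Otsu threshold, largest
component, hole filling) followed by `normalize_orientation()`. Synthetic
test material comes from `synthetic_spec()` / `generate_silhouette()`. A
thin command-line front end is installed as `exec/seedgeom`
(`seedgeom render VAM1 --png out.png`, `seedgeom classify mask.png`, ...).

See the vignette `vignettes/seed-geometry.Rmd` for the model equations,
the reconstruction decisions behind them, the superposition search, and
known limitations.

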