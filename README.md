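# citrusect

Dissecting sensorily scored citrus fruit quality traits — easiness of
peeling (**Peeling**) and fruit hardness (**FruH**) — into quantitative
cross-section morphology.

Breeders score these traits on a 1–5 ordinal scale by hand and feel, which
makes large-scale phenotyping expensive and the morphological basis of the
scores opaque. `citrusect` implements the full analysis chain that makes
the "breeder's sense" measurable from flatbed-scanner cross-section images:

1. **Synthetic fruit generator** — parametric cross-sections (flavedo and
   albedo rings, flesh locules and septa, seeds, central core, degradation
   cavities) with exact ground-truth region masks, a genotype × year
   population structure, and trait scores generated from a known linear
   model, so every downstream method can be validated against known truth.
2. **Region segmentation** — rule-based recovery of the 8 canonical regions
   (Whole, Flavedo, Albedo, DegAlbedo, Flesh, Seed, Center, DegCenter) from
   RGB images via CIE L\*a\*b\* thresholds and radial geometry.
3. **Feature extraction** — the 21 standard morphological features: areas
   (normalized by whole area), equivalent-circle radius, circularity
   4πA/P², locule count / mean central angle / angle variance, mean
   L\*a\*b\* colors, albedo thickness (normalized by radius), seed count,
   degradation areas. Undetectable regions follow the set-to-0 convention.
4. **Year adjustment** — mixed model `y = μ + year (fixed) + genotype
   (random) + e` fitted by profiled REML; genotype BLUPs are the expected
   phenotypic values used downstream.
5. **Explainable association battery** — pairwise collinearity filter
   (|r| ≥ 0.95), MLR on z-scored features, random forest with shadow-feature
   (Boruta-style) importance, partial dependence, decision-path interaction
   scores, repeated 10-fold CV with shared partitions (Pearson r, RMSE,
   paired test), apparent vs partial correlations via the precision matrix.
6. **Bayesian networks** — Gaussian BIC-scored hill-climbing and tabu
   structure search with a trait-endpoint blacklist, bootstrap model
   averaging (arc strength and direction confidence), consensus network.
7. **CNN + Grad-CAM** — a small from-scratch convolutional classifier for
   binary trait classes and gradient-weighted class-activation maps,
   quantified as mean relevance per fruit region over correctly predicted
   images, with a between-class rank test.

The random forest, Bayesian-network search, REML/BLUP solver, CNN and
Grad-CAM are implemented inside the package (R + Rcpp); they depend only on
base R, `Rcpp`, `png`, `jsonlite` and `yaml`.

## Worked example

```r
library(citrusect)
set.seed(42)

# one synthetic fruit with ground-truth masks, and its 21 features
fr <- render_fruit(fruit_spec(), seed = 42)
fv <- extract_features(fr$image, fr$masks)
round(fv[c("Whole area", "Circularity", "Locule number", "Locule angle",
           "Albedo thickness", "DegCenter area")], 3)
#>       Whole area      Circularity    Locule number     Locule angle
#>            0.347            0.996           10.000           31.951
#> Albedo thickness   DegCenter area
#>            0.103            0.020

# segmentation recovers the regions from pixels alone
sm <- segment(fr$image)
dice(fr$masks$Flesh, sm$Flesh)
#> 0.961

# population -> BLUP genotype values -> association and causal structure
pop <- sample_population(30, n_years = 2, fruits_per_genotype_year = 3,
                         render = FALSE)
ph <- generate_traits(pop$truth, pop$meta, trait_model("Peeling"))
vars <- c("DegCenter area", "DegAlbedo area", "Whole area")
long <- rbind(
  do.call(rbind, lapply(vars, function(v)
    data.frame(genotype = pop$meta$genotype, year = pop$meta$year,
               variable = v, value = pop$truth[, v]))),
  data.frame(genotype = ph$genotype, year = ph$year,
             variable = "Peeling", value = ph$continuous))
G <- adjust_genotype_values(long)

fit_mlr(G[, vars], G[, "Peeling"])$coefficients[, c("feature", "estimate", "p_value")]
#>          feature estimate  p_value
#> 1 DegCenter area   -0.659 7.97e-09
#> 2 DegAlbedo area   -0.265 4.57e-03
#> 3     Whole area    0.451 1.23e-05

bl <- trait_blacklist(colnames(G), "Peeling")
bc <- bootstrap_average(scale(G), "hc", replicates = 100, blacklist = bl)
head(bc$arcs[order(-bc$arcs$strength, bc$arcs$from), ], 2)
#>              from             to strength direction_confidence
#> 3  DegCenter area        Peeling        1                    1
#> 10        Peeling DegCenter area        1                    0
```

The standardized MLR coefficients recover the generative signs (core
degradation eases peeling, larger fruit peel harder), and the bootstrap-
averaged network orients core degradation *into* the trait with full
direction confidence — the blacklist forbids arcs leading away from the
trait, and the bootstrap quantifies how stable each arc is under
resampling.

## Command line

```sh
inst/cli/citrusect simulate  --config sim.yaml --out data --seed 1
inst/cli/citrusect segment   --image fruit.png --out labels.png
inst/cli/citrusect features  --image fruit.png --masks labels.png --out fv.csv
inst/cli/citrusect adjust    --in phenotypes_long.csv --out genotype_values.csv
inst/cli/citrusect associate --matrix genotype_values.csv --traits Peeling,FruH --out assoc
inst/cli/citrusect network   --matrix genotype_values.csv --trait Peeling --replicates 5000 --seed 1
inst/cli/citrusect xai       --data data --trait Peeling --seed 1
```

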