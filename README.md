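# ectofauna

Macroecological analysis of ectoparasite faunas — the sets of flea and mite
species recorded on small mammal host species across their geographic
ranges. The package answers two questions about a host community given a
phylogeny, a trait table, gridded range maps, environmental layers and a
parasite × host incidence matrix:

1. **What drives parasite species richness per host?** Richness is modelled
   with negative-binomial GLMs (log link) on log body mass, log geographic
   range size, log diversity field (the mean number of other hosts
   co-occurring within the focal host's range) and habitat breadth. All 16
   predictor subsets are ranked by AIC; the best model is summarised by
   explained deviance and Nagelkerke's R². A Blomberg K/K* permutation test
   on richness runs first and warns if phylogenetic signal is present.

2. **What makes two hosts share a parasite?** For each parasite recorded on
   at least 6 hosts, incidence cases (carrier sources vs. sampled
   non-carriers) are regressed logistically on a normalized between-host
   distance — phylogenetic (cophenetic), trait (Gower, 18 mixed traits),
   geographic (haversine between range centroids) or environmental
   (Euclidean on PCA scores of 100-km-buffered climate profiles). A species
   bootstrap pools per-parasite coefficients into a mean intercept *a* and
   slope *b*; the sharing probability curve is *P(D) = 1/(1+e^(−(a+bD)))*
   and PNS is the proportion of parasites with negative slopes.

Because the empirical compilations behind such analyses cannot be
redistributed, the package ships a synthetic-realm generator (pure-birth
phylogeny, Brownian traits, contiguous gridded ranges, correlated
environmental layers, incidence matrices with *planted* richness or sharing
coefficients) so every stage is validated by parameter recovery. See
`vignettes/methods.Rmd` for the models, assumptions and numerical choices.

## Worked example

The `analysis/` directory holds the numbered workflow. Stage 1 simulates a
60-host × 30-parasite realm on a 20°×20° one-degree grid with a planted
sharing kernel (*a* = 2, *b* = −6 on trait distance); stages 2–5 run the
full analysis from the written CSV inputs:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_range_metrics.R
Rscript analysis/03_distances.R
Rscript analysis/04_richness.R
Rscript analysis/05_sharing.R
```

which prints, among other things:

```
range size: median 324841 km^2 (IQR 211527-421833)
diversity field: median 5.9 co-occurring species
environmental PCA: 2 components, 77.7% of variance
phylogenetic signal in richness: K* = 0.156, p = 0.009
best model: ln_BM (ED = 6.0%, Nagelkerke R2 = 0.053)
PD: a =  0.819, b = -1.044, PNS = 0.70 (30 parasites)
TD: a =  1.500, b = -2.572, PNS = 0.87 (30 parasites)
GD: a = -0.018, b =  0.009, PNS = 0.53 (30 parasites)
ED: a = -0.055, b =  0.066, PNS = 0.47 (30 parasites)
```

Reading this: the realm was generated in *sharing* mode, so host richness
is a by-product of the sharing kernel rather than of the richness
predictors — the best richness model is weak (ED = 6%), while the sharing
analysis points at the planted driver: the trait-distance slope is the most
negative and has the highest PNS (0.87), with phylogenetic distance partly
echoing it (traits evolve on the tree), and the two distances unrelated to
generation (geographic, environmental) show slopes near zero and PNS near
0.5. The pooled curves in `results/analysis/curve_*.csv` give *P(D)* on a
101-point grid.

The same machinery is available programmatically:

```r
library(ectofauna)
w <- simulate_world(world_config(n_hosts = 150, n_parasites = 60, seed = 1))
fit <- pooled_coefficients(w$incidence, w$distances$TD, n_iter = 200, seed = 2)
print(fit)
sharing_probability(fit$a, fit$b, c(0, 0.5, 1))
```

`run_pipeline(default_config(outdir = "out"))` runs simulation, range
metrics, distances, richness selection and sharing end to end from a single
(YAML-serialisable) configuration, writing every artifact plus a JSON run
report; identical config and seed give byte-identical outputs.

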