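# canopynorm

Normalisation and analysis of canopy temperatures measured by infrared
imaging of replicated field trials.

## The problem

Canopy temperature is a proxy for stomatal conductance — genotypes that
transpire more run cooler — so thermal imaging of a field trial is a
fast, non-destructive screen for stomatal behaviour. But a trial of
hundreds of plots takes many images to cover, and between images the
mean canopy temperature drifts by several degrees with cloud cover,
irradiance and wind, while genotype differences are only a few tenths
of a degree. `canopynorm` implements the normalisation chain that makes
such data usable, plus the statistics needed to decide whether the
genotypic signal is real, for plant physiologists and breeders running
thermal phenotyping campaigns.

## The method

For plot $p$ observed in image $i$ the model is additive,
$y_{pi} = b_i + g_{g(p)} + u_p + e_{pi}$, with $b_i$ the image-level
environmental baseline. The chain is:

1. **IPT** — the plot's mean canopy-pixel temperature in one image,
   from a sampling polygon with an automated median ± k °C outlier trim
   (`extract_plot_temperature()`);
2. **IINPT** — IPT minus the mean of all plot IPTs in the same image
   (`compute_iinpt()`), removing $b_i$ exactly;
3. **NPT** — the mean of a plot's IINPTs over the images covering it
   (`compute_npt()`); images are taken with deliberate overlap so most
   plots are measured more than once;
4. **normalised genotype temperature** — the mean NPT over replicate
   plots (`genotype_means()`).

A sum-to-zero least-squares fit of $y = g + \mathrm{image} +
\varepsilon$ (`fit_additive_model()`) provides the model-based
alternative, and `compare_estimators()` quantifies their agreement.
Downstream, `anova_twoway()` / `anova_on_means()` test genotype and
genotype-by-day effects, `monte_carlo_randomization()` computes a
permutation null with its *apparent LSD* (the difference magnitude
chance alone generates), `spearman_rho()` / `extreme_subset_rho()` /
`correlation_matrix()` assess ranking consistency, and
`forward_stepwise()` relates yield to temperature, maturity and height.
A synthetic-trial generator (alpha-type layouts, overlapping
acquisition plans, pixel-level frames, correlated harvest traits) makes
the whole chain testable end to end.

## Worked example

```r
library(canopynorm)
cfg <- read_run_config(system.file("extdata", "demo_config.yaml",
                                   package = "canopynorm"))
res <- run_pipeline(cfg, "demo_run")
```

The demo simulates a 48-genotype, 2-replicate trial imaged on 3 days
and runs the full analysis, logging:

```
design: 48 genotypes x 2 reps, 6 x 16 plots
day 1: 12 images, 288 observations, mean coverage 3.00
method agreement (day 1): Pearson r = 0.9745, mean difference = -3.326e-18
genotypes explain 85.8% of variation in daily means
randomisation: p = 0.0050, observed range 1.152 vs apparent LSD 0.501
```

Reading the numbers: the two genotype-mean estimators (image-mean
differencing vs the additive model) agree at r = 0.97 with no bias;
genotypes account for 85.8% of the variation in daily means; and the
observed spread of genotype means (1.15 °C) is more than twice the
apparent LSD (0.50 °C), the spread that re-randomising genotype labels
within each day could produce — so the ranking is not chance
(permutation p = 0.005, the smallest value 199 replicates allow).

```r
print(res$stepwise)
#> Forward stepwise selection (n = 48, full-model r2 = 0.302)
#>  step        term    r2_cum partial_f      p_value r2_pct
#>     1 temperature 0.2764447  17.57496 0.0001241846  27.6%
```

Canopy temperature alone explains 27.6% of simulated yield variation;
maturity and height do not clear the 5% partial-F entry threshold at
this trial size.

All outputs (design, per-day observations, genotype summaries, ANOVA
tables, randomisation summary, correlation matrices, stepwise report)
are written to the run directory as CSV/text, and reruns with the same
config are byte-identical.

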