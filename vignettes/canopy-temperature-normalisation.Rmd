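---
title: "Normalising canopy temperatures from overlapping thermal images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normalising canopy temperatures from overlapping thermal images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canopynorm)
```

## The problem

Canopy temperature is an indirect readout of stomatal conductance: a
genotype that keeps its stomata open transpires more and runs cooler.
Imaging a replicated field trial with a hand-held or platform-mounted
infrared camera is therefore an attractive high-throughput screen for
stomatal behaviour. The catch is environmental drift. A trial of several
hundred plots cannot be captured in one frame; over the sequence of
images the mean canopy temperature wanders by several degrees as cloud
cover, irradiance and wind change, while the genotypic signal of
interest is only a few tenths of a degree per genotype. Raw plot
temperatures from different images are simply not comparable.

`canopynorm` implements a normalisation and analysis chain for this
setting, together with a synthetic trial generator that reproduces its
statistical structure, so every stage can be validated without access to
a particular field campaign.

## The normalisation chain

Three quantities organise the pipeline:

* **IPT** — individual-image plot temperature: the mean of the canopy
  pixels sampled by a polygon inside one plot, in one image
  (`extract_plot_temperature()`).
* **IINPT** — individual-image normalised plot temperature: the IPT
  minus the unweighted mean of all plot IPTs in the same image
  (`compute_iinpt()`). IINPTs sum to zero within each image, and are
  exactly invariant to adding any constant to all of an image's
  observations — the additive environmental component is removed, not
  estimated.
* **NPT** — normalised plot temperature: the mean of a plot's IINPTs
  over every image that covers it (`compute_npt()`).

Normalised genotype temperatures are the means of NPTs over replicate
plots (`genotype_means()`). Acquisition deliberately overlaps images —
the camera advances by fewer plots than its footprint — so most plots
are measured two or more times; the overlap both tightens the image
means used as normalisers and adds replication at the plot level.

The underlying model is additive:

$$ y_{pi} = b_i + g_{g(p)} + u_p + e_{pi} $$

with $b_i$ the per-image environmental baseline, $g$ the genotype
effect, $u_p$ a persistent plot effect and $e_{pi}$ independent
observation noise. Image-mean differencing removes $b_i$ exactly under
this model; a multiplicative genotype-by-irradiance interaction would
not be removed, which is why the simulator's default generative model is
additive (matching the assumption the method relies on) and why
`fit_additive_model()` exists as a cross-check.

## Two estimators of the genotype effects

`fit_additive_model()` fits $y = g + \text{image} + \varepsilon$ by
ordinary least squares with sum-to-zero constraints, reporting genotype
effects as deviations from the grand mean. It plays the role that a
REML mixed-model fit plays in larger analyses; with both effect sets
fixed, least squares is the transparent, oracle-checkable version of
the same adjustment. Differencing remains the package default — it is
direct, closed-form and field-book friendly — with the model fit used
to confirm that nothing systematic separates the two.

Two properties of the pair are worth knowing:

* They coincide *exactly* only when images are genotype-balanced (for
  instance, each image covering one complete replicate), making image
  and genotype effects orthogonal. Equal image sizes and disjoint
  coverage are not sufficient: on a disjoint tiling whose images are
  not genotype-balanced the two estimators differ, because least
  squares pools genotype information across images while differencing
  does not. The test suite pins both facts numerically.
* Differencing carries a small irreducible *composition* noise: the
  subtracted image mean includes the genotype effects of whichever
  plots happen to share the image. With ~24 plots per image this term
  is small, and across seeded replicate simulations of the default
  scenario the two estimators' genotype means correlate above 0.95 —
  the agreement bound the acceptance script recomputes. For recovering
  the *true* effects the additive model is slightly better, and it is
  the estimator against which the package's parameter-recovery property
  is tested.

## Significance analysis

`anova_twoway()` tests genotype, day and genotype-by-day interaction on
plot-level NPTs; a non-significant interaction is the evidence that
genotype ranking is stable across the season. For balanced tables the
orthogonal decomposition is computed directly from cell and marginal
means; unbalanced tables (lost plots) fall back to sequential Type I
sums of squares in the order Genotype, Days, Interaction, with a note —
no attempt is made to emulate any particular package's adjustment for
missing plots. `anova_on_means()` treats per-day genotype means as
replicates and reports the percentage of variation explained by
genotype.

`monte_carlo_randomization()` asks the sharper question of whether the
observed spread of genotype means could be chance: genotype labels are
re-randomised independently *within each day* (preserving each day's
multiset of values and any day-level structure), and each randomisation
yields a null F, a null genotype-mean range, and an **apparent LSD** —
the least significant difference computed from the null analysis, i.e.
the difference magnitude that label noise alone generates. The p-value
uses the add-one correction $(b+1)/(m+1)$, which makes the test exact at
level $\lfloor\alpha(m+1)\rfloor/(m+1)$ under exchangeability; with the
default 1000 replicates the achievable levels are dense enough for any
practical $\alpha$. The LSD itself uses the standard t-based form
$t_{1-\alpha/2,\,\mathrm{df}}\sqrt{2\,\mathrm{MS_E}/n}$.

Rank consistency uses Spearman's rho with average ranks
(`spearman_rho()`), on the full genotype set or on the `k` coolest plus
`k` hottest genotypes by mean rank (`extreme_subset_rho()`, ties in
mean rank broken by genotype identifier so selection is deterministic).
`correlation_matrix()` adds per-day mean columns to show the gain from
averaging repeated measures within a day. No multiplicity adjustment is
applied to these correlation panels; treat them as descriptive.
`forward_stepwise()` relates yield to canopy temperature, maturity and
height by forward selection with a partial-F entry test at 0.05,
reporting the cumulative r-squared path; maturity (scored 1-9, 9 = less
mature) is treated as a numeric covariate.

## The synthetic trial generator

`generate_layout()` produces a resolvable randomised incomplete-block
layout: replicates form contiguous superblocks and, within each
replicate, genotypes are partitioned at random into blocks of
`block_size` plots (default 8) whose field order is also randomised.
This reproduces the randomisation structure of an alpha design without
optimising block concurrences — nothing downstream depends on
alpha-optimality, only on the randomisation. The default geometry is
192 genotypes in two replicates at 16 plots per field row (24 rows);
where a trial description is ambiguous between "planted in 16 plot
rows" and a 24-row by 16-plot grid, the package reads 16 as
plots-per-row, which is the only reading consistent with 384 plots.

`plan_acquisition()` emulates the camera pass: footprints of up to 9
plots by 4 rows, an advance smaller than the footprint, and an integer
jitter on each image origin so the overlap is deliberate but not
systematic. Coverage of every plot is guaranteed (patch images are
appended in the rare case jitter opens a gap). `simulate_baselines()`
drives the environmental drift as a Gaussian random walk with occasional
±`cloud_step_size` shocks; the sign is random because cloud banks both
arrive and clear during a session, and the differencing analysis is
invariant to the baseline path in either case.

Default generative parameters, chosen once to represent a cool-climate
well-watered trial:

| parameter | default | meaning |
|---|---|---|
| `sigma_g` | 0.4 °C | genotype effect SD; gives ≈2 °C range across 192 genotypes |
| `sigma_obs` | 0.3 °C | per-observation noise (wind gusts, viewing geometry, sensor) |
| `sigma_plot` | 0.1 °C | persistent plot effect (soil, establishment) |
| `sigma_day` | 0 °C | genotype-by-day instability (off: stable ranking) |
| `drift_sd` | 0.2 °C | baseline random-walk SD per image |
| `cloud_step_prob`, `cloud_step_size` | 0.05, 4 °C | abrupt irradiance shocks |
| `base_temp` | 20 °C | session mean canopy temperature |

The split of plot-level noise into a dominant per-observation component
and a small persistent component reflects how thermal plot readings
behave: most of the scatter between repeated images of the same plot
comes from moment-to-moment wind and geometry, not from a fixed plot
offset. The package's validation properties are calibrated to these
defaults as the study conditions; they are not tuning knobs.

`render_thermal_frame()` optionally descends to pixel level: covered
plots tile a 320 × 240 frame, each sampled by an axis-aligned rectangle
eroded 20% from its cell (canopy, avoiding edges and bare ground),
against a hotter sunlit-soil background. The manual histogram check
used when polygons are drawn by hand is automated as a symmetric
median ± k °C trim (default k = 3 °C) with a QC flag when more than 20%
of pixels are excluded; the trim moves with the median, so extraction is
exactly equivariant under constant shifts. Pixel membership uses the
even-odd rule on pixel centres in 0-based coordinates — unambiguous and
brute-force verifiable.

What the simulator does **not** emulate: perspective distortion of
oblique images, radiometric calibration error (constant camera
parameters drop out of a relative analysis), wind/boundary-layer
physics, spatial field trends, and multiplicative
genotype-by-irradiance interactions (available but off by default —
`sigma_day` reintroduces ranking instability additively). A pass on
synthetic data therefore shows the chain is correct *under the additive
model*, not that field data obey that model.

## Numerical choices and degenerate inputs

* Sum-to-zero constraints make genotype and image effects identifiable;
  genotype effects are always reported centred, so differencing and the
  model fit are directly comparable.
* A disconnected plot-image graph (two blocks of the field never
  sharing an image) leaves only within-component contrasts
  identifiable; `fit_additive_model()` detects this by union-find and
  warns.
* Image means are computed over QC-passing observations only; a
  soil-contaminated plot would otherwise bias the normaliser for every
  plot in its image.
* Unweighted means throughout: plots are the experimental unit, so
  pixel counts do not weight plot values and image counts do not weight
  NPTs.
* Single-replicate genotypes keep their mean; their standard error is
  reported missing rather than zero.
* Permutations, layouts and noise draws all flow from explicit integer
  seeds; every simulating function leaves the caller's RNG state
  untouched.

## Problem sizes used by the validation suite

The shipped tests exercise the full 192 × 2 trial for layout, ANOVA
degrees of freedom, normalisation invariance and estimator agreement
(100 seeded replicates); parameter recovery runs 200 full-size
scenarios; randomisation calibration runs 500 zero-effect simulations of
a 48-genotype trial with 199-replicate permutation tests, a size at
which the add-one p-value grid makes the nominal 5% level exact. These
sizes were chosen so the complete suite runs in well under a minute per
property while keeping binomial/KS checks adequately powered.

## Limitations

The package analyses one trial at a time; multi-environment modelling,
spatial row-column adjustment and variance-component (true REML)
estimation are out of scope, as are camera file formats and interactive
polygon drawing. The alpha-design generator randomises but does not
optimise; if design efficiency matters, generate the layout elsewhere
and import it with `read_design()`.
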