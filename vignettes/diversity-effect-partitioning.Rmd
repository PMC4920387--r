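---
title: "Partitioning diversity effects under varying resource availability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning diversity effects under varying resource availability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(befpart)
```

## The experiment and the questions it answers

`befpart` analyses replacement-series biodiversity experiments in which
perennial grassland species are grown in monocultures and mixtures under
crossed light (shading) and nutrient (fertilization) manipulations.  The
reference design has 96 plots in 8 blocks: two independent pools of four
species, each pool crossing two functional groups (grass, forb) with two
growth statures (small, tall).  Every block holds, per pool, two
monocultures, three two-species mixtures and one four-species mixture;
four whole blocks are shaded, and within every block half the plots of
each richness level are fertilized.  Each species composition is observed
exactly once in each of the four resource environments (F-S-, F-S+, F+S-,
F+S+); the four-species mixtures twice.

The scientific questions are (i) whether mixtures overyield relative to
their monocultures, (ii) how the net diversity effect decomposes into
complementarity and selection-type components, (iii) whether resource
availability shifts that decomposition, and (iv) which aspects of
functional trait composition predict each component.

## Overyielding and the tripartite partition

For a mixture of $S$ species sown at equal proportions, let $Y_{Oi}$ be
species $i$'s observed mixture biomass and $BM_i$ its monoculture biomass
in the *same* resource environment (the monoculture-reference-per-
environment rule).  Relative yields are $RY_i = Y_{Oi}/BM_i$, the relative
yield total is $RYT = \sum_i RY_i$, non-transgressive overyielding is
$D_{mean} = (Y_O - \overline{BM})/\overline{BM}$ and transgressive
overyielding is $D_{max} = (Y_O - \max_i BM_i)/\max_i BM_i$.

The net diversity effect $NE = Y_O - Y_E$ (with
$Y_E = \sum_i BM_i / S$) splits into three additive components:

* **TICE** (trait-independent complementarity)
  $= S\,\overline{\Delta RY}\,\overline{BM}$, with
  $\Delta RY_i = RY_i - 1/S$: a uniform average increase in relative
  yields.  Identical to the Loreau–Hector complementarity effect.
* **DE** (dominance) $= S\,\mathrm{cov}(BM_i,\; RY_i/RYT - 1/S)$:
  high-monoculture-biomass species capture mixture share at the expense
  of others.
* **TDCE** (trait-dependent complementarity)
  $= S\,\mathrm{cov}(BM_i,\; RY_i - RY_i/RYT)$: high-monoculture-biomass
  species gain relative yield without depressing others.

Two numerical conventions matter.  First, the covariances use the
population form (divide by $S$); only then does
$NE = TICE + TDCE + DE$ hold as an exact identity, which the test suite
checks to $10^{-9}$ relative error on fuzzed inputs.  Second, the
dominance covariance can be written with argument $\Delta RY_i / RYT$ or
$RY_i/RYT - 1/S$; the two differ by a within-mixture constant and give
identical covariances, which is asserted against an independent
summed-deviation implementation.  The Loreau–Hector two-way partition
($CE = TICE$, $SE = TDCE + DE$) is computed alongside as an algebraic
cross-check.

```{r partition}
p <- tripartite_partition(y_obs = c(50, 200), bm_mono = c(100, 200))
p
```

Two caveats are worth stating explicitly because they shape
interpretation:

* $D_{mean} = RYT - 1$ is **not** an identity, although it is often
  quoted as one.  $D_{mean}$ weights species by the monoculture mean
  while $RYT$ weights by each species' own monoculture; they coincide
  exactly when monoculture biomasses are equal or relative yields are
  uniform, and only approximately otherwise.
* Within a single mixture, $TDCE = (RYT - 1) \cdot DE$ identically
  (both covariances are scalar multiples of
  $\mathrm{cov}(BM_i, RY_i)$).  The two components decouple only across
  mixtures, through variation in $RYT$.  A consequence for simulation
  design is that per-mixture TDCE and DE cannot be dialled
  independently.

## Percent gains and one-sample tests

Percent biomass gains per component are reported as a ratio of group
means, $100\,\overline{\text{component}}/\overline{Y_E}$, which is robust
when individual $Y_E$ are small; the mean-of-ratios convention is
available as an option (`percent_gain_summary(method =
"mean_of_ratios")`).  Overall overyielding is tested with two-sided
one-sample t-tests ($RYT \ne 1$, $D_{max} \ne 0$, components $\ne 0$),
by default ignoring block structure; a block-means variant is provided
(`test_mean_against(block = )`) for readers who prefer the conservative
aggregation.

## Trait composition

Community-weighted means $CWM = \sum_i p_i t_i$ and single-trait Rao
quadratic entropy $FD = \sum_i \sum_j p_i p_j d_{ij}$ are computed per
mixture for six traits (SLA, SRL, LNC, RNC, Hmax, WMD), with relative
abundances $p_i$ taken from annual biomass proportions and trait values
matched to the plot's resource environment.  The per-trait distance
$d_{ij}$ is the absolute trait difference on the raw scale; a
range-scaled (Gower) option differs only by a positive per-trait factor,
which cancels in any rank-based use.  The predictor matrix for inference
holds 12 columns (CWM and FD for six traits); all FD columns and the
CWM columns for SRL, RNC and LNC are natural-log transformed.  Mixtures
in which a sown species is missing from the biomass (FD undefined as
specified) or in which a log transform would hit a non-positive value
are excluded, with the reason recorded — these exclusions change the
analysis *n* and must stay auditable.

## Inference

**Sequential ANOVA.**  Fixed effects enter in a fixed order — shade,
fertilization, log species richness, functional-group composition,
growth-stature composition, then all two- and three-way interactions —
and each term is tested given all earlier terms (type I SS).  Random
intercepts are block and mixture identity at the community level; block,
plot-in-block, mixture identity and species identity at the species
level.  Denominator degrees of freedom are approximated by Satterthwaite
(default) or Kenward–Roger (when pbkrtest is available); both are
recorded in the output.

**Design-based fallback.**  `method = "permutation"` replaces the df
approximation with re-randomization inference: the treatment assignment
is re-drawn under the experiment's own randomization scheme, holding the
composition layout fixed — shading is re-assigned to 2 of the 4 blocks
within each template group, and fertilization roles are re-permuted
within pool and template group.  Because the re-draws follow the same
conditional distribution that produced the actual assignment, the test
is exact under the global null of no treatment effect.  Two details are
deliberate: (i) the block-level shade randomization has only
$\binom{4}{2}^2 = 36$ distinct assignments, so ties in the Monte-Carlo
reference are resolved uniformly at random (a randomized, "fuzzy"
p-value), restoring exact uniformity of the p-value under the null;
(ii) terms not involving a randomized factor (richness, composition)
receive `NA` p-values under this method, because species composition is
not randomized relative to species identity — use the df-approximation
methods for those terms.

**Multimodel inference.**  All candidate models with up to three of the
12 trait predictors (299 models including the null) are fitted by
maximum likelihood with a block random intercept, ranked by AIC (AICc by
flag), and averaged over the $\Delta < 4$ set with full
(zero-substitution) averaging; a predictor's relative importance is the
sum of renormalized Akaike weights of the models containing it.
Predictors are z-scored after the log transforms, so averaged estimates
are standardized; whether standardization should precede the transform
is genuinely ambiguous in the source material, and the package fixes
the transform-then-standardize order.  The candidate fits use an
internal profiled-ML solver for the single-random-intercept
compound-symmetry model (whitening is closed-form per block, leaving a
one-dimensional profile over the variance ratio); it reproduces
`lmer(REML = FALSE)` log-likelihoods and AICs to numerical precision —
asserted in the test suite — and `engine = "lmer"` is available.

## The synthetic-data generator

`generate_experiment()` emulates the study conditions with known ground
truth:

* **Design**: the full 96-plot layout, built constructively from two
  complementary half-block templates per pool so that all balance
  constraints (composition-per-environment coverage, species three times
  per block, fertilization balance within block and richness level) hold
  for every seed.
* **Biomass**: monoculture biomass $M_{ie}$ is lognormal around species
  × environment means with CV 0.26 (matching reported monoculture
  means of order $900 \pm 240\,\mathrm{g\,m^{-2}}$); the environment
  means carry multiplicative shade (0.76) and fertilization (1.36)
  effects with no interaction by default.  Mixture species biomass is
  $M_{ie}\,(1/S + \Delta RY^{true}_i)\,\beta_b\,\varepsilon_i$ with a
  mean-one lognormal block multiplier ($\sigma_{\log} = 0.15$) and
  per-species noise ($\sigma_{\log} = 0.2$) — together a mixture-plot CV
  close to the monoculture CV.
* **True diversity effects**: $\Delta RY^{true}$ composes a uniform
  complementarity shift `delta_c` (default 0.21), a zero-sum transfer
  toward higher-$M$ species `delta_d` (default 0.5), and a non-zero-sum
  `delta_t` (default 0).  Defaults were calibrated once so the mean
  percent-gain decomposition lands near the reference experiment's
  headline split (NE ≈ +34%, TICE ≈ +21%, DE ≈ +12%, TDCE minor); the
  exact per-mixture truth is always computed by applying the partition
  formulas to the noise-free skeleton (`true_partition()`), never from a
  closed form.
* **Dropouts**: by default one species dies (biomass 0) in two
  two-species plots, reproducing the exclusion bookkeeping of the field
  analyses (62 of 64 mixtures enter the trait models).
* **Traits**: species × environment trait values are lognormal around
  structured means (e.g. shade raises SLA and Hmax, fertilization raises
  tissue N) with persistent per-species × trait deviations
  ($\sigma_{\log} = 0.25$) so that species combine traits
  idiosyncratically and single-trait FD predictors are not collinear
  across traits.

One structural choice deserves emphasis: the species-level lognormal
deviation is *shared* across environments (comonotone draws), so each
$M_{ie}$ is marginally lognormal around its environment mean, but
environments differ only through the systematic multipliers.  This makes
"no treatment effect" a sharp null — a plot's biomass genuinely does not
depend on its treatment assignment — which is what a calibration study
of the treatment tests requires.  The cost is that the generator does
not emulate species × environment interaction noise (a species being
idiosyncratically good in one environment) or plot-level noise on the
monoculture observations themselves; both exist in real data, where the
single monoculture per species × environment makes relative yields
noisier than in these simulations.  Passing recovery tests therefore
demonstrates correctness of the estimators under the stated conditions,
not immunity to reference-monoculture noise.

## Numerical and design choices

* Replicated monocultures (a generalization beyond the reference design)
  are averaged arithmetically.
* Species that die in mixture are kept as biomass-0 rows so $S$ and sown
  proportions stay correct; a *zero monoculture reference* instead
  excludes the affected mixtures from the partition with a logged
  reason, rather than propagating infinite relative yields.
* The sequential-ANOVA engine drops terms confounded with earlier ones
  (aliased columns) and reports them as missing rather than failing.
* `optimize()` profiles the MMI variance ratio on the log scale over
  $[e^{-15}, e^{10}]$, with the boundary fit ($\lambda = 0$, i.e. no
  block variance) checked explicitly.
* All generator randomness flows through a single integer seed;
  identical seeds give byte-identical outputs.

## Problem sizes used by the checks

The packaged checks run the partition identity on 10,000 random
mixtures, oracle equivalence on 500 fuzzed mixtures, multiplier recovery
on 1,000 simulated experiments, component-recovery bias on 500, type-I
calibration on 2,000 null experiments with 199 re-randomizations each,
and multimodel recovery on 200 experiments — sizes chosen to make the
Monte-Carlo error small relative to the tolerances being asserted.

## Known limitations

* TDCE is deliberately minor under the default conditions, and the
  ratio-form estimator of a small component inherits a noticeable
  relative bias from noise in $RYT$ (see the recovery check); the other
  components are recovered essentially unbiased.
* The re-randomization method calibrates treatment terms only; richness
  and composition terms rely on the df-approximation methods, whose
  small-sample behaviour with 8 blocks is approximate.
* The generator's dominance mechanism operates through monoculture
  biomass ranks; it does not model light-competition mechanisms
  (height-structured asymmetry) explicitly.
* Multi-trait functional diversity indices (FDis, FRic), unequal sowing
  densities, and multi-year dynamics are out of scope.
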