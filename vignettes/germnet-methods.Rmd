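---
title: "germnet: methods, models, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{germnet: methods, models, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(germnet)
```

## Overview

`germnet` analyzes plant and rhizosphere-microbiome expression profiles
measured on the same samples as one interacting system. The package covers
five stages — compositional preprocessing, permutation-based community
statistics, Fisher-z differential correlation between kingdoms across two
temperature conditions, trait-association modeling with a three-method
consensus, and a synthetic-data generator with a truth registry — wired
together by `run_pipeline()`. This vignette explains the statistical models
behind each stage, the parameters that matter, what the generator emulates,
and the choices made where the design was genuinely open.

## The differential-correlation model

The core statistic asks, for every plant gene $g$ and microbial feature
$m$: did the strength of their association change between the optimal
condition (A, e.g. 28 °C) and heat (B, 38 °C)?

Within each condition the association is Spearman's $\rho$ (midranks for
ties), which is invariant to monotone transforms — so whether the inputs
are median-of-ratios normalized plant counts or CLR-transformed microbial
pathways does not affect it, only the *sample subset* does. Each $\rho$ is
variance-stabilized by Fisher's transformation $z = \mathrm{atanh}(\rho)$,
and the contrast is

$$\Delta z = z_B - z_A, \qquad
  SE = \sqrt{\tfrac{1}{n_A - 3} + \tfrac{1}{n_B - 3}}, \qquad
  Z = \Delta z / SE,$$

with a two-tailed normal p-value and Benjamini–Hochberg adjustment over
all tested pairs. A pair is *significant* when both $q < 0.05$ and
$|\Delta z| > 1$: the FDR threshold controls false discovery, and the
$|\Delta z|$ floor discards statistically detectable but practically
negligible shifts. Positive $\Delta z$ means the association strengthened
under heat.

Assumptions worth stating:

- **Independent sampling between conditions.** The SE formula assumes the
  two condition subsets are independent groups of samples, which holds for
  the factorial design (different pots in different chambers).
- **The $1/(n-3)$ variance is the Pearson-based classic.** For Spearman
  correlations the asymptotic variance is about 6% larger; the package
  follows the standard practice of using the Pearson form. The measured
  consequence on null data (see the acceptance suite) is a raw-$p$
  rejection rate of ≈ 0.051 at the 0.05 level — slightly anticonservative
  but well within the calibration band the tests enforce, and immaterial
  after the BH + $|\Delta z|$ double threshold.
- **Tested family.** Pairs untestable in either condition (a feature
  constant within the subset) are removed *before* BH, so the family size
  reflects tested pairs only.

Numerical choices: the far tail is computed via
`pnorm(..., lower.tail = FALSE)` (erfc-based), accurate for $|Z| > 8$ where
`1 - pnorm(Z)` would underflow; an empirical $\rho = \pm 1$ (possible at
finite $n$) is clamped to $\pm(1 - 10^{-7})$ inside the scan operation so a
single degenerate pair does not abort a whole-matrix analysis — the scalar
`fisher_z()` keeps the strict error default, with clamping opt-in.

## Compositional preprocessing

Counts from community sequencing carry no absolute scale, so microbial
tables are treated compositionally: relative abundance (total-sum scaling)
and the centered log-ratio
$\mathrm{clr}(x)_i = \ln(x_i + c) - \frac{1}{p}\sum_k \ln(x_k + c)$,
which maps compositions into a Euclidean geometry where PCA, distances,
and PERMANOVA are meaningful. The CLR is invariant to per-sample scaling,
so applying it to raw counts or relative abundances is equivalent — a
property the tests assert rather than assume. The pseudocount defaults to
0.5 and is only added when zeros are present; it is configurable because
zero-handling is the one genuinely arbitrary choice in the transform.

Plant counts instead get DESeq2-style median-of-ratios size factors:
$s_j = \mathrm{median}_i\, k_{ij} / (\prod_j k_{ij})^{1/n}$ over reference
features with positive counts in all samples, rescaled so the geometric
mean of the size factors is 1 (which makes the single-sample case the
identity). This recovers planted size factors *exactly* when samples are
multiplicative rescalings of each other — the sharpest test the operation
admits.

Rarefaction subsamples each column without replacement to a fixed depth;
under-depth samples are dropped with a warning rather than erroring,
because heterogeneous depths are the norm and a hard failure would make
the operation unusable in pipelines. Pathway aggregation sums member-gene
counts; genes annotated to several pathways count once per pathway (EC and
KEGG maps are many-to-many), and unannotated genes are kept in an
explicit `unassigned` bin so mass is never silently lost.

The three default filter rules are: plant genes need ≥ 75 reads in ≥ 4
samples, microbial genes ≥ 250 reads in ≥ 3 samples, and taxa are kept
only when present in ≥ 2 samples *and* ≥ 10 reads in ≥ 2 samples. The
taxon rule is often written ambiguously in workflow descriptions ("omit
taxa present in fewer than two samples or with fewer than 10 reads in at
least two samples"); the implementation reads it as removing
low-prevalence *and* low-abundance taxa, which matches the rule's purpose.
The alternative reading (omit when < 10 reads in ≥ 2 samples) would
delete abundant taxa that happen to have two low-count samples and was
rejected.

## Permutation statistics

`permanova()` partitions the distance matrix's total sum of squares
($\sum d^2 / n$) by design terms using the Gower-centered inner-product
form $G = -\frac{1}{2} C D^{(2)} C$; each term's SS is the increment of
$\mathrm{tr}(H G)$ as its columns enter the hat matrix — sequential
(Type-I) SS, matching the convention of the ecology packages this follows,
with term order given by the caller. Significance permutes sample labels;
p-values use the add-one convention $(1 + \#\{F^* \ge F\})/(1 + n_{perm})$,
which can never return 0 and makes "p = 2e-04 at 5000 permutations"
the smallest reportable value. For $n \le 8$ an exhaustive mode enumerates
all $n!$ orderings and reports the exact fraction — this is what the
package's own oracle tests use.

`mantel()` correlates the upper triangles of two distance matrices by
Spearman and permutes one matrix's sample order (rows and columns
jointly); one-sided (greater), add-one convention, matching the cited
ecosystem's default. The platform slope test regresses alternative-platform
per-taxon means on the reference platform's (OLS with intercept) and tests
$H_0\!: b = 1$ one-sided below via $t = (b-1)/SE(b)$; the choice of which
platform plays regressor is genuinely open, so the reference-as-predictor
orientation is fixed here and documented. A noise-free degenerate fit
($SE = 0$) reports $p = 0.5$ at $b = 1$, else 0 or 1 by sign.

## Trait models and consensus

Before modeling, features with $|\rho| \le 0.05$ against the response are
dropped. This step is sometimes described as filtering out "features with
weak univariate correlations (ρ > 0.05)", a self-contradictory phrasing —
retaining only weak features would be nonsensical — so the implementation
retains $|\rho| > 0.05$. At this threshold the filter is a
mild dimensionality reducer, not a discovery step — on pure noise at
$n = 48$ a substantial fraction of features pass.

The elastic net (`glmnet`, $\alpha = 0.5$) is fit on standardized features
with $\lambda$ chosen by 10-fold cross-validation at minimum CV error
(a 1-SE-rule flag exists); fold assignment is fixed by the seed so runs
are reproducible. Nonzero coefficients at the chosen $\lambda$ are the
method's hit set. The random forest is a regression forest written for
this package (no RF implementation is available in the deployment
environment): bagged CART trees, per-node feature subsampling
(`mtry = p/3`), minimum node size 5, importance as mean decrease in node
impurity, with out-of-bag predictions returned for diagnostics. Importance
is computed on the full fit; cross-validation serves error estimation,
not importance extraction. The top 25 features are kept
*per feature-type stratum* (plant genes and microbial pathways ranked
separately), so the plant kingdom's systematically higher importances
cannot crowd out microbial features.

The consensus counts, per trait, how many of the three methods
(differential correlation, elastic net, random forest) identified each
feature; features with ≥ 2 hits are selected. A feature counts as
"identified by differential correlation" when it belongs to at least one
significant differential pair — no canonical mapping from pairs to
features exists, and this is the least committal choice. The cross-trait
tally (the "k of 9 tests" count) defaults to 3 methods × 3 traits
(heat score, shoot biomass, root volume); the trait set is configurable
so a fourth trait (root:shoot ratio) can be included, giving a
"k of 12" tally instead.

## The synthetic world

The generator emulates a growth-chamber factorial — 3 genotypes × 2 soils
(field/autoclaved) × 2 temperatures (28 °C/38 °C) × 4 replicates = 48
samples — with desk-scale feature counts (defaults: 400 plant genes, 300
microbial genes, 40 pathways, 50–100k reads/sample); real experiments of
this kind publish no per-feature dispersions or library models to match,
so the defaults aim at realistic orders of magnitude, not at any
particular dataset.

- **Plant counts** are negative binomial (dispersion 0.2) around
  gene-specific log-normal baselines times a per-sample library factor,
  with designated genes carrying ±1 log2-fold temperature, soil, or
  genotype effects (10% of genes for temperature, 5% each for the other
  factors, by default).
- **Microbial counts** are compositional: log-normal per-sample
  proportions drawn into a multinomial at the sample's depth, so column
  sums equal the drawn depths exactly. Temperature and soil effects
  perturb log-proportions for designated genes.
- **Planted cross-kingdom pairs** share a Gaussian latent per sample whose
  correlation is $\rho_A$ in optimal samples and $\rho_B$ in heat samples.
  Targets are on the Spearman scale; the latent Pearson correlation is
  back-transformed through the Gaussian copula identity
  $\rho_S = \frac{6}{\pi}\arcsin(\rho_P/2)$. Planted features ride high
  baselines with low dispersion so count noise attenuates the planted
  correlation only mildly (observed Spearman lands within ±0.15 of target,
  which the tests verify by Monte Carlo over 200 generations).
- **Trait features** (5 plant genes, 3 pathways by default) load on a
  shared stress latent $u$ mixed with feature-specific components
  ($0.6u + 0.8e_f$, unit variance). The mixture matters: if all features
  were clones of one latent they would be statistically redundant and no
  selection method could be expected to recover each of them — the
  registry's per-feature coefficients would be unidentifiable. Shoot
  biomass is exactly the registered linear combination of the features'
  standardized log abundances plus $N(0, \sigma)$ noise
  ($\sigma = 0.5$ by default); root volume tracks the same signal at 0.6
  gain; the heat score thresholds a latent stress (a temperature shift of
  1.3 minus the registered feature contributions plus $N(0, 0.35)$ noise)
  into five bins at standard-normal quintile cutpoints, yielding an
  ordinal 0–4 score that rises with temperature and is negatively
  correlated with biomass by construction.
- **Seeding.** One master seed; substreams (`seed+1` plant counts,
  `seed+2` microbial counts, `seed+3` phenotypes) so each matrix is
  independently reproducible. Identical seeds give byte-identical output.

What the generator does *not* emulate: sequencing reads and alignment
artifacts, taxonomy, rRNA contamination, the bulk-soil no-plant controls,
batch effects, and the long-tailed depth distributions of real libraries.
A green test therefore establishes that the statistics behave correctly on
data satisfying their model assumptions — not that the pipeline is robust
to upstream bioinformatic failure modes.

An interaction worth knowing about: per-sample library factors are shared
across all genes of a kingdom, so on *raw* counts any chance correlation
between the two kingdoms' depths within a condition subset induces
correlated pairs en masse — visible as excess differential correlations.
This is not a bug but a faithful reproduction of why one normalizes before
correlating; the pipeline runs the differential test on median-of-ratios /
CLR matrices, where the effect vanishes (and the null-calibration
acceptance test runs on the normalized path).

## Degenerate inputs and tie-breaks

Spearman ties use midranks throughout. Features constant within a
condition subset yield `NA` correlations, are counted, and are excluded
from the BH family. `filter_low_expression` returning an empty matrix is a
warning, not an error (an empty survivor set is a legitimate outcome of a
strict rule); an all-zero sample in `relative_abundance` is an error naming
the sample. Network edges use signed $\rho >$ threshold by default (a
positive-association rule), with an `use_abs` flag for the absolute-value
variant.

## Known limitations

- The forest implementation targets importance ranking, not prediction
  accuracy: no honest splitting, no permutation importance (the impurity
  measure is biased toward high-cardinality features, immaterial here
  because all features are continuous abundances).
- PERMANOVA permutes freely; restricted permutation schemes for nested or
  repeated-measures designs are out of scope.
- The pipeline's resume logic is checksum-based at the manifest level;
  partial stage outputs are retained on failure but stages re-run whole.
- Exhaustive PERMANOVA enumeration is limited to $n \le 8$ samples
  ($8! = 40320$ orderings).
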