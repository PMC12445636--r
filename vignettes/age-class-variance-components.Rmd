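---
title: "Variance components of boar semen traits across age classes"
author: "semenvc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variance components of boar semen traits across age classes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semenvc)
```

## The problem

Artificial-insemination boars are collected repeatedly from about 7 to 60
months of age, and their ejaculates are scored for semen quantity
(volume, concentration, total sperm cells) and quality (motility and
morphology percentages). Two features make the genetic analysis of such
longitudinal records delicate:

* repeated records per boar share both genetic and non-genetic
  ("permanent environment") animal effects, and
* boars with poor semen quality are culled during production, so records
  at older ages come from a selected subset of animals. Raw trait
  averages by age then mix the true ageing trend with the survivorship
  of good boars, and variance components estimated from old-age records
  alone are biased downward.

`semenvc` implements the two models that address this, a synthetic-data
generator that emulates the data-generating process including culling,
and REML machinery to estimate all parameters.

## Models

### The repeatability animal model

For a single trait,

$$y = X\beta + Za + Wp + Hh + Cc + e$$

with fixed effects $\beta$ for age of the boar at collection (monthly
classes), rest days since the previous collection (15 one-day classes)
and month of the year (12 classes); and independent random effects
$a \sim N(0, A\sigma^2_a)$ (additive genetic, $A$ the pedigree
relationship matrix), $p \sim N(0, I\sigma^2_{pe})$ (permanent
environment), $h \sim N(0, I\sigma^2_{hys})$ (herd-year-season of
birth), $c \sim N(0, I\sigma^2_{clt})$ (collector-lab technician) and
residual $e \sim N(0, I\sigma^2_e)$.

Phenotypic variance, heritability and repeatability are
$\sigma^2_p = \sigma^2_a + \sigma^2_{pe} + \sigma^2_{hys} +
\sigma^2_{clt} + \sigma^2_e$, $h^2 = \sigma^2_a / \sigma^2_p$ and
$rep = (\sigma^2_a + \sigma^2_{pe}) / \sigma^2_p$.

### The trivariate age-class model

Records are split into three age classes — early production (7–13 mo),
peak (14–23 mo) and post-peak (24–60 mo) — and the same trait in the
three classes is treated as three correlated traits. The additive
genetic and permanent-environment effects get unstructured $3\times3$
covariance matrices $\Sigma_a$ and $\Sigma_{pe}$; herd-year-season,
technician and residual effects are class-specific with cross-class
covariances fixed to zero (residuals of the same boar at different ages
are independent given $a$ and $p$). Within each class the age factor
uses the class's own monthly levels (7, 10 and 37 when all months are
present); rest-day and month-of-year effects are common across classes,
the only reading of the class structure that keeps those
well-identified factors estimable from every record.

Because essentially every boar is collected in the early class before
any culling can act, a joint fit that includes the early class lets the
likelihood correct the later classes for selection on the phenotype —
this is the standard multivariate-selection argument, and the reason
the trivariate estimates of $\sigma^2_a$ at old ages exceed estimates
from a univariate fit of the old-age records alone. The package's
`selection_demo()` reproduces both this contrast and the corresponding
contrast between predicted and unadjusted age-effect curves.

### Predicted age effects

`predict_factor_means()` predicts the phenotype per age month as the
intercept plus the month's own fixed effect plus the average of every
other fixed factor's effects; random effects contribute zero. Equal
weights across the other factors' levels are the default; observed
frequencies are available (`weights = "observed"`). Equal weighting was
chosen as the default because it makes predictions comparable across
datasets with different rest-day or seasonal usage patterns; the two
options coincide in balanced data.

## REML machinery

Variance components are estimated by restricted maximum likelihood.
The criterion is evaluated through Henderson's mixed-model equations
(MME): with coefficient matrix $M$ and diagonal residual matrix $R$,

$$-2\ell = (n - p)\log 2\pi + \log|R| + \log|G| + \log|M| + y'Py,$$

identical (not just up to a constant) to the dense
$\log|V| + \log|X'V^{-1}X| + y'Py$ definition; the test suite asserts
this equivalence against an independent dense implementation at
tolerance $10^{-8}$.

The optimiser is a hybrid:

1. **EM warm start** (5 iterations by default): component-wise updates
   from BLUP quadratic forms and traces of the inverse MME coefficient
   matrix. Monotone, extremely stable, slow near optima.
2. **Average-information (AI) Newton steps** afterwards. The AI matrix
   is $\tfrac12 F'PF$ with $F$ holding the vectors $V_i Py$. The step
   is taken in the Cholesky factor of $\Sigma_a$ and $\Sigma_{pe}$, so
   positive semidefiniteness can never be violated, with a
   Levenberg–Marquardt damping ladder for ill-conditioned systems. Each
   iteration accepts whichever of the AI candidate and an over-relaxed
   EM proposal (extrapolation factors 2–16) improves the likelihood
   more, so the trajectory is monotone by construction.
3. **Boundary handling**: scalar variances are floored at
   $10^{-8}\,\mathrm{var}(y)$; $\Sigma$ proposals are clipped by a
   symmetric eigenvalue floor at $10^{-8}$ of their trace. Parameters
   pinned at the floor are excluded from the sampling-covariance
   computation and reported with `NA` standard errors.

### Convergence and likelihood-flat ridges

Convergence is declared when the relative likelihood change is below
$10^{-8}$ and the maximum relative parameter change below $10^{-6}$.
That joint rule alone turned out to be unattainable in a practically
important regime: when the true cross-class genetic correlations are
all close to one, $\Sigma_a$ is nearly singular and the REML optimum
lies on a likelihood-flat ridge along which EM keeps drifting the
parameters at a roughly constant (slow) rate without changing the fit.
The optimiser therefore also declares convergence when the absolute
likelihood improvement stays below `tol_flat` (default $3\times10^{-3}$, far
below any meaningful likelihood-ratio difference) for three consecutive
iterations. On replicate fits the reported correlations change by less
than about $0.005$ between this stopping point and hundreds of further
crawl iterations, while the runtime drops several-fold.

Sampling covariances of the estimates come from the inverse AI matrix
at convergence; standard errors of heritability, repeatability,
correlations and component differences use the first-order delta
method, the standard practice behind published REML standard errors.

Starting values split the per-class phenotypic variance equally across
the included components, with cross-class correlations started at 0.5.

## The synthetic-data generator

`simulate_dataset()` draws a discrete-generation pedigree (founders,
random non-self sire × dam matings, configurable matings and progeny
per generation), samples class-specific breeding values down the
pedigree by the Mendelian-sampling recursion (joint covariance exactly
$A \otimes \Sigma_a$, with inbreeding reducing the sampling variance),
and builds one record per ejaculate as mean + age-curve + rest-day +
month effects + class-specific $a$ and $p$ + herd-year-season (one
level per generation × birth quarter) + technician (drawn per record
from a pool of 20) + class-specific residual.

Defaults emulate the reference population: collections every month
from 7 to 60 months at 1.5 ejaculates per month on average (roughly 80
per boar), quality-trait age curves that rise to a peak at about 13
months and decline after, quantity curves that plateau at about 18
months, and per-class variance components taken from the reference
genetic-parameter table for a commercial boar line. The
permanent-environment cross-class correlations are not published for
that population; the generator uses 0.85 for all pairs, a plausible
value for environmental carry-over, fixed once. Only genetic
correlations are recovery targets.

Culling is phenotype-based, not breeding-value-based: a boar whose
running mean of the watched trait over its last $k$ records falls below
a population quantile is culled with a per-month probability, and later
records are dropped. This mirrors station practice, where boars are
removed for observed poor semen quality.

What the generator does **not** emulate: measurement-system error
structure (CASA machine effects), non-Gaussian raw-scale distributions
(simulation happens directly on the analysis scale, so REML recovery
targets do not depend on the unknown transformation scaling),
unbalanced ejaculate counts per boar (the real 5th–95th percentile
range of 7–202 ejaculates is only loosely matched by the regular
schedule), and economically motivated culling. Passing recovery tests
therefore demonstrates correctness of the estimation machinery under
the stated model, not robustness to violations of it.

## Trait transformations and filters

Motility percentages are right-skewed and morphology percentages
left-skewed; the analysis scale uses a cubic transformation
$t = y^3 \cdot 10^{-4}$ for motility and a log transformation
$t = 100\ln(y+1)$ for morphology. The multiplicative constants are the
package's own choice (the conventional transformations are defined only
up to scale); they keep transformed values on a percent-like range and
give transformed-scale variances of the order seen in the reference
population. Quantity traits are analysed untransformed.

The minimum-ejaculate filter keeps a boar's records within an age class
only when the boar has at least 3 ejaculates in that class. Per-class
removal (drop the deficient class's records, keep the boar elsewhere)
is the default; whole-boar removal is available behind
`whole_boar = TRUE`, since either reading is defensible.

## Significance testing

Pairwise differences between variance components at different ages are
tested with a Z-test on the difference, using the joint sampling
covariance of the two estimates. With 12 traits, 4 components (additive
genetic, permanent environment, residual, phenotypic) and 3 class
pairs, the family holds 144 tests and the Bonferroni-adjusted threshold
at a nominal 0.05 is $3.5\times10^{-4}$
($-\log_{10} = 3.46$). Which four components enter the family is
configurable, as the decomposition is a convention.

## Problem sizes and verification

Every stage is verified by tests that run in minutes on one CPU:

* pedigree algebra against dense tabular oracles on random pedigrees up
  to 200 animals (max abs error $<10^{-8}$);
* MME solutions and the REML criterion against dense GLS /
  conditional-mean formulas on instances of at most 30 records;
* EM monotonicity, fixed-effect reparameterisation invariance, scale
  equivariance, and exact agreement with one-way ANOVA estimators on
  balanced unrelated designs ($10^{-6}$);
* parameter recovery at scale: 30 replicates of 800 phenotyped boars
  (three generations, 12 ejaculates each in one class) for univariate
  heritability and repeatability, and 20 replicates of 400 boars with
  6 ejaculates per age class for the trivariate genetic correlations —
  mean estimates land within about $\pm0.015$ of the reference rows'
  values;
* selection properties: under culling, the univariate post-peak genetic
  variance falls below the trivariate estimate, and model-predicted age
  curves beat unadjusted means against the true curve, in the large
  majority of replicates.

The replicate counts and herd sizes were chosen so that the Monte-Carlo
standard error of each recovery mean is well below the acceptance
bands; the phenotyped set spans multiple generations because
parent–offspring records are what separate additive-genetic from
permanent-environment variance in practice.

## Known limitations

* Dense pedigree algebra (A, inbreeding) is $O(n^2)$ and guarded at
  5,000 animals; industrial pedigrees (tens of thousands of animals)
  would need the recursive inbreeding algorithm alone, which is
  provided, plus a sparse-only code path for the tabular oracle.
* The per-iteration cost of REML is dominated by a dense inverse of the
  MME coefficient matrix for the EM/AI traces; around 3,000 equations
  this costs roughly a second per iteration. A supernodal selected
  inverse would lift this ceiling.
* Random-regression (polynomial) alternatives to the age-class
  partition are out of scope by design.
* Standard errors are first-order delta approximations; they inherit
  the usual optimism of AI-based covariances near parameter boundaries.
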