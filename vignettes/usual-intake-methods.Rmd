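---
title: "Estimating usual-intake distributions from single 24-hour recalls: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating usual-intake distributions from single 24-hour recalls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(usualintake)
```

## The measurement-error model

A 24-hour recall records what one person ate on one day. For planning
fortification programmes or estimating the prevalence of inadequate
intake, the quantity of interest is instead *usual intake*: each
person's long-run average daily intake. The package treats the recall
as an unbiased but noisy instrument for usual intake — not that a recall
measures a day's intake without error, but that the average of many
recalls would converge to the person's usual intake.

On a Box-Cox transformed scale, a person-day intake is modelled as

$$g(R_{ij};\lambda)=\beta_0+\sum_k\beta_k X_{ki}+\sum_l\beta_l Z_{lij}
  + u_i + e_{ij},\qquad g(x;\lambda)=\frac{x^\lambda-1}{\lambda},$$

with $g(x;0)=\log x$. The $X_{ki}$ are person-level covariates (age,
group indicators), the $Z_{lij}$ temporal covariates (a weekend
indicator), $u_i\sim N(0,\sigma^2_u)$ is the person effect (usual
intakes genuinely differ between people beyond what covariates explain)
and $e_{ij}\sim N(0,\sigma^2_e)$ the day-to-day error. The model is
restricted to *nearly-daily consumed* components — fewer than 5% zero
intakes — so a single amount model suffices and no consumption-
probability part is needed; episodically consumed foods are out of
scope.

Two assumptions matter in practice: recalls within a person must be
from nonconsecutive days (independence of the $e_{ij}$), and the
transformation must render both random terms approximately normal.

## Two fitting routes

**With replicate recalls** (`fit_amount_only()`), the variance
components are identified from the data. For each candidate $\lambda$
on a grid, the random-intercept model is fitted by weighted maximum
likelihood: the ratio $\rho=\sigma^2_u/\sigma^2_e$ is the only free
parameter after the coefficients and residual scale are profiled out in
closed form (quasi-demeaning each person's rows by
$1-1/\sqrt{1+n_i\rho}$), so the inner problem is a one-dimensional
search. The Box-Cox Jacobian $(\lambda-1)\sum w\log R$ makes
likelihoods comparable across $\lambda$, and the grid maximiser is
returned. ML rather than REML is used; with thousands of persons the
distinction is immaterial. Survey weights multiply each person's
log-likelihood contribution (frequency-style); design-based uncertainty
is carried separately by replicate-weight reruns. An equal-weight fit
reproduces `lme4::lmer(..., REML = FALSE)` to machine precision, which
the test suite verifies.

**With one recall per person** (`fit_oneday()`), only the total
residual variance $V=\mathrm{var}(d_i)$, $d_i=u_i+e_i$, is estimable.
The split comes from an external variance ratio, supplied in any of
three conventions and converted internally:

| convention | definition | between | within |
|---|---|---|---|
| $\alpha$ | within/between | $V/(1+\alpha)$ | $V\alpha/(1+\alpha)$ |
| $\beta$  | within/total   | $V(1-\beta)$   | $V\beta$ |
| $\gamma$ | between/total  | $V\gamma$      | $V(1-\gamma)$ |

(For example $V=20$, $\alpha=2$ gives between $20/3=6.67$ and within
$40/3=13.3$.) The ratio should come from a comparable population fitted
with a comparable covariate set, because the components here are the
*unstructured* parts of variation — what covariates explain is excluded
from both numerator and denominator. Published ratios vary widely and
their convention is often unclear; `convert_ratio()` and `run_sweep()`
exist precisely because of that.

Because a joint likelihood over $(\lambda,\sigma^2_u,\sigma^2_e)$ is
unavailable with one recall, $\lambda$ is chosen by a formalised
probability-plot criterion: for each grid value, transform, refit the
survey-weighted regression, compute the survey-weighted percentiles
1–99 of the residuals, pair them with $\Phi^{-1}(p/100)$, and score the
squared Pearson correlation. The $\lambda$ with the most linear plot
wins. This extends naturally to weighted data where classical normality
tests do not. Residuals are recomputed from a $\lambda$-specific refit
(not a single fit), and the plotting positions are plain $p/100$ rather
than a continuity-corrected variant — with 99 interior percentiles the
difference is negligible and $p/100$ is the simpler contract. The two
routes may legitimately select different $\lambda$ on the same data;
the downstream distribution is insensitive to this so long as the
variance *ratio* is right, which is the central empirical point the
package's acceptance tests replay in miniature.

## From fit to distribution

Person $i$'s usual intake is the long-run average over days,

$$T_i=\sum_t \pi_t\,E_e\!\left[g^{-1}(lp_{it}+u_i+e;\lambda)\right],
 \qquad e\sim N(0,\sigma^2_e),$$

with day types $t$ (weekday/weekend) mixed by $\pi=(4/7,3/7)$ to match
a Friday–Sunday weekend definition (configurable). Both fits store each
person's linear predictor at *both* day-type levels, whichever day was
observed, so this average is always available.

Numerical choices in `estimate_distribution()`:

- The inner expectation uses Gauss–Hermite quadrature,
  default 9 nodes (nodes from `pracma::gaussHermite`). Nine nodes are
  exact for polynomial integrands of degree 17 and agree with a
  $10^6$-draw Monte-Carlo oracle within 0.5% over the $(\lambda,
  \sigma^2_e)$ ranges the tests scan; at $\lambda=0$ the closed-form
  lognormal mean $e^{\sigma^2/2}$ is reproduced to four digits.
- The population is represented by *pseudo-persons*: $M=100$
  independent draws of $u\sim N(0,\sigma^2_u)$ per sampled person, each
  carrying weight $w_i/M$. Summaries are weighted statistics of this
  pseudo-population. The draw stream is seeded and restored, so results
  are bit-reproducible given the seed.
- Where $\lambda y+1\le 0$ the inverse transform is undefined; such
  evaluations clip to zero intake and the clipped fraction is reported
  on the result (`clipped_fraction`). At realistic parameter values it
  is zero or negligible; a visibly nonzero value signals a model/scale
  mismatch.
- Weighted percentiles interpolate the weighted empirical CDF with
  plotting positions $(C_k-w_k)/(C_n-w_n)$, the weighted
  generalisation of the familiar type-7 rule; one definition is used
  everywhere (λ selection, percentile tables, prevalence) for internal
  consistency. Exact invariance under *splitting* records is not a
  property of interpolated definitions; invariance under rescaling all
  weights is, and is tested.
- Zero intakes (tolerated below the 5% nearly-daily bound) are shifted
  by half the smallest positive intake before transformation (or
  dropped, by option), with the count kept in the fit diagnostics.
- The one-day total variance uses the weighted mean squared residual
  with an effective-degrees-of-freedom correction
  $n_{\mathrm{eff}}=(\sum w)^2/\sum w^2$, unbiased in the equal-weight
  limit.
- Grid ties in either $\lambda$ criterion resolve to the smaller
  $\lambda$ (deterministic; favours the log end, where skew correction
  is stronger). Variance-ratio estimates at the optimiser's bounds are
  flagged as boundary fits: $\sigma^2_u\to 0$ warns and reports the
  ratio as infinite, and `extract_ratio()` refuses to export it.

## Inference and sensitivity

`brr_se()` implements balanced repeated replication,
$SE^2=\frac{1}{R(1-F)^2}\sum_r(\hat\theta_r-\hat\theta)^2$. The Fay
coefficient defaults to 0 (classical doubled/zeroed half-samples) but
must be set to match how the replicate weights were built — NHANES
releases, for instance, use Fay-adjusted weights. When comparing the
two routes (`compare_methods()`), both are re-run under every replicate
weight set and the *differences* are replicated, which accounts for the
correlation induced by the shared sample; the Box-Cox parameters are
frozen at their full-sample values across replicates, stabilising the
SE and matching common practice (switchable by refitting manually).
Equivalence is declared by a z-based TOST (the p-value is the larger of
the two one-sided p-values) at margins of 5% of the amount-only
estimate for means and percentiles and an absolute 0.5 percentage
points for prevalence. A z rather than t reference is used: replicate
counts are moderate (32) and the statistics are smooth functionals of
large samples.

`run_sweep()` repeats the distribution step under multiples
25%–200% of the nominal ratio, recomputing only the variance split —
the transformation and coefficients are frozen, because the external
ratio enters after them, so the sweep isolates exactly the quantity a
user must assume. The same seed is reused across multipliers so
differences are not Monte-Carlo noise. The characteristic signature,
which the acceptance tests assert: the mean is essentially invariant
(drift below 0.5%), understating the ratio flattens and spreads the
distribution while overstating tightens it (interquartile range
strictly decreasing in the multiplier), and prevalence below a cutoff
moves monotonically with direction set by whether the cutoff sits below
or above the median.

## The synthetic generator

`generate_recalls()` inverts the generating model: it draws covariates,
person effects and day errors, forms the transformed-scale linear
predictor and back-transforms, clipping negatives to zero and refusing
specs whose clipped-plus-zero fraction reaches 5%. It returns a truth
table with each person's $u_i$ and closed-form usual intake (41-node
quadrature under the generator's own parameters), so percentile and
prevalence recovery can be judged against exact targets.

Defaults are the package's study conditions: 5000 persons, true
$\lambda=0.25$, $\sigma^2_u=0.5$, $\sigma^2_e=1.0$ (within:between
ratio 2, typical of published micronutrient ratios), intercept 15 on
the transformed scale so intakes land in the hundreds of units/day,
age slope 0.02/y over ages 19–80, a 3-level group (proportions
0.4/0.3/0.3, effects 0/−0.5/0.3), weekend effect 0.3 with
$P(\text{weekend})=3/7$, and gamma(4, 4) survey weights (unit mean,
NHANES-like dispersion) — unequal weights keep the weighted code paths
honestly exercised. BRR replicate weights come from a Sylvester
Hadamard design over pairs of persons, so the replicate count must be a
power of two (32 covers the common survey setup).

What the generator does *not* emulate: stratified/clustered sampling
designs (weights are independent of intake), nonresponse, recall-
instrument bias, within-person autocorrelation from consecutive days,
and real covariate distributions. Passing tests therefore demonstrate
the estimators recover the model they assume under survey-style
weighting — not robustness to instrument bias or design features absent
from the generator.

## Problem sizes, identifiability, and limitations

The test suite runs at deliberately modest sizes: module tests use
150–800 persons; the end-to-end equivalence check uses 5000 persons ×
2 recalls with $M=100$ pseudo-draws; parameter recovery uses 20
replicates of 2000 persons × 2 recalls. One fact worth knowing when
reading results: $\lambda$ is weakly identified at realistic
transformed-scale coefficients of variation — its single-sample SD at
$n=2000\times 2$ is about 0.05, and the two routes can select visibly
different values on the same data. Recovery of $\lambda$ is therefore
a statement about the estimator (unbiasedness across replicates), not
about any single sample, whereas the variance *ratio* and all
distribution summaries are much more stable — which is, again, the
package's central point: get the ratio right and the rest follows.

Other limitations: the one-day route inherits the assumption that the
first recall is not systematically different from later ones;
individual-level inference (a person's own usual intake) is out of
scope, as are multivariate (multi-nutrient) distributions and
episodically consumed foods.
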