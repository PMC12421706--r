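---
title: "Multimethod latent state-trait models for random and fixed situations: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimethod latent state-trait models for random and fixed situations: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lstmm)
```

## The model

Latent state-trait (LST) theory decomposes a repeatedly measured score into
a stable trait component, an occasion-specific state residual, and
measurement error. The model family implemented here extends this
decomposition in two directions at once: multiple *methods* (e.g., true- and
false-keyed items, or self- versus other-reports, which are
non-interchangeable) and multiple *fixed situations* (predefined,
non-interchangeable measurement contexts such as offline versus online, in
contrast to the unrecorded "random" situations absorbed by the occasion
factors).

For indicator $i$, method $m$, occasion $t$, and fixed situation $s$, the
measurement equations are

$$
Y_{imts} =
\begin{cases}
T_{11s} + O_{11ts} + \varepsilon_{11ts} & i = 1, m = 1\\[2pt]
\alpha_{ims} + \lambda_{ims} T_{11s} + \delta_{ims} O_{11ts} + TM_{ims}
  + \gamma_{ims} OM_{mts} + \varepsilon_{imts} & \text{otherwise,}
\end{cases}
$$

with, per situation $s$: one reference trait factor $T_{11s}$, $T$ occasion
factors $O_{11ts}$, $I \cdot M - 1$ trait-method factors $TM_{ims}$ (one per
non-reference indicator-method combination), and $M \cdot T$ occasion-method
factors $OM_{mts}$ (one per method and occasion). Occasion, trait-method,
and occasion-method factors are residual factors with zero means. The model
is identified by the reference-indicator convention:

* the reference indicator ($i = 1$, $m = 1$) has $\lambda = \delta = 1$ and
  $\alpha = 0$, defining the metric and origin of the trait and occasion
  factors;
* all trait-method loadings are fixed to one;
* one $\gamma$ per occasion-method factor is fixed to one — we fix the
  loading of the lowest-indexed non-reference indicator of that method, a
  deterministic rule that mirrors the reference-indicator convention;
* $\alpha$, $\lambda$, $\delta$, $\gamma$ carry no occasion index: loadings
  and intercepts are time-invariant.

With one method the builder emits the reduced situation-specific LST model
(no method factors); with one situation, the single-situation multimethod
LST model. All latent variables are uncorrelated by default; covariance sets
can be switched on per family (trait and trait-method factors with all
factors of their own type; occasion and occasion-method factors only with
their same-occasion, same-method counterparts in *other* situations —
occasion-method factors never covary within a situation).

## Change-score structure and the two trait parametrizations

Cross-situation generalizability can be expressed in two covariance-
equivalent ways. The *correlated-trait* parametrization frees
$\mathrm{Cov}(T_{111}, T_{11s})$. The *latent-difference* parametrization
decomposes $T_{11s} = T_{111} + (T_{11s} - T_{111})$ and regresses the
difference on the reference trait,

$$ (T_{11s} - T_{111}) = \beta_{011s} + \beta_{111s} T_{111} + \omega_{11s}, $$

so that $\beta_{111s}$ is a person-by-fixed-situation interaction (negative:
buffering; positive: synergistic) and, with a mean structure, the mean of
the difference variable carries the situation effect. The implied moments
coincide under the mapping
$\mathrm{Cov}(T_{111}, T_{11s}) = (1+\beta_{111s})\mathrm{Var}(T_{111})$ and
$\mathrm{Var}(T_{11s}) = (1+\beta_{111s})^2 \mathrm{Var}(T_{111}) +
\mathrm{Var}(\omega_{11s})$; the test suite verifies that both
parametrizations reach the same log-likelihood on the same data. The same
construction applies to trait-method factors
($\beta_{1ims}$, no intercept, because trait-method factors have zero
means). Because a regression and a covariance on the same pair would be
redundant, trait covariances cannot be combined with trait interactions
(and likewise for trait-method factors); `mmOptions()` rejects the
combination.

The residuals $\omega$ are uncorrelated with everything by default; users
can add covariances through custom syntax lines.

## Equivalence and invariance

*Equivalence* constrains parameters within the indicators of one factor:
congeneric (identification constraints only), essential equivalence (equal
loadings — all one, given the reference constraint), equivalence
(additionally intercepts fixed to zero; trait family only, since the
residual families carry no intercepts), essential parallelity (equal
loadings and error variances, free intercepts), and parallelity (loadings,
intercepts, and error variances). "Equal error variances" is scoped within
each situation-occasion cell across indicators; this follows from
equivalence being defined over the indicators of a common factor, and
factors here are situation-specific. Defaults are parallelity for trait
factors and essential equivalence elsewhere — start restrictive, relax on
misfit. Trait-method loadings are already all fixed, so no equivalence
choice exists for them.

*Measurement invariance* constrains parameters across methods or
situations: configural (nothing beyond structure), metric (loadings),
scalar (plus intercepts), residual (plus error variances). Constraints are
placed only on parameters free at every level of the facet; for example,
when equating across methods, indicator 1's loadings are fixed at one for
the reference method but free for the others, so that group is skipped and
recorded in `skipped_constraints` rather than silently forced. Latent means
stay free across situations under scalar invariance — comparing them is the
point of establishing it. Time invariance (the default) is the least
restrictive member of every sequence: `invarianceSequence()` fits
configural, metric, scalar, and residual models and evaluates each
transition with the large-sample change-in-fit rule: non-invariance iff
$\Delta\mathrm{CFI} \le -0.010$ *and* ($\Delta\mathrm{RMSEA} \ge 0.015$ or
$\Delta\mathrm{SRMR} \ge 0.030$ at the metric step, $0.010$ later),
thresholds inclusive. The rule is conjunctive; because practice sometimes
reads the CFI criterion alone, a CFI-only exceedance is flagged separately
(`cfi_flag`) without flipping the decision, so either reading is
recoverable. Partial invariance is expressed by choosing the weaker level
and adding equality constraints for the invariant parameters via
`extra_lines`.

## Estimation

The model compiles to a reticular-action (RAM) representation: directed
coefficients $A$ (loadings, regressions), symmetric $S$ (variances,
covariances), means $M$, with implied moments
$\Sigma = F(I-A)^{-1}S(I-A)^{-\top}F^\top$ and $\mu = F(I-A)^{-1}M$.
Estimation minimizes the normal-theory discrepancy on the complete cases
(listwise) or the casewise log-likelihood grouped by missing-data pattern
(FIML, unbiased under missing-at-random). For FIML without a model mean
structure, manifest means enter saturated — one free intercept per
manifest — which leaves the chi-square and degrees of freedom unchanged;
the FIML-saturated model is obtained by an EM algorithm for the
unrestricted multivariate normal, and the FIML independence baseline
factorizes into per-variable univariate likelihoods.

Numerical choices:

* Gradients are analytic (chain rule through $(I-A)^{-1}$), verified
  against finite differences in the test suite; iterates with a
  non-positive-definite implied covariance fall back to a penalized
  objective with numerical gradients.
* Optimization uses a quasi-Newton minimizer on the discrepancy scale
  (relative tolerance $10^{-10}$, polish pass at $10^{-13}$), with up to
  three seed-controlled jittered restarts; a fit is reported as converged
  when the scaled gradient maximum norm is below $10^{-4}$.
* Start values: loadings 1, intercepts at sample means, latent variances at
  half the reference-manifest variance, error variances at half the own
  variance, slopes and covariances 0.
* Variances are deliberately unbounded: inadmissible (Heywood) solutions
  must surface as negative variance estimates because they are diagnostic —
  near-zero occasion-method variance, for instance, is the standard reason
  to drop those factors. Fits carry `negative_variances` and a latent
  covariance positive-semidefiniteness flag instead of silently bounding.
* Standard errors are observed-information (inverse numerical Hessian of
  the negative log-likelihood, computed with the analytic gradient); a
  singular information matrix is reported as per-parameter
  non-identification rather than numbers.
* SRMR uses covariance residuals only (no mean residuals), keeping the
  index comparable across mean-structure settings; other software that
  includes mean residuals can differ. CFI/TLI are clamped at 1, and a
  model-minus-df deviation below the convergence tolerance ($10^{-6}$) is
  treated as exact fit. AIC and BIC use $-2\ell +$ penalty with $n$ =
  subjects.

### A non-identification worth knowing about

The reference method's occasion-method factors load only on that method's
$I-1$ non-reference indicators. With $I = 3$ and congeneric occasion-method
loadings that is a two-indicator factor whose single free loading trades
off against the factor variance and the error variances: the likelihood is
flat along that direction, and two runs can return different parameter
values at the same log-likelihood. This is a property of the model family,
not of the optimizer. The default essential-equivalence assumption for
occasion-method factors (all $\gamma = 1$) removes the indeterminacy, which
is why `recoveryPopulation()` and the package's recovery checks use it; the
builder still allows congeneric occasion-method loadings for users whose
designs identify them.

## Coefficients

From an (admissible) fit, with model-implied variances throughout —
sample-based denominators would break the identities below:

* Consistency $\mathrm{Con}(Y) = \lambda^2\mathrm{Var}(T_{11s}) /
  \mathrm{Var}(Y)$; method variance is excluded, because trait-method
  variance is method-specific even though it is stable.
* Occasion specificity $\mathrm{Spe}(Y) = \delta^2\mathrm{Var}(O_{11ts}) /
  \mathrm{Var}(Y)$, again excluding (occasion-)method variance.
* Reliability $\mathrm{Rel}(Y) = [\lambda^2\mathrm{Var}(T) +
  \delta^2\mathrm{Var}(O) + \mathrm{Var}(TM) + \gamma^2\mathrm{Var}(OM)] /
  \mathrm{Var}(Y)$ — all systematic variance.
* Commonality $\mathrm{Comm} = \mathrm{Corr}(T_{111}, T_{11s})^2$ and
  situation specificity $1 - \mathrm{Comm}$, likewise for corresponding
  trait-method pairs. Under the difference parametrization the correlation
  is read off the implied latent covariance matrix (equivalently, from the
  closed-form mapping above). Pairs with no modeled association are
  reported as *unavailable*, not zero: an absent covariance is a modeling
  choice, not an estimate. Structural association is decided by evaluating
  the implied latent covariance at generic parameter values, so any path
  that can produce a nonzero covariance counts.

$\mathrm{Con} + \mathrm{Spe} + \text{method share} = \mathrm{Rel}$ and
$\mathrm{Comm} + \mathrm{SitSpe} = 1$ hold exactly; on inadmissible fits the
coefficients are still computed but flagged, since a negative variance can
push them outside $[0, 1]$.

## The simulator and what passing tests show

`simulateData()` draws all latent variables and errors as jointly normal
shocks with the model's means and (co)variances, propagates them through
the latent regressions, and composes manifests through the loadings; a
completely-at-random missingness mask can be applied afterwards.
`exampleData()` emulates the two designs a user would meet in practice:
`"simulated_like"` (500 subjects, 3 indicators x 2 methods x 3 occasions x
2 situations, continuous and complete, correlated traits with population
cross-situation correlation 0.7) and `"real_like"` (425 subjects,
3 x 2 x 2 x 2, a latent-difference population with trait mean 3.6, marginal
situation mean difference $-0.43$ scale points, buffering interaction
$\beta = -0.4$, substantial trait-method variance, responses rounded to a
1..5 rating scale with 3% sporadic missingness). The rounding rule was
chosen over equal-probability thresholds deliberately: equal-probability
cuts would force uniform item margins and erase the latent mean structure
these data are meant to carry. `real_like` emulates a design and its
qualitative structure — it is not a replica of any particular dataset.

The generator draws Gaussian latents, uses an MCAR mechanism only, and
(except for `real_like`) produces continuous responses. Passing tests
therefore show that the estimator recovers the generating process under
normality and ignorable missingness; they do not speak to ordinal items
(beyond the rounding emulation), non-normal traits, or systematic
missingness, and FIML inherits its missing-at-random assumption.

Problem sizes in the test suite are chosen to keep a serial run fast while
leaving the checks informative: the moment oracle compares implied against
simulated covariances at $10^6$ subjects (tolerance 0.01 entrywise, about
five Monte-Carlo standard errors), full-design recovery uses one fit at
$n = 20{,}000$ (every estimate within 0.05 of truth), the chi-square
calibration uses 10 replicates at $n = 2000$, the standard-error scaling
check compares $n = 500$ against $n = 2000$, and the null invariance
sequence uses one replicate at $n = 800$. `parameterRecovery()` exposes the
full replicate machinery (bias, RMSE, interval coverage, convergence rate)
for larger studies.

## Limitations

Single construct (no multitrait designs); reference-indicator approach only
(no reference-method variant); continuous-data maximum likelihood only — no
ordinal/weighted least-squares estimation, robust corrections, or bootstrap;
no multigroup models; no small-sample or many-variable fit-index
corrections; listwise and MCAR/FIML missingness handling only, without
auxiliary variables. Sample sizes in the low hundreds are fragile for the
full model — several hundred subjects are typically needed, and the
convergence-rate report of `parameterRecovery()` makes that visible for a
given design.
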