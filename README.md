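# lstmm: multimethod latent state–trait models for random and fixed situations

Latent state–trait (LST) theory splits repeated psychological measurements
into a stable **trait** component, occasion-specific **state** residuals,
and measurement **error**. Real study designs complicate this twice over:
constructs are measured with several non-interchangeable **methods** (true-
vs. false-keyed items, self- vs. other-reports), and in several predefined
**fixed situations** (offline vs. online, before vs. after an
intervention). The MM-LST-RF model family handles both at once, and this
package is a complete engine for it, aimed at personality and individual-
differences researchers running longitudinal multimethod studies.

For indicator *i*, method *m*, occasion *t*, situation *s*:

```
Y_imts = T_11s + O_11ts + e_11ts                                      (reference indicator)
Y_imts = a_ims + l_ims T_11s + d_ims O_11ts + TM_ims + g_ims OM_mts + e_imts   (otherwise)
```

with situation-specific reference traits `T_11s`, occasion factors
`O_11ts`, trait-method factors `TM_ims`, and occasion-method factors
`OM_mts`, identified by the reference-indicator convention and
time-invariant loadings/intercepts. The package:

* builds the symbolic model from the factorial design (`mmDesign()`,
  `mmOptions()`, `buildModel()`), including equivalence assumptions,
  measurement-invariance constraints across methods/situations, latent
  covariance sets, latent change-score (interaction) regressions, and
  custom syntax lines;
* estimates it by maximum likelihood — complete-case or full-information
  (FIML) for missing data — with analytic gradients,
  observed-information standard errors, fit indices (CFI, TLI, RMSEA with
  CI, SRMR, AIC/BIC), and honest Heywood-case flags (`fitModel()`);
* computes the LST variance-decomposition coefficients — consistency,
  occasion specificity, reliability, cross-situation commonality and
  situation specificity (`lstCoefficients()`);
* runs sequential invariance testing with the change-in-fit decision rule
  (`invarianceSequence()`, `chenDecision()`);
* simulates data from any parameterized model and runs parameter-recovery
  studies (`simulateData()`, `exampleData()`, `parameterRecovery()`);
* exports any model as lavaan-dialect syntax (`exportSyntax()`,
  `parseSyntax()`), and ships a command-line pipeline (`runCli()`,
  `inst/cli/lstmm.R`).

## Worked example

A two-method, two-occasion, two-situation questionnaire study (3 indicators
per method, 5-point items, sporadic missingness), analyzed with a latent
trait-difference model, FIML, and occasion covariances across situations:

```r
library(lstmm)

design <- mmDesign(indicators = 3, methods = 2, occasions = 2, situations = 2)
opts <- mmOptions(structural = "trait_interactions", include_om_factors = FALSE,
                  mean_structure = TRUE, cov_occasion = TRUE,
                  equivalence_trait = "congeneric",
                  equivalence_occasion = "congeneric",
                  missing = "fiml")
model <- buildModel(design, opts)

dat <- exampleData("real_like", seed = 1)   # 425 x 24 emulated rating data
fit <- fitModel(dat, model, seed = 1)
fit
#> MM-LST-RF model fit (fiml)
#>   n = 425, free parameters = 75
#>   loglik = -11822.316, chisq = 260.000, df = 249, p = 0.3031
#>   CFI = 0.998, TLI = 0.998, RMSEA = 0.010, SRMR = 0.032
```

The model fits (χ²/df ≈ 1.04, all benchmarks met). The structural
parameters answer the substantive questions — is the trait lower in the
second situation, and does the change depend on the person?

```r
subset(standardErrors(fit),
       parameter %in% c("T_S1~1", "dT_S2~T_S1", "dT_S2~1"))
#>     parameter estimate     se     z   pvalue
#> 70     T_S1~1    3.563 0.0395 90.31 0.00e+00
#> 71 dT_S2~T_S1   -0.401 0.0555 -7.22 5.39e-13
#> 73    dT_S2~1    1.010 0.2005  5.04 4.69e-07
```

The reference-situation trait mean is 3.56 on the 1–5 scale; the
interaction slope −0.40 (z = −7.2) is a buffering effect: people with
higher trait levels in situation 1 change less across situations. The
expected mean difference at the mean trait level is
`1.010 − 0.401 × 3.563 ≈ −0.42` scale points (the generating population
uses −0.43). Generalizability and measurement quality come from the
coefficient table:

```r
co <- lstCoefficients(fit)
co$trait
#>          pair  corr  comm sitspe available
#> 1 T_S1 x T_S2 0.651 0.424  0.576      TRUE

head(co$indicators[, c("name", "con", "spe", "method_share", "rel")], 3)
#>       name  con   spe method_share  rel
#> 1 S1T1M1I1 0.52 0.168         0.00 0.69
#> 2 S1T1M1I2 0.25 0.108         0.31 0.67
#> 3 S1T1M1I3 0.37 0.095         0.30 0.77
```

42% of trait variance is shared across the two situations; non-reference
indicators owe roughly a third of their variance to method factors, which
is why their consistency is low even though their reliability is not.

The same pipeline runs from the shell:

```sh
Rscript inst/cli/lstmm.R --data mydata.csv \
  --situations 2 --occasions 2 --methods 2 \
  --structural traits --cov-occasion --mean-structure --missing fiml \
  --no-om-factors --fit --out results/
```

which writes `model.lav` (exported syntax), `fit.json`, `coefficients.csv`,
`report.txt`, and `run.log`.

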