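test_that("the analytic likelihood gradient matches finite differences", {
  model <- buildModel(mmDesign(2, 2, 2, 2),
                      cong_opts(structural = "trait_interactions",
                                include_om_factors = FALSE,
                                mean_structure = TRUE))
  th <- trueValues(model)
  dat <- simulateData(model, th, n = 300, seed = 5, mcar_rate = 0.08)
  Y <- dat$values
  colnames(Y) <- model$manifests
  ms <- lstmm:::start_values(model, Y)
  ram <- lstmm:::compileRAM(ms)
  p <- length(model$manifests)
  x <- lstmm:::pt_start(ms$partable) * 0.9 + 0.03

  # listwise, with mean structure
  st <- lstmm:::listwise_stats(Y)
  negll_lw <- function(theta) {
    mm <- lstmm:::ram_moments_all(ram, theta)
    -lstmm:::loglik_listwise(mm$V[1:p, 1:p], mm$mu[1:p], st, TRUE)
  }
  ga <- lstmm:::ram_grad_negll(ram, x,
                               lstmm:::neg_dldmoments_listwise(st, TRUE))
  gn <- lstmm:::num_gradient(negll_lw, x)
  expect_lt(max(abs(ga - gn) / (abs(gn) + 1)), 1e-4)

  # FIML over missing-data patterns
  pats <- lstmm:::pattern_stats(Y)
  negll_fi <- function(theta) {
    mm <- lstmm:::ram_moments_all(ram, theta)
    -lstmm:::loglik_fiml(mm$V[1:p, 1:p], mm$mu[1:p], pats)
  }
  ga2 <- lstmm:::ram_grad_negll(ram, x, lstmm:::neg_dldmoments_fiml(pats, p))
  gn2 <- lstmm:::num_gradient(negll_fi, x)
  expect_lt(max(abs(ga2 - gn2) / (abs(gn2) + 1)), 1e-4)
})

test_that("a saturated model reproduces the sample moments with zero chisq", {
  set.seed(1)
  Y <- matrix(rnorm(300), 100, 3)
  m <- parseSyntax(c("y1 ~~ y1", "y2 ~~ y2", "y3 ~~ y3",
                     "y1 ~~ y2", "y1 ~~ y3", "y2 ~~ y3"))
  dat <- structure(list(values = Y, missing = is.na(Y), design = NULL,
                        n_subjects = 100), class = "mmData")
  fit <- fitModel(dat, m, se = FALSE)
  expect_equal(fit$df, 0)
  expect_lt(fit$chisq, 1e-6)
  expect_lt(max(abs(fit$Sigma_hat - fit$sample_Sigma)), 1e-6)
  expect_equal(fit$indices$cfi, 1)
  expect_equal(fit$indices$rmsea, 0)
})

test_that("parameters are recovered on a compact design", {
  model <- buildModel(mmDesign(2, 2, 2, 1), cong_opts(include_om_factors = FALSE))
  th <- recoveryPopulation(model)
  dat <- simulateData(model, th, n = 4000, seed = 41)
  fit <- fitModel(dat, model, se = FALSE)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$estimates - th)), 0.06)
})

test_that("FIML equals listwise ML on complete data", {
  pair <- equiv_pair()
  th <- equiv_theta(pair$diff)
  dat <- simulateData(pair$diff, th, n = 400, seed = 7)
  f_lw <- fitModel(dat, pair$diff, missing = "listwise", se = FALSE)
  f_fi <- fitModel(dat, pair$diff, missing = "fiml", se = FALSE)
  expect_lt(abs(f_lw$loglik - f_fi$loglik), 1e-6)
  expect_lt(abs(f_lw$chisq - f_fi$chisq), 1e-5)
  expect_equal(f_lw$df, f_fi$df)
  # FIML adds saturated manifest means; structural parameters must agree
  shared <- intersect(names(f_lw$estimates), names(f_fi$estimates))
  expect_lt(max(abs(f_lw$estimates[shared] - f_fi$estimates[shared])), 1e-3)
})

test_that("FIML handles MCAR missingness and stays near the truth", {
  model <- buildModel(mmDesign(2, 2, 2, 1), cong_opts(include_om_factors = FALSE))
  th <- recoveryPopulation(model)
  dat <- simulateData(model, th, n = 800, seed = 13, mcar_rate = 0.1)
  fit <- fitModel(dat, model, missing = "fiml", se = FALSE)
  expect_true(fit$converged)
  expect_equal(fit$n, 800)             # every subject contributes
  expect_lt(max(abs(fit$estimates[names(th)] - th)), 0.15)
  expect_gte(fit$chisq, 0)
})

test_that("listwise estimation fails informatively when no case is complete", {
  model <- buildModel(mmDesign(2, 2, 2, 1), cong_opts(include_om_factors = FALSE))
  dat <- simulateData(model, recoveryPopulation(model), n = 50, seed = 2)
  Y <- dat$values
  Y[cbind(1:50, rep_len(1:8, 50))] <- NA  # one hole in every row
  expect_error(fitModel(asWideData(Y, model$design), model),
               "empty-sample")
})

test_that("standard errors exist for free parameters and scale with 1/sqrt(n)", {
  model <- buildModel(mmDesign(2, 2, 2, 1), cong_opts(include_om_factors = FALSE))
  th <- recoveryPopulation(model)
  f1 <- fitModel(simulateData(model, th, n = 500, seed = 5), model)
  pe <- standardErrors(f1)
  expect_equal(nrow(pe), f1$n_free)    # fixed parameters have no entries
  expect_true(all(is.finite(pe$se)))
  expect_true(all(pe$se > 0))

  f2 <- fitModel(simulateData(model, th, n = 2000, seed = 5), model)
  ratio <- median(f2$se / f1$se)       # quadrupling n should halve the se
  expect_gt(ratio, 0.35)
  expect_lt(ratio, 0.65)
})

test_that("inadmissible solutions are flagged, not hidden", {
  model <- buildModel(mmDesign(2, 2, 2, 1), cong_opts(include_om_factors = FALSE))
  th <- trueValues(model)
  th[grep("^O_", names(th))] <- 0.02   # near-zero occasion variance
  dat <- simulateData(model, th, n = 120, seed = 5)
  fit <- suppressWarnings(fitModel(dat, model, se = FALSE, seed = 5))
  expect_gt(length(fit$negative_variances), 0)
  expect_false(fit$admissible)
})

test_that("fit indices match hand-computed values on a fixed covariance matrix", {
  # over-identified one-factor model fit to a hand-picked, slightly
  # non-conformant sample covariance matrix (df = 2)
  set.seed(8)
  S_target <- matrix(c(1.0, 0.5, 0.4, 0.30,
                       0.5, 1.0, 0.3, 0.35,
                       0.4, 0.3, 1.0, 0.45,
                       0.30, 0.35, 0.45, 1.0), 4, 4)
  n <- 200
  Z <- matrix(rnorm(n * 4), n, 4)
  Z <- scale(Z, center = TRUE, scale = FALSE)
  Y <- Z %*% solve(chol(crossprod(Z) / n)) %*% chol(S_target)
  colnames(Y) <- paste0("y", 1:4)
  m <- parseSyntax(c("F =~ 1*y1 + y2 + y3 + y4", "F ~~ F",
                     paste0("y", 1:4, " ~~ y", 1:4)))
  dat <- structure(list(values = Y, missing = is.na(Y), design = NULL,
                        n_subjects = n), class = "mmData")
  fit <- fitModel(dat, m, se = FALSE)
  expect_equal(fit$df, 2)
  expect_lt(max(abs(fit$sample_Sigma - S_target)), 1e-10)

  # hand computation from the discrepancy function
  Sg <- fit$Sigma_hat
  Fmin <- log(det(Sg)) + sum(diag(S_target %*% solve(Sg))) -
    log(det(S_target)) - 4
  expect_equal(fit$chisq, n * Fmin, tolerance = 1e-6)

  # independence baseline by hand
  chisq_b <- n * (log(prod(diag(S_target))) - log(det(S_target)))
  expect_equal(fit$chisq_base, chisq_b, tolerance = 1e-6)

  # incremental and residual indices by hand
  cfi_hand <- 1 - max(fit$chisq - 2, 0) /
    max(chisq_b - fit$df_base, fit$chisq - 2, 0)
  expect_equal(fit$indices$cfi, cfi_hand, tolerance = 1e-8)
  rmsea_hand <- sqrt(max(fit$chisq - 2, 0) / (2 * n))
  expect_equal(fit$indices$rmsea, rmsea_hand, tolerance = 1e-8)
  srmr_hand <- sqrt(mean(((S_target - Sg) /
                            tcrossprod(sqrt(diag(S_target))))[
                              upper.tri(S_target, diag = TRUE)]^2))
  expect_equal(fit$indices$srmr, srmr_hand, tolerance = 1e-8)
  aic_hand <- -2 * fit$loglik + 2 * 8   # 3 loadings + 1 variance + 4 errors
  expect_equal(fit$indices$aic, aic_hand, tolerance = 1e-8)
})

test_that("the true model attains near-perfect fit indices at large n", {
  model <- buildModel(mmDesign(2, 2, 2, 1), cong_opts(include_om_factors = FALSE))
  th <- recoveryPopulation(model)
  fit <- fitModel(simulateData(model, th, n = 8000, seed = 77), model, se = FALSE)
  expect_gt(fit$indices$cfi, 0.995)
  expect_lt(fit$indices$rmsea, 0.02)
  expect_lt(fit$indices$srmr, 0.03)
  expect_true(fit$indices$benchmarks$cfi_ok)
})

test_that("chi-square difference test detects a false constraint and not a true one", {
  model <- buildModel(mmDesign(2, 2, 2, 1), cong_opts(include_om_factors = FALSE))
  th <- recoveryPopulation(model)   # loadings differ from one
  dat <- simulateData(model, th, n = 2000, seed = 19)
  f_free <- fitModel(dat, model, se = FALSE)

  # identical models: zero difference
  same <- chisqDiffTest(f_free, f_free)
  expect_equal(same$dchisq, 0)
  expect_equal(same$ddf, 0)

  # essential equivalence (all loadings one) is false in this population
  m_eq <- buildModel(mmDesign(2, 2, 2, 1),
                     mmOptions(include_om_factors = FALSE,
                               equivalence_trait = "essential_equivalence",
                               equivalence_occasion = "congeneric"))
  f_eq <- fitModel(dat, m_eq, se = FALSE)
  dt <- chisqDiffTest(f_eq, f_free)
  expect_gt(dt$ddf, 0)
  expect_lt(dt$pvalue, 0.001)

  # a true constraint: equating two error variances that are equal in truth
  m_true <- addCustomLines(model, c("S1T1M1I1 ~~ evA*S1T1M1I1",
                                    "S1T2M1I1 ~~ evA*S1T2M1I1"))
  f_true <- fitModel(dat, m_true, se = FALSE)
  dt2 <- chisqDiffTest(f_true, f_free)
  expect_equal(dt2$ddf, 1)
  expect_gt(dt2$pvalue, 0.001)

  expect_error(chisqDiffTest(f_free, f_eq), "nesting error")
})
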