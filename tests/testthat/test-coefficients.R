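test_that("population coefficients obey the closed-form special cases", {
  model <- buildModel(mmDesign(2, 2, 2, 1), cong_opts(include_om_factors = FALSE))
  th <- recoveryPopulation(model)

  # zero occasion and trait-method variance: Con = Rel, Spe = 0
  th0 <- th
  th0[grep("^O_", names(th0))] <- 0
  th0[grep("^TM_", names(th0))] <- 0
  co0 <- lstCoefficients(model, th0)
  expect_equal(co0$indicators$spe, rep(0, 8))
  expect_equal(co0$indicators$method_share, rep(0, 8))
  expect_equal(co0$indicators$con, co0$indicators$rel, tolerance = 1e-12)

  # reference indicator: Rel = (Var(T) + Var(O)) / Var(Y)
  co <- lstCoefficients(model, th)
  ref <- co$indicators[co$indicators$i == 1 & co$indicators$m == 1, ]
  vt <- th[["T_S1~~T_S1"]]
  vo <- th[["O_T1S1~~O_T1S1"]]
  ve <- th[["S1T1M1I1~~S1T1M1I1"]]
  expect_equal(ref$rel[1], (vt + vo) / (vt + vo + ve), tolerance = 1e-12)
  expect_equal(ref$method_share, rep(0, 2))
})

test_that("coefficient identities hold on a fitted admissible solution", {
  model <- buildModel(mmDesign(3, 2, 2, 2), recovery_opts(cov_trait = TRUE))
  th <- recoveryPopulation(model)
  dat <- simulateData(model, th, n = 1500, seed = 23)
  fit <- fitModel(dat, model, se = FALSE)
  expect_true(fit$admissible)
  co <- lstCoefficients(fit)
  ind <- co$indicators
  expect_equal(ind$con + ind$spe + ind$method_share, ind$rel, tolerance = 1e-10)
  expect_true(all(ind$con >= 0 & ind$con <= 1))
  expect_true(all(ind$spe >= 0 & ind$spe <= 1))
  expect_true(all(ind$rel >= 0 & ind$rel <= 1))
  expect_true(all(ind$con + ind$spe <= ind$rel + 1e-12))
  expect_equal(co$trait$comm + co$trait$sitspe, rep(1, nrow(co$trait)))
})

test_that("coefficients agree with a latent-regression simulation oracle", {
  model <- buildModel(mmDesign(2, 2, 2, 1), cong_opts())
  th <- recoveryPopulation(model)
  co <- lstCoefficients(model, th)

  # oracle: simulate subjects, regress a manifest's variance onto the
  # variance contributions of its own latent components
  ram <- lstmm:::compileRAM(model)
  mats <- lstmm:::ram_matrices(ram, unname(th))
  set.seed(99)
  n <- 2e5
  L <- lstmm:::psd_sqrt(mats$S)
  U <- matrix(rnorm(n * ram$nv), n, ram$nv) %*% L
  V <- U %*% t(solve(diag(ram$nv) - mats$A))
  colnames(V) <- ram$vars

  y <- "S1T1M2I2"
  pt <- model$partable
  lam <- pt$value; ids <- lstmm:::pt_free_ids(pt)
  lam[ids > 0] <- th[ids[ids > 0]]
  get_load <- function(fam) {
    r <- which(pt$op == "=~" & pt$rhs == y & pt$family == fam)
    list(lv = pt$lhs[r], v = lam[r])
  }
  lt <- get_load("loading_trait"); lo <- get_load("loading_occasion")
  tm <- get_load("loading_tm"); om <- get_load("loading_om")
  vy <- var(V[, y])
  con_mc <- lt$v^2 * var(V[, lt$lv]) / vy
  spe_mc <- lo$v^2 * var(V[, lo$lv]) / vy
  meth_mc <- (tm$v^2 * var(V[, tm$lv]) + om$v^2 * var(V[, om$lv])) / vy
  row <- co$indicators[co$indicators$name == y, ]
  expect_equal(row$con, con_mc, tolerance = 0.02)
  expect_equal(row$spe, spe_mc, tolerance = 0.02)
  expect_equal(row$method_share, meth_mc, tolerance = 0.02)
})

test_that("trait commonality tracks the change-score parameters", {
  model <- buildModel(mmDesign(2, 2, 2, 2),
                      cong_opts(structural = "trait_interactions",
                                include_om_factors = FALSE))
  th <- recoveryPopulation(model)

  # perfect generalization: zero difference variance and slope
  th1 <- th; th1[["dT_S2~T_S1"]] <- 0; th1[["dT_S2~~dT_S2"]] <- 0
  co1 <- lstCoefficients(model, th1)
  expect_equal(co1$trait$comm, 1, tolerance = 1e-12)
  expect_equal(co1$trait$sitspe, 0, tolerance = 1e-12)

  # full decoupling: slope -1 makes the situations uncorrelated
  th2 <- th; th2[["dT_S2~T_S1"]] <- -1; th2[["dT_S2~~dT_S2"]] <- 0.3
  co2 <- lstCoefficients(model, th2)
  expect_equal(co2$trait$comm, 0, tolerance = 1e-12)

  # the derived commonality matches the closed-form mapping
  beta <- 0.3; vt <- th[["T_S1~~T_S1"]]; vw <- 0.25
  th3 <- th; th3[["dT_S2~T_S1"]] <- beta; th3[["dT_S2~~dT_S2"]] <- vw
  co3 <- lstCoefficients(model, th3)
  rho <- (1 + beta) * vt / sqrt(vt * ((1 + beta)^2 * vt + vw))
  expect_equal(co3$trait$comm, rho^2, tolerance = 1e-12)
})

test_that("commonality agrees across the two parametrizations after refitting", {
  pair <- equiv_pair()
  th <- equiv_theta(pair$diff)
  dat <- simulateData(pair$diff, th, n = 600, seed = 29)
  co_diff <- lstCoefficients(fitModel(dat, pair$diff, se = FALSE))
  co_corr <- lstCoefficients(fitModel(dat, pair$corr, se = FALSE))
  expect_equal(co_diff$trait$comm, co_corr$trait$comm, tolerance = 1e-5)
})

test_that("trait-method commonality reports modeled pairs and flags unmodeled ones", {
  d <- mmDesign(2, 2, 2, 2)
  # no association modeled: unavailable, not zero
  m_none <- buildModel(d, cong_opts(include_om_factors = FALSE))
  co_none <- lstCoefficients(m_none, recoveryPopulation(m_none))
  expect_true(all(!co_none$trait_method$available))
  expect_true(all(is.na(co_none$trait_method$comm)))

  # change-score regression induces the association
  m_tm <- buildModel(d, cong_opts(structural = "trait_method_interactions",
                                  include_om_factors = FALSE))
  th <- recoveryPopulation(m_tm)
  co_tm <- lstCoefficients(m_tm, th)
  expect_true(all(co_tm$trait_method$available))
  expect_equal(co_tm$trait_method$comm + co_tm$trait_method$sitspe,
               rep(1, nrow(co_tm$trait_method)))

  # a perfectly correlated pair: zero residual variance and slope
  th1 <- th
  th1[grep("^dTM_.*~TM_", names(th1))] <- 0
  th1[grep("^dTM_.*~~dTM_", names(th1))] <- 0
  co1 <- lstCoefficients(m_tm, th1)
  expect_equal(co1$trait_method$comm, rep(1, nrow(co1$trait_method)),
               tolerance = 1e-12)
})

test_that("coefficients are invariant to rescaling a non-reference manifest", {
  model <- buildModel(mmDesign(2, 2, 2, 1), cong_opts(include_om_factors = FALSE))
  th <- recoveryPopulation(model)
  dat <- simulateData(model, th, n = 2000, seed = 37)
  co1 <- lstCoefficients(fitModel(dat, model, se = FALSE))

  Y2 <- dat$values
  j <- which(model$manifests %in% c("S1T1M1I2", "S1T2M1I2"))
  Y2[, j] <- Y2[, j] * 2.5   # rescale indicator 2 of method 1 (both occasions)
  co2 <- lstCoefficients(fitModel(asWideData(Y2, model$design), model,
                                  se = FALSE))
  expect_equal(co2$indicators$con, co1$indicators$con, tolerance = 1e-4)
  expect_equal(co2$indicators$rel, co1$indicators$rel, tolerance = 1e-4)
})

test_that("zero trait variance raises an undefined-correlation error", {
  model <- buildModel(mmDesign(2, 2, 2, 2),
                      cong_opts(cov_trait = TRUE, include_om_factors = FALSE))
  th <- recoveryPopulation(model)
  th[["T_S1~~T_S1"]] <- 0
  th[["T_S1~~T_S2"]] <- 0
  expect_error(lstCoefficients(model, th), "undefined-correlation")
})
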