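test_that("factor counts follow the model family formulas", {
  # single-situation multimethod case: I = 3, M = 2, T = 2
  m1 <- buildModel(mmDesign(3, 2, 2, 1), cong_opts())
  kinds <- table(m1$latents$kind)
  expect_equal(unname(kinds[["tm"]]), 5)   # I*M - 1 trait-method factors
  expect_equal(unname(kinds[["om"]]), 4)   # M*T occasion-method factors
  expect_equal(unname(kinds[["trait"]]), 1)
  expect_equal(unname(kinds[["occasion"]]), 2)

  # full two-situation model: per-situation counts times S
  m2 <- buildModel(mmDesign(3, 2, 2, 2), cong_opts())
  kinds2 <- table(m2$latents$kind)
  expect_equal(unname(kinds2[["trait"]]), 2)
  expect_equal(unname(kinds2[["occasion"]]), 4)
  expect_equal(unname(kinds2[["tm"]]), 10)
  expect_equal(unname(kinds2[["om"]]), 8)
})

test_that("factor-count formulas hold across a design sweep", {
  for (I in 2:4) for (M in 1:3) for (TT in 2:3) for (S in 1:3) {
    m <- buildModel(mmDesign(I, M, TT, S), cong_opts())
    kinds <- table(factor(m$latents$kind,
                          levels = c("trait", "occasion", "tm", "om")))
    expect_equal(unname(kinds[["trait"]]), S)
    expect_equal(unname(kinds[["occasion"]]), TT * S)
    if (M > 1) {
      expect_equal(unname(kinds[["tm"]]), (I * M - 1) * S)
      expect_equal(unname(kinds[["om"]]), M * TT * S)
    } else {
      # one method: reduced LST-RF model without method factors
      expect_equal(unname(kinds[["tm"]]), 0)
      expect_equal(unname(kinds[["om"]]), 0)
    }
  }
})

test_that("identification constraints fix the reference parameters", {
  m <- buildModel(mmDesign(3, 2, 2, 2), cong_opts(mean_structure = TRUE))
  pt <- m$partable
  ref <- pt$i == 1 & pt$m == 1
  # reference indicator: trait and occasion loadings 1, intercept 0
  expect_true(all(!pt$free[pt$family == "loading_trait" & ref]))
  expect_true(all(pt$value[pt$family == "loading_trait" & ref] == 1))
  expect_true(all(!pt$free[pt$family == "loading_occasion" & ref]))
  expect_true(all(!pt$free[pt$family == "intercept" & ref]))
  expect_true(all(pt$value[pt$family == "intercept" & ref] == 0))
  # all trait-method loadings fixed to one
  expect_true(all(!pt$free[pt$family == "loading_tm"]))
  expect_true(all(pt$value[pt$family == "loading_tm"] == 1))
  # exactly one fixed loading per occasion-method factor
  om <- pt[pt$family == "loading_om", ]
  fixed_per_factor <- tapply(!om$free, om$lhs, sum)
  expect_true(all(fixed_per_factor == 1))
  # time invariance: loadings and intercepts share labels across occasions
  lam <- pt[pt$family == "loading_trait" & pt$free, ]
  expect_true(all(tapply(lam$label, paste(lam$i, lam$m, lam$s),
                         function(x) length(unique(x))) == 1))
})

test_that("free trait-loading entries and parameters are counted correctly", {
  m <- buildModel(mmDesign(3, 2, 2, 2), cong_opts())
  pt <- m$partable
  # 24 manifests minus 4 reference manifests carry a free loading entry
  expect_equal(sum(pt$family == "loading_trait" & pt$free), 20)
  # time invariance collapses them to one parameter per (i, m, s)
  expect_equal(length(unique(pt$label[pt$family == "loading_trait" & pt$free])), 10)

  m2 <- buildModel(mmDesign(2, 2, 2, 1), cong_opts())
  pt2 <- m2$partable
  expect_equal(length(unique(pt2$label[pt2$family == "loading_trait" & pt2$free])), 3)
})

test_that("equivalence levels are monotone in free-parameter count", {
  d <- mmDesign(2, 2, 2, 1)
  levels_ <- c("congeneric", "essential_equivalence", "equivalence",
               "essential_parallelity", "parallelity")
  base <- buildModel(d, cong_opts(mean_structure = TRUE,
                                  include_om_factors = FALSE))
  nf <- vapply(levels_, function(lv) {
    m <- applyEquivalence(base, "trait", lv)
    lstmm:::pt_n_free(m$partable)
  }, numeric(1))
  expect_equal(unname(nf["congeneric"]), lstmm:::pt_n_free(base$partable))
  expect_true(all(diff(nf[c("congeneric", "essential_equivalence",
                            "equivalence", "parallelity")]) < 0))
  expect_lt(nf[["essential_parallelity"]], nf[["essential_equivalence"]])
  expect_lt(nf[["parallelity"]], nf[["congeneric"]])
})

test_that("essential equivalence fixes all family loadings to one", {
  m <- buildModel(mmDesign(3, 2, 2, 2),
                  mmOptions(equivalence_trait = "essential_equivalence",
                            equivalence_occasion = "congeneric",
                            equivalence_om = "congeneric"))
  pt <- m$partable
  lam <- pt[pt$family == "loading_trait", ]
  expect_true(all(!lam$free))
  expect_true(all(lam$value == 1))
})

test_that("intercept-level equivalence on residual families is reduced with a warning", {
  base <- buildModel(mmDesign(2, 2, 2, 1), cong_opts(mean_structure = TRUE))
  expect_warning(m <- applyEquivalence(base, "occasion", "equivalence"),
                 "residual family")
  pt <- m$partable
  expect_true(all(!pt$free[pt$family == "loading_occasion"]))  # loadings fixed
  expect_true(any(pt$free[pt$family == "intercept"]))          # intercepts kept
})

test_that("invariance levels nest strictly on the full design", {
  d <- mmDesign(3, 2, 2, 2)
  nf <- vapply(c("configural", "metric", "scalar", "residual"), function(lv)
    lstmm:::pt_n_free(buildModel(d, cong_opts(mean_structure = TRUE,
                                              invariance_situations = lv))$partable),
    numeric(1))
  expect_equal(nf[["configural"]],
               lstmm:::pt_n_free(buildModel(d, cong_opts(mean_structure = TRUE))$partable))
  expect_true(all(diff(nf) < 0))
})

test_that("scalar invariance across situations labels every non-reference (i, m)", {
  m <- buildModel(mmDesign(3, 2, 2, 2),
                  cong_opts(mean_structure = TRUE,
                            invariance_situations = "scalar"))
  pt <- m$partable
  for (mm in 1:2) for (i in 1:3) {
    if (i == 1 && mm == 1) next
    lam <- pt$label[pt$family == "loading_trait" & pt$i == i & pt$m == mm]
    alf <- pt$label[pt$family == "intercept" & pt$i == i & pt$m == mm]
    expect_length(unique(lam), 1)  # same label in both situations
    expect_length(unique(alf), 1)
  }
})

test_that("method-facet invariance skips reference-asymmetric parameters", {
  m <- buildModel(mmDesign(3, 2, 2, 1), cong_opts(invariance_methods = "metric"))
  expect_gt(length(m$skipped_constraints), 0)
  expect_true(any(grepl("methods", m$skipped_constraints)))
  # indicator 1's trait loading is fixed for method 1, so no equating for i=1
  pt <- m$partable
  l12 <- pt[pt$family == "loading_trait" & pt$i == 1 & pt$m == 2, ]
  expect_true(all(l12$free))
  # i = 2, 3 loadings are equated across methods
  l2 <- pt[pt$family == "loading_trait" & pt$i == 2 & pt$free, ]
  expect_length(unique(l2$label), 1)
})

test_that("trait change-score structure has the stated shape and moments", {
  d <- mmDesign(2, 2, 2, 2)
  m <- buildModel(d, cong_opts(structural = "trait_interactions",
                               include_om_factors = FALSE))
  expect_equal(sum(m$latents$kind == "tdiff"), 1)   # one non-reference situation
  expect_equal(sum(m$partable$family == "slope_trait"), 1)

  th <- trueValues(m)
  beta <- 0.4; vt <- 0.6; vw <- 0.3
  th[["dT_S2~T_S1"]] <- beta
  th[["T_S1~~T_S1"]] <- vt
  th[["dT_S2~~dT_S2"]] <- vw
  V <- impliedMoments(m, unname(th))$Sigma_all
  expect_equal(V["T_S1", "T_S2"], (1 + beta) * vt, tolerance = 1e-12)
  expect_equal(V["T_S2", "T_S2"], (1 + beta)^2 * vt + vw, tolerance = 1e-12)

  expect_warning(addTraitStructural(buildModel(mmDesign(2, 2, 2, 1), cong_opts())),
                 "at least two situations")
})

test_that("trait-method change-score structure covers all non-reference pairs", {
  m <- buildModel(mmDesign(3, 2, 2, 2),
                  cong_opts(structural = "trait_method_interactions"))
  expect_equal(sum(m$latents$kind == "tmdiff"), 5)  # (I*M - 1) per extra situation
  expect_equal(sum(m$partable$family == "slope_tm"), 5)
  # residual factors: no intercept rows on the difference variables
  dtm <- m$latents$name[m$latents$kind == "tmdiff"]
  expect_false(any(m$partable$op == "~1" & m$partable$lhs %in% dtm))
})

test_that("covariance sets add exactly the admissible pairs", {
  d <- mmDesign(3, 2, 2, 2)
  count_cov <- function(opts) {
    pt <- buildModel(d, opts)$partable
    sum(pt$family == "cov_latent")
  }
  expect_equal(count_cov(cong_opts()), 0)
  expect_equal(count_cov(cong_opts(cov_occasion = TRUE)), 2)       # one per occasion
  expect_equal(count_cov(cong_opts(cov_trait_method = TRUE)), 45)  # C(10, 2)
  expect_equal(count_cov(cong_opts(cov_trait = TRUE)), 1)
  expect_equal(count_cov(cong_opts(cov_occasion_method = TRUE)), 4)  # same (m, t), s1-s2
  # occasion-method factors never covary within a situation
  pt <- buildModel(d, cong_opts(cov_occasion_method = TRUE))$partable
  covs <- pt[pt$family == "cov_latent", ]
  s_of <- function(x) as.integer(sub(".*S(\\d+)$", "\\1", x))
  expect_true(all(s_of(covs$lhs) != s_of(covs$rhs)))
})

test_that("incompatible option combinations are rejected", {
  expect_error(mmOptions(structural = "trait_interactions", cov_trait = TRUE),
               "option conflict")
  expect_error(mmOptions(structural = "both", cov_trait_method = TRUE),
               "option conflict")
})

test_that("degrees of freedom agree between moment counting and label groups", {
  for (opts in list(cong_opts(), cong_opts(mean_structure = TRUE),
                    recovery_opts(invariance_situations = "metric"))) {
    m <- buildModel(mmDesign(3, 2, 2, 2), opts)
    pt <- m$partable
    p <- length(m$manifests)
    moments <- p * (p + 1) / 2 + if (opts$mean_structure) p else 0
    brute <- length(unique(lstmm:::pt_free_ids(pt)[pt$free]))
    expect_equal(degreesOfFreedom(m), moments - brute)
  }
})

test_that("an equality label raises df by group size minus one", {
  m <- buildModel(mmDesign(2, 2, 2, 1), cong_opts())
  df0 <- degreesOfFreedom(m)
  m2 <- addCustomLines(m, c("S1T1M1I1 ~~ ev1*S1T1M1I1",
                            "S1T2M1I1 ~~ ev1*S1T2M1I1"))
  expect_equal(degreesOfFreedom(m2), df0 + 1)
  m3 <- addCustomLines(m, c("S1T1M1I1 ~~ ev1*S1T1M1I1",
                            "S1T2M1I1 ~~ ev1*S1T2M1I1",
                            "S1T1M1I2 ~~ ev1*S1T1M1I2"))
  expect_equal(degreesOfFreedom(m3), df0 + 2)
})

test_that("custom lines add, override, and reject as specified", {
  m <- buildModel(mmDesign(3, 2, 2, 2), cong_opts())
  # within-method trait-method covariances, within and across situations
  lines <- c("TM_I2M1S1 ~~ TM_I3M1S1", "TM_I2M1S2 ~~ TM_I3M1S2",
             "TM_I1M2S1 ~~ TM_I2M2S1", "TM_I1M2S1 ~~ TM_I3M2S1",
             "TM_I2M2S1 ~~ TM_I3M2S1", "TM_I1M2S2 ~~ TM_I2M2S2",
             "TM_I1M2S2 ~~ TM_I3M2S2", "TM_I2M2S2 ~~ TM_I3M2S2")
  m2 <- addCustomLines(m, lines)
  expect_equal(sum(m2$partable$op == "~~") - sum(m$partable$op == "~~"), 8)
  expect_equal(lstmm:::pt_n_free(m2$partable) - lstmm:::pt_n_free(m$partable), 8)

  # re-fixing an already fixed parameter to the same value is a no-op
  m3 <- addCustomLines(m, "T_S1 =~ 1*S1T1M1I1")
  expect_equal(lstmm:::pt_n_free(m3$partable), lstmm:::pt_n_free(m$partable))
  expect_length(m3$log, length(m$log))

  expect_error(addCustomLines(m, "TM_999 ~~ TM_I2M1S1"), "unknown model variable")
  expect_error(addCustomLines(m, "T_S1 =~~ x"), "malformed")
})

test_that("exported syntax round-trips and shows the identification", {
  m <- buildModel(mmDesign(3, 2, 2, 2),
                  cong_opts(structural = "trait_interactions",
                            mean_structure = TRUE))
  txt <- exportSyntax(m)
  lines <- strsplit(txt, "\n")[[1]]
  expect_equal(sum(grepl("^T_S\\d+ =~", lines)), 2)  # one per situation
  # reference indicator carries the fixed unit loading notation
  expect_true(any(grepl("T_S1 =~ 1\\*S1T1M1I1", lines)))
  parsed <- parseSyntax(txt)
  expect_equal(degreesOfFreedom(parsed), degreesOfFreedom(m))
  expect_equal(lstmm:::pt_n_free(parsed$partable),
               lstmm:::pt_n_free(m$partable))
})
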