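# Shared fixtures: designs, option presets, and small simulated datasets are
# all built in code at test time.

# congeneric everywhere (the least restrictive equivalence), with overrides
cong_opts <- function(...) {
  mmOptions(equivalence_trait = "congeneric",
            equivalence_occasion = "congeneric",
            equivalence_om = "congeneric", ...)
}

# congeneric loadings but occasion-method loadings fixed to one (the default
# occasion-method equivalence, under which all parameters are identified)
recovery_opts <- function(...) {
  mmOptions(equivalence_trait = "congeneric",
            equivalence_occasion = "congeneric",
            equivalence_om = "essential_equivalence", ...)
}

# the two covariance-equivalent trait parametrizations on a compact design
equiv_pair <- function() {
  d <- mmDesign(2, 2, 2, 2)
  list(
    design = d,
    corr = buildModel(d, cong_opts(cov_trait = TRUE, include_om_factors = FALSE)),
    diff = buildModel(d, cong_opts(structural = "trait_interactions",
                                   include_om_factors = FALSE))
  )
}

# population for the difference parametrization of equiv_pair()
equiv_theta <- function(model) {
  th <- recoveryPopulation(model)
  th[["dT_S2~T_S1"]] <- 0.3
  th[["dT_S2~~dT_S2"]] <- 0.25
  th
}

write_csv_fixture <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(lines, path)
  path
}
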