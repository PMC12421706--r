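#' Model-specification options for MM-LST-RF models
#'
#' Collects every switch that governs how a model is built from a design:
#' structural (latent change-score) regressions, latent covariance sets,
#' inclusion of occasion-method factors, the mean structure, measurement
#' invariance across methods and/or fixed situations, per-family equivalence
#' assumptions, extra model-syntax lines, and the missing-data treatment.
#'
#' Defaults mirror the model family's conventions: all latent variables
#' uncorrelated, occasion-method factors included, no mean structure,
#' time invariance only (time-invariant loadings and intercepts), trait
#' factors under parallelity and all other factor families under essential
#' equivalence, listwise deletion.
#'
#' @param structural which latent change-score regressions to add:
#'   `"measurement_only"` (none), `"trait_interactions"` (person-by-situation),
#'   `"trait_method_interactions"` (method-by-situation), or `"both"`.
#' @param cov_trait,cov_trait_method,cov_occasion,cov_occasion_method latent
#'   covariance sets. Trait and trait-method factors correlate with all
#'   factors of the same type; occasion and occasion-method factors only with
#'   their same-occasion (and same-method) counterparts in other situations.
#'   `cov_trait` cannot be combined with trait interactions (the regression
#'   replaces the covariance); likewise `cov_trait_method` with trait-method
#'   interactions.
#' @param include_om_factors keep occasion-method factors (`TRUE`) or build
#'   the simplified model without them.
#' @param mean_structure estimate intercepts and latent means.
#' @param invariance_methods,invariance_situations invariance level imposed
#'   across methods / situations: `"configural"`, `"metric"`, `"scalar"`,
#'   `"residual"`. Time invariance (scalar across occasions) always holds.
#' @param equivalence_trait,equivalence_occasion,equivalence_om equivalence
#'   assumption per factor family: `"congeneric"`, `"essential_equivalence"`,
#'   `"equivalence"`, `"essential_parallelity"`, `"parallelity"`. Trait-method
#'   loadings are all fixed to one by identification, so no equivalence option
#'   exists for them. For the residual factor families (occasion,
#'   occasion-method) the intercept-bearing levels reduce to their loading and
#'   error-variance implications.
#' @param extra_lines character vector of extra model-syntax lines (lavaan
#'   dialect subset), applied last; they override conflicting selections.
#' @param missing `"listwise"` or `"fiml"`.
#' @return an object of class `mmOptions`.
#' @export
mmOptions <- function(structural = c("measurement_only", "trait_interactions",
                                     "trait_method_interactions", "both"),
                      cov_trait = FALSE, cov_trait_method = FALSE,
                      cov_occasion = FALSE, cov_occasion_method = FALSE,
                      include_om_factors = TRUE,
                      mean_structure = FALSE,
                      invariance_methods = c("configural", "metric", "scalar", "residual"),
                      invariance_situations = c("configural", "metric", "scalar", "residual"),
                      equivalence_trait = "parallelity",
                      equivalence_occasion = "essential_equivalence",
                      equivalence_om = "essential_equivalence",
                      extra_lines = character(0),
                      missing = c("listwise", "fiml")) {
  structural <- match.arg(structural)
  invariance_methods <- match.arg(invariance_methods)
  invariance_situations <- match.arg(invariance_situations)
  missing <- match.arg(missing)
  eq_levels <- c("congeneric", "essential_equivalence", "equivalence",
                 "essential_parallelity", "parallelity")
  equivalence_trait <- match.arg(equivalence_trait, eq_levels)
  equivalence_occasion <- match.arg(equivalence_occasion, eq_levels)
  equivalence_om <- match.arg(equivalence_om, eq_levels)

  for (nm in c("cov_trait", "cov_trait_method", "cov_occasion",
               "cov_occasion_method", "include_om_factors", "mean_structure")) {
    v <- get(nm)
    if (!is.logical(v) || length(v) != 1L || is.na(v))
      stop("`", nm, "` must be TRUE or FALSE", call. = FALSE)
  }
  if (cov_trait && structural %in% c("trait_interactions", "both"))
    stop("option conflict: `cov_trait` cannot be combined with trait ",
         "interaction effects; the change-score regression replaces the ",
         "trait covariance", call. = FALSE)
  if (cov_trait_method && structural %in% c("trait_method_interactions", "both"))
    stop("option conflict: `cov_trait_method` cannot be combined with ",
         "trait-method interaction effects", call. = FALSE)

  structure(list(
    structural = structural,
    cov_trait = cov_trait, cov_trait_method = cov_trait_method,
    cov_occasion = cov_occasion, cov_occasion_method = cov_occasion_method,
    include_om_factors = include_om_factors,
    mean_structure = mean_structure,
    invariance_methods = invariance_methods,
    invariance_situations = invariance_situations,
    equivalence_trait = equivalence_trait,
    equivalence_occasion = equivalence_occasion,
    equivalence_om = equivalence_om,
    extra_lines = as.character(extra_lines),
    missing = missing
  ), class = "mmOptions")
}

#' @export
print.mmOptions <- function(x, ...) {
  cat("MM-LST-RF model options\n")
  cat("  structural:           ", x$structural, "\n")
  cat("  covariance sets:      ",
      paste(c("trait", "trait_method", "occasion", "occasion_method")[
        c(x$cov_trait, x$cov_trait_method, x$cov_occasion, x$cov_occasion_method)],
        collapse = ", "), "\n")
  cat("  occasion-method:      ", if (x$include_om_factors) "included" else "excluded", "\n")
  cat("  mean structure:       ", x$mean_structure, "\n")
  cat("  invariance:            methods=", x$invariance_methods,
      ", situations=", x$invariance_situations, "\n", sep = "")
  cat("  equivalence:           trait=", x$equivalence_trait,
      ", occasion=", x$equivalence_occasion,
      ", occasion-method=", x$equivalence_om, "\n", sep = "")
  cat("  missing:              ", x$missing, "\n")
  if (length(x$extra_lines))
    cat("  extra syntax lines:   ", length(x$extra_lines), "\n")
  invisible(x)
}
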