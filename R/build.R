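#' Build an MM-LST-RF model from a design and options
#'
#' Constructs the symbolic model graph: per fixed situation one reference
#' trait factor, one occasion factor per occasion, one trait-method factor per
#' non-reference indicator-method combination, and one occasion-method factor
#' per method and occasion (when included and when the design has at least two
#' methods). Identification follows the reference-indicator convention: the
#' reference indicator (i = 1, m = 1) has trait and occasion loadings fixed to
#' one and intercept fixed to zero; trait-method loadings are all fixed to
#' one; one occasion-method loading per factor is fixed to one. Loadings and
#' intercepts carry no occasion index (time invariance).
#'
#' With `methods = 1` the reduced LST-RF model (no method factors) is built;
#' with `situations = 1` the MM-LST model.
#'
#' The options are applied in order: equivalence assumptions, measurement
#' invariance, structural change-score regressions, covariance sets, custom
#' syntax lines (which override earlier selections).
#'
#' @param design an [mmDesign()] object.
#' @param options an [mmOptions()] object.
#' @return an object of class `mmModel`.
#' @export
buildModel <- function(design, options = mmOptions()) {
  model <- buildMeasurementModel(design, options)
  model <- applyEquivalence(model, "trait", options$equivalence_trait)
  if (design$`T` > 1)
    model <- applyEquivalence(model, "occasion", options$equivalence_occasion)
  if (design$M > 1 && options$include_om_factors)
    model <- applyEquivalence(model, "occasion_method", options$equivalence_om)
  if (options$invariance_methods != "configural")
    model <- applyInvariance(model, "methods", options$invariance_methods)
  if (options$invariance_situations != "configural")
    model <- applyInvariance(model, "situations", options$invariance_situations)
  if (options$structural %in% c("trait_interactions", "both"))
    model <- addTraitStructural(model)
  if (options$structural %in% c("trait_method_interactions", "both"))
    model <- addTmStructural(model)
  model <- addCovarianceSets(model, options)
  if (length(options$extra_lines))
    model <- addCustomLines(model, options$extra_lines)
  model
}

om_loader_indicators <- function(design, m) {
  if (m == 1L) setdiff(seq_len(design$I), 1L) else seq_len(design$I)
}

#' Construct the bare measurement model
#'
#' The measurement part only: factors, loadings with identification
#' constraints, error variances, and (optionally) the mean structure. All
#' loadings are congeneric; equivalence, invariance, structural regressions
#' and covariances are layered on by the dedicated operators or by
#' [buildModel()].
#'
#' @inheritParams buildModel
#' @return an `mmModel` object.
#' @export
buildMeasurementModel <- function(design, options = mmOptions()) {
  stopifnot_design(design)
  if (!inherits(options, "mmOptions"))
    stop("`options` must be an mmOptions object", call. = FALSE)
  lay <- manifestLayout(design)
  I <- design$I; M <- design$M; TT <- design$`T`; S <- design$S
  has_methods <- M > 1L

  rows <- list()
  lat <- list()
  add_lat <- function(name, kind, i = NA, m = NA, t = NA, s = NA) {
    lat[[length(lat) + 1L]] <<- data.frame(
      name = name, kind = kind, i = as.integer(i), m = as.integer(m),
      t = as.integer(t), s = as.integer(s), stringsAsFactors = FALSE)
  }
  add <- function(...) rows[[length(rows) + 1L]] <<- pt_row(...)
  yname <- function(i, m, t, s) lay$name[lay$i == i & lay$m == m &
                                           lay$t == t & lay$s == s]

  for (s in seq_len(S)) {
    Ts <- sprintf("T_S%d", s)
    add_lat(Ts, "trait", s = s)
    for (t in seq_len(TT)) for (m in seq_len(M)) for (i in seq_len(I)) {
      y <- yname(i, m, t, s)
      ref <- i == 1L && m == 1L
      add(Ts, "=~", y, free = !ref, value = 1,
          label = if (ref) "" else sprintf("l_I%dM%dS%d", i, m, s),
          family = "loading_trait", i = i, m = m, t = t, s = s)
    }
    for (t in seq_len(TT)) {
      Ot <- sprintf("O_T%dS%d", t, s)
      add_lat(Ot, "occasion", t = t, s = s)
      for (m in seq_len(M)) for (i in seq_len(I)) {
        y <- yname(i, m, t, s)
        ref <- i == 1L && m == 1L
        add(Ot, "=~", y, free = !ref, value = 1,
            label = if (ref) "" else sprintf("d_I%dM%dS%d", i, m, s),
            family = "loading_occasion", i = i, m = m, t = t, s = s)
      }
      add(Ot, "~~", Ot, free = TRUE, value = 0.2, family = "var_occasion",
          t = t, s = s)
    }
    if (has_methods) {
      for (m in seq_len(M)) for (i in seq_len(I)) {
        if (i == 1L && m == 1L) next
        TMf <- sprintf("TM_I%dM%dS%d", i, m, s)
        add_lat(TMf, "tm", i = i, m = m, s = s)
        for (t in seq_len(TT))
          add(TMf, "=~", yname(i, m, t, s), free = FALSE, value = 1,
              family = "loading_tm", i = i, m = m, t = t, s = s)
        add(TMf, "~~", TMf, free = TRUE, value = 0.2, family = "var_tm",
            i = i, m = m, s = s)
      }
      if (options$include_om_factors) {
        for (m in seq_len(M)) {
          loaders <- om_loader_indicators(design, m)
          if (!length(loaders)) next
          for (t in seq_len(TT)) {
            OMf <- sprintf("OM_M%dT%dS%d", m, t, s)
            add_lat(OMf, "om", m = m, t = t, s = s)
            for (i in loaders) {
              fixed <- i == loaders[1]   # lowest non-reference indicator
              add(OMf, "=~", yname(i, m, t, s), free = !fixed, value = 1,
                  label = if (fixed) "" else sprintf("g_I%dM%dS%d", i, m, s),
                  family = "loading_om", i = i, m = m, t = t, s = s)
            }
            add(OMf, "~~", OMf, free = TRUE, value = 0.1, family = "var_om",
                m = m, t = t, s = s)
          }
        }
      }
    }
    add(Ts, "~~", Ts, free = TRUE, value = 0.5, family = "var_trait", s = s)
  }
  for (r in seq_len(nrow(lay)))
    add(lay$name[r], "~~", lay$name[r], free = TRUE, value = 0.5,
        family = "var_error", i = lay$i[r], m = lay$m[r], t = lay$t[r],
        s = lay$s[r])

  if (options$mean_structure) {
    for (s in seq_len(S)) for (m in seq_len(M)) for (i in seq_len(I)) {
      ref <- i == 1L && m == 1L
      for (t in seq_len(TT))
        add(yname(i, m, t, s), "~1", "", free = !ref, value = 0,
            label = if (ref) "" else sprintf("a_I%dM%dS%d", i, m, s),
            family = "intercept", i = i, m = m, t = t, s = s)
    }
    for (s in seq_len(S))
      add(sprintf("T_S%d", s), "~1", "", free = TRUE, value = 0,
          family = "latent_mean", s = s)
  }

  structure(list(
    design = design,
    options = options,
    partable = do.call(rbind, rows),
    latents = do.call(rbind, lat),
    manifests = lay$name,
    skipped_constraints = character(0),
    log = character(0)
  ), class = "mmModel")
}

#' @export
print.mmModel <- function(x, ...) {
  kinds <- table(factor(x$latents$kind,
                        levels = c("trait", "occasion", "tm", "om",
                                   "tdiff", "tmdiff")))
  cat("MM-LST-RF model graph\n")
  cat(sprintf("  manifest variables: %d\n", length(x$manifests)))
  cat(sprintf("  latent variables:   %d (trait %d, occasion %d, trait-method %d, occasion-method %d, difference %d)\n",
              nrow(x$latents), kinds[["trait"]], kinds[["occasion"]],
              kinds[["tm"]], kinds[["om"]], kinds[["tdiff"]] + kinds[["tmdiff"]]))
  cat(sprintf("  free parameters:    %d\n", pt_n_free(x$partable)))
  cat(sprintf("  degrees of freedom: %d\n", degreesOfFreedom(x)))
  if (length(x$skipped_constraints))
    cat("  skipped constraints:", length(x$skipped_constraints), "\n")
  invisible(x)
}

is_mmModel <- function(x) inherits(x, "mmModel")
stopifnot_model <- function(x) {
  if (!is_mmModel(x)) stop("`model` must be an mmModel object", call. = FALSE)
  invisible(x)
}

#' Apply an equivalence assumption to a factor family
#'
#' Equivalence constrains parameters within the set of indicators of a common
#' factor: essential equivalence equates loadings (with the reference loading
#' fixed to one, all become one); equivalence additionally fixes intercepts to
#' zero (trait family only -- the residual factor families carry no
#' intercepts); (essential) parallelity additionally equates error variances,
#' scoped within each situation-occasion cell across indicators.
#'
#' Trait-method loadings are already all fixed to one by identification, so no
#' equivalence choice exists for that family.
#'
#' @param model an `mmModel` object.
#' @param family `"trait"`, `"occasion"`, or `"occasion_method"`.
#' @param level equivalence level; see [mmOptions()].
#' @return the modified `mmModel`.
#' @export
applyEquivalence <- function(model, family = c("trait", "occasion", "occasion_method"),
                             level = c("congeneric", "essential_equivalence",
                                       "equivalence", "essential_parallelity",
                                       "parallelity")) {
  stopifnot_model(model)
  family <- match.arg(family)
  level <- match.arg(level)
  if (level == "congeneric") return(model)
  pt <- model$partable

  load_fam <- switch(family, trait = "loading_trait",
                     occasion = "loading_occasion",
                     occasion_method = "loading_om")
  equal_loadings <- TRUE  # every level beyond congeneric equates loadings
  fix_intercepts <- level %in% c("equivalence", "parallelity")
  equal_errors <- level %in% c("essential_parallelity", "parallelity")

  if (equal_loadings) {
    sel <- pt$family == load_fam & pt$free
    pt$free[sel] <- FALSE
    pt$value[sel] <- 1
    pt$label[sel] <- ""
  }
  if (fix_intercepts) {
    if (family != "trait") {
      warning("intercept-level equivalence requested for the residual family '",
              family, "'; reduced to its loading/error-variance implications",
              call. = FALSE)
    } else {
      sel <- pt$family == "intercept" & pt$free
      pt$free[sel] <- FALSE
      pt$value[sel] <- 0
      pt$label[sel] <- ""
    }
  }
  if (equal_errors) {
    for (s in seq_len(model$design$S)) for (t in seq_len(model$design$`T`)) {
      idx <- which(pt$family == "var_error" & pt$free & pt$s == s & pt$t == t)
      pt <- pt_equate(pt, idx, sprintf("ev_T%dS%d", t, s))
    }
  }
  model$partable <- pt
  model$log <- c(model$log, sprintf("equivalence '%s' applied to %s family",
                                    level, family))
  model
}

#' Impose measurement invariance across methods or situations
#'
#' Adds equality labels across the chosen facet: `metric` equates loadings
#' (trait, occasion, occasion-method), `scalar` additionally intercepts,
#' `residual` additionally error variances. Constraints are only placed on
#' parameters that are free at every level of the facet; parameters fixed by
#' identification in some facet level (e.g. the reference indicator's
#' loadings when comparing methods) are skipped and recorded in
#' `model$skipped_constraints`. Latent means stay free across situations so
#' that mean comparisons remain possible under scalar invariance.
#'
#' @param model an `mmModel` object.
#' @param facet `"methods"` or `"situations"`.
#' @param level `"configural"`, `"metric"`, `"scalar"`, or `"residual"`.
#' @return the modified `mmModel`.
#' @export
applyInvariance <- function(model, facet = c("methods", "situations"),
                            level = c("configural", "metric", "scalar", "residual")) {
  stopifnot_model(model)
  facet <- match.arg(facet)
  level <- match.arg(level)
  if (level == "configural") return(model)
  pt <- model$partable
  nlev <- if (facet == "methods") model$design$M else model$design$S
  facet_col <- if (facet == "methods") "m" else "s"

  # group rows of `fam` by `keycols`; equate groups free at every facet level
  equate_family <- function(pt, fam, keycols, label_stub) {
    cand <- which(pt$family == fam)
    if (!length(cand)) return(pt)
    key <- do.call(paste, c(lapply(keycols, function(cl) pt[[cl]][cand]),
                            sep = "."))
    for (k in unique(key)) {
      idx <- cand[key == k]
      lev_free <- tapply(pt$free[idx], pt[[facet_col]][idx], any)
      if (length(lev_free) < nlev || !all(lev_free)) {
        if (any(pt$free[idx]))
          model$skipped_constraints <<- c(
            model$skipped_constraints,
            sprintf("%s %s across %s (fixed in some level)", fam, k, facet))
        next
      }
      lab <- paste0(label_stub, "_",
                    paste(paste0(toupper(substr(keycols, 1, 1)),
                                 vapply(keycols, function(cl)
                                   pt[[cl]][idx[1]], integer(1))),
                          collapse = ""))
      pt <- pt_equate(pt, idx[pt$free[idx]], lab)
    }
    pt
  }

  other <- function(cols) setdiff(cols, facet_col)
  if (level %in% c("metric", "scalar", "residual")) {
    pt <- equate_family(pt, "loading_trait", other(c("i", "m", "s")), "l")
    pt <- equate_family(pt, "loading_occasion", other(c("i", "m", "s")), "d")
    pt <- equate_family(pt, "loading_om", other(c("i", "m", "s")), "g")
  }
  if (level %in% c("scalar", "residual"))
    pt <- equate_family(pt, "intercept", other(c("i", "m", "s")), "a")
  if (level == "residual")
    pt <- equate_family(pt, "var_error", other(c("i", "m", "t", "s")), "ev")

  model$partable <- pt
  model$log <- c(model$log, sprintf("invariance '%s' applied across %s",
                                    level, facet))
  model
}

#' Add latent trait change-score structure
#'
#' For each non-reference situation s, the situation trait is decomposed as
#' T_s = T_1 + (T_s - T_1) and the latent difference variable is regressed on
#' the reference trait: (T_s - T_1) = b0 + b1 T_1 + w. The slope b1 captures
#' the person-by-fixed-situation interaction; the intercept b0 (present only
#' with a mean structure) is the expected situation effect at T_1 = 0.
#'
#' @param model an `mmModel` object; requires at least two situations.
#' @return the modified `mmModel`.
#' @export
addTraitStructural <- function(model) {
  stopifnot_model(model)
  S <- model$design$S
  if (S < 2L) {
    warning("trait change-score structure needs at least two situations; no-op",
            call. = FALSE)
    return(model)
  }
  pt <- model$partable
  if (any(pt$op == "~~" & pt$family == "cov_latent" &
            grepl("^T_S", pt$lhs) & grepl("^T_S", pt$rhs)))
    stop("option conflict: trait covariances present; the change-score ",
         "regression replaces them", call. = FALSE)
  for (s in 2:S) {
    Ts <- sprintf("T_S%d", s); D <- sprintf("dT_S%d", s)
    vidx <- pt_match(pt, Ts, "~~", Ts)
    pt$free[vidx] <- FALSE; pt$value[vidx] <- 0; pt$label[vidx] <- ""
    pt$family[vidx] <- "var_fixed"
    midx <- which(pt$lhs == Ts & pt$op == "~1")
    if (length(midx)) pt <- pt[-midx, , drop = FALSE]
    pt <- pt_bind(
      pt,
      pt_row(Ts, "~", "T_S1", free = FALSE, value = 1, family = "structural_fixed", s = s),
      pt_row(Ts, "~", D, free = FALSE, value = 1, family = "structural_fixed", s = s),
      pt_row(D, "~", "T_S1", free = TRUE, value = 0, family = "slope_trait", s = s),
      pt_row(D, "~~", D, free = TRUE, value = 0.2, family = "var_resid_diff", s = s))
    if (model$options$mean_structure)
      pt <- pt_bind(pt, pt_row(D, "~1", "", free = TRUE, value = 0,
                               family = "diff_intercept", s = s))
    model$latents <- rbind(model$latents,
                           data.frame(name = D, kind = "tdiff", i = NA_integer_,
                                      m = NA_integer_, t = NA_integer_,
                                      s = as.integer(s)))
  }
  model$partable <- pt
  model$log <- c(model$log, "trait change-score structure added")
  model
}

#' Add trait-method change-score structure
#'
#' For each non-reference (indicator, method) pair and each non-reference
#' situation, the trait-method factor is decomposed against its reference-
#' situation counterpart and the difference is regressed on it:
#' (TM_ims - TM_im1) = b1 TM_im1 + w. Trait-method factors are residual
#' factors with zero means, so no intercept is included.
#'
#' @param model an `mmModel` object; requires at least two situations and
#'   trait-method factors (at least two methods).
#' @return the modified `mmModel`.
#' @export
addTmStructural <- function(model) {
  stopifnot_model(model)
  S <- model$design$S
  if (S < 2L) {
    warning("trait-method change-score structure needs at least two situations; no-op",
            call. = FALSE)
    return(model)
  }
  tm <- model$latents[model$latents$kind == "tm", , drop = FALSE]
  if (!nrow(tm)) {
    warning("no trait-method factors in the model; no-op", call. = FALSE)
    return(model)
  }
  pt <- model$partable
  pairs <- unique(tm[, c("i", "m")])
  for (r in seq_len(nrow(pairs))) {
    i <- pairs$i[r]; m <- pairs$m[r]
    ref <- sprintf("TM_I%dM%dS1", i, m)
    for (s in 2:S) {
      TMs <- sprintf("TM_I%dM%dS%d", i, m, s)
      D <- sprintf("dTM_I%dM%dS%d", i, m, s)
      vidx <- pt_match(pt, TMs, "~~", TMs)
      pt$free[vidx] <- FALSE; pt$value[vidx] <- 0; pt$label[vidx] <- ""
      pt$family[vidx] <- "var_fixed"
      pt <- pt_bind(
        pt,
        pt_row(TMs, "~", ref, free = FALSE, value = 1, family = "structural_fixed",
               i = i, m = m, s = s),
        pt_row(TMs, "~", D, free = FALSE, value = 1, family = "structural_fixed",
               i = i, m = m, s = s),
        pt_row(D, "~", ref, free = TRUE, value = 0, family = "slope_tm",
               i = i, m = m, s = s),
        pt_row(D, "~~", D, free = TRUE, value = 0.2, family = "var_resid_diff",
               i = i, m = m, s = s))
      model$latents <- rbind(model$latents,
                             data.frame(name = D, kind = "tmdiff",
                                        i = as.integer(i), m = as.integer(m),
                                        t = NA_integer_, s = as.integer(s)))
    }
  }
  model$partable <- pt
  model$log <- c(model$log, "trait-method change-score structure added")
  model
}

#' Add latent covariance sets
#'
#' Trait factors and trait-method factors correlate with all other factors of
#' their own type; occasion factors correlate with their same-occasion
#' counterparts in other situations, and occasion-method factors with their
#' same-method same-occasion counterparts in other situations.
#' Occasion-method factors never covary within a situation.
#'
#' @param model an `mmModel` object.
#' @param options an [mmOptions()] object; only the `cov_*` switches are used.
#' @return the modified `mmModel`.
#' @export
addCovarianceSets <- function(model, options = model$options) {
  stopifnot_model(model)
  pt <- model$partable
  lat <- model$latents
  add_cov <- function(pt, a, b) {
    if (length(pt_match(pt, a, "~~", b))) return(pt)
    pt_bind(pt, pt_row(a, "~~", b, free = TRUE, value = 0,
                       family = "cov_latent"))
  }
  pick <- function(kind) lat[lat$kind == kind, , drop = FALSE]

  if (isTRUE(options$cov_trait)) {
    tr <- pick("trait")
    if (nrow(tr) < 2) warning("trait covariances requested but fewer than two trait factors; skipped", call. = FALSE)
    else for (a in 1:(nrow(tr) - 1)) for (b in (a + 1):nrow(tr))
      pt <- add_cov(pt, tr$name[a], tr$name[b])
  }
  if (isTRUE(options$cov_trait_method)) {
    tm <- pick("tm")
    if (nrow(tm) < 2) warning("trait-method covariances requested but factors absent; skipped", call. = FALSE)
    else for (a in 1:(nrow(tm) - 1)) for (b in (a + 1):nrow(tm))
      pt <- add_cov(pt, tm$name[a], tm$name[b])
  }
  if (isTRUE(options$cov_occasion)) {
    oc <- pick("occasion")
    if (model$design$S < 2) warning("occasion covariances requested but only one situation; skipped", call. = FALSE)
    else for (a in seq_len(nrow(oc))) for (b in seq_len(nrow(oc)))
      if (a < b && oc$t[a] == oc$t[b] && oc$s[a] != oc$s[b])
        pt <- add_cov(pt, oc$name[a], oc$name[b])
  }
  if (isTRUE(options$cov_occasion_method)) {
    om <- pick("om")
    if (!nrow(om) || model$design$S < 2)
      warning("occasion-method covariances requested but counterparts absent; skipped", call. = FALSE)
    else for (a in seq_len(nrow(om))) for (b in seq_len(nrow(om)))
      if (a < b && om$t[a] == om$t[b] && om$m[a] == om$m[b] &&
            om$s[a] != om$s[b])
        pt <- add_cov(pt, om$name[a], om$name[b])
  }
  model$partable <- pt
  model
}

#' Count model degrees of freedom
#'
#' Modeled sample moments -- p(p+1)/2 covariances plus p means when the mean
#' structure is on -- minus the number of distinct free parameters.
#'
#' @param model an `mmModel` object.
#' @param mean_structure override; defaults to the model's option.
#' @return integer degrees of freedom.
#' @export
degreesOfFreedom <- function(model, mean_structure = model$options$mean_structure) {
  stopifnot_model(model)
  p <- length(model$manifests)
  moments <- p * (p + 1) / 2 + if (mean_structure) p else 0
  df <- moments - pt_n_free(model$partable)
  if (df < 0)
    stop(sprintf("model under-identified: %d free parameters exceed %d sample moments",
                 pt_n_free(model$partable), moments), call. = FALSE)
  as.integer(df)
}

#' Model-implied free parameter names
#'
#' @param model an `mmModel` object.
#' @return character vector, one name per free parameter.
#' @export
parameterNames <- function(model) {
  stopifnot_model(model)
  pt_param_names(model$partable)
}
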