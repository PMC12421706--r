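#' Variance-decomposition and generalizability coefficients
#'
#' Computes the classic latent state-trait coefficients per manifest variable
#' and the cross-situation generalizability coefficients per factor pair from
#' a fitted model:
#'
#' * Consistency `Con(Y) = lambda^2 Var(T_s) / Var(Y)` -- proportion of an
#'   indicator's variance explained by the (situation-specific) trait factor.
#'   Method variance is excluded.
#' * Occasion specificity `Spe(Y) = delta^2 Var(O_ts) / Var(Y)` -- proportion
#'   due to occasion factors that fluctuate across occasions; occasion-method
#'   variance is excluded.
#' * Reliability `Rel(Y) = [lambda^2 Var(T) + delta^2 Var(O) + Var(TM) +
#'   gamma^2 Var(OM)] / Var(Y)` -- total systematic variance share, including
#'   the method factors.
#' * Trait commonality `Comm(T_s) = Corr(T_1, T_s)^2` and situation
#'   specificity `SitSpe(T_s) = 1 - Comm(T_s)` for every non-reference
#'   situation, and likewise `Comm(TM_ims)` / `SitSpe(TM_ims)` for
#'   corresponding trait-method pairs. Pairs without any modeled association
#'   (no covariance, no change-score regression) are reported as unavailable
#'   rather than zero.
#'
#' All variances are model-implied, so the identities `Con + Spe +
#' method share = Rel` and `Comm + SitSpe = 1` hold exactly for admissible
#' solutions. Coefficients computed from an inadmissible solution (negative
#' variance estimates) are flagged.
#'
#' @param fit an `mmFit` object whose model carries a design, or an
#'   `mmModel` together with `theta` to evaluate the population coefficients
#'   implied by a parameter vector.
#' @param theta population parameter vector, only when `fit` is a model.
#' @return a list of class `mmCoefficients` with elements `indicators`
#'   (per-manifest table), `trait` (per non-reference situation), and
#'   `trait_method` (per trait-method pair and situation).
#' @export
lstCoefficients <- function(fit, theta = NULL) {
  if (is_mmModel(fit)) {
    model <- fit
    if (is.null(theta)) theta <- trueValues(model)
    mm <- impliedMoments(model, unname(theta))
    est <- stats::setNames(unname(theta), pt_param_names(model$partable))
    pt <- model$partable
    ids <- pt_free_ids(pt)
    vr <- pt$op == "~~" & pt$lhs == pt$rhs & pt$free
    neg <- unique(pt$lhs[vr][est[ids[vr]] < 0])
    fit <- list(model = model, estimates = est, Sigma_all = mm$Sigma_all,
                negative_variances = neg, latent_psd = TRUE)
    class(fit) <- "mmFit"
  }
  stopifnot(inherits(fit, "mmFit"))
  model <- fit$model
  if (is.null(model$design))
    stop("coefficients need a design-based model", call. = FALSE)
  design <- model$design
  pt <- model$partable
  ids <- pt_free_ids(pt)
  val <- ifelse(ids > 0, fit$estimates[pmax(ids, 1L)], pt$value)
  V <- fit$Sigma_all
  lay <- manifestLayout(design)
  inadmissible <- length(fit$negative_variances) > 0 || !fit$latent_psd

  coef_of <- function(y, fam) {
    r <- which(pt$op == "=~" & pt$rhs == y & pt$family == fam)
    if (!length(r)) return(NULL)
    list(lv = pt$lhs[r[1]], value = val[r[1]])
  }

  ind <- lay
  ind$con <- ind$spe <- ind$method_share <- ind$rel <- ind$error_share <- NA_real_
  for (r in seq_len(nrow(lay))) {
    y <- lay$name[r]
    vy <- V[y, y]
    lt <- coef_of(y, "loading_trait")
    lo <- coef_of(y, "loading_occasion")
    tm <- coef_of(y, "loading_tm")
    om <- coef_of(y, "loading_om")
    con <- lt$value^2 * V[lt$lv, lt$lv] / vy
    spe <- lo$value^2 * V[lo$lv, lo$lv] / vy
    meth <- 0
    if (!is.null(tm)) meth <- meth + tm$value^2 * V[tm$lv, tm$lv] / vy
    if (!is.null(om)) meth <- meth + om$value^2 * V[om$lv, om$lv] / vy
    ind$con[r] <- con
    ind$spe[r] <- spe
    ind$method_share[r] <- meth
    ind$rel[r] <- con + spe + meth
    ind$error_share[r] <- 1 - (con + spe + meth)
  }
  ind <- ind[, c("name", "i", "m", "t", "s", "con", "spe", "method_share",
                 "rel", "error_share")]

  pair_table <- function(ref, other, label) {
    v1 <- V[ref, ref]; v2 <- V[other, other]
    if (v1 <= 0 || v2 <= 0)
      stop("undefined-correlation error: zero or negative variance for ",
           label, call. = FALSE)
    if (!structurallyAssociated(model, ref, other))
      return(data.frame(pair = label, corr = NA_real_, comm = NA_real_,
                        sitspe = NA_real_, available = FALSE))
    rho <- V[ref, other] / sqrt(v1 * v2)
    data.frame(pair = label, corr = rho, comm = rho^2, sitspe = 1 - rho^2,
               available = TRUE)
  }

  trait <- NULL
  if (design$S >= 2) {
    trait <- do.call(rbind, lapply(2:design$S, function(s)
      pair_table("T_S1", sprintf("T_S%d", s),
                 sprintf("T_S1 x T_S%d", s))))
  }
  tm_tab <- NULL
  tm_lat <- model$latents[model$latents$kind == "tm", , drop = FALSE]
  if (design$S >= 2 && nrow(tm_lat)) {
    pairs <- unique(tm_lat[tm_lat$s == 1, c("i", "m")])
    rows <- list()
    for (r in seq_len(nrow(pairs))) for (s in 2:design$S) {
      i <- pairs$i[r]; m <- pairs$m[r]
      a <- sprintf("TM_I%dM%dS1", i, m)
      b <- sprintf("TM_I%dM%dS%d", i, m, s)
      if (!b %in% model$latents$name) next
      rows[[length(rows) + 1L]] <- pair_table(a, b, sprintf("%s x %s", a, b))
    }
    if (length(rows)) tm_tab <- do.call(rbind, rows)
  }

  structure(list(indicators = ind, trait = trait, trait_method = tm_tab,
                 inadmissible = inadmissible),
            class = "mmCoefficients")
}

#' @export
print.mmCoefficients <- function(x, digits = 3, ...) {
  cat("Indicator coefficients (consistency / occasion specificity / reliability):\n")
  tab <- x$indicators
  tab[, 6:10] <- round(tab[, 6:10], digits)
  print(utils::head(tab, 12), row.names = FALSE)
  if (nrow(tab) > 12) cat("  ...", nrow(tab) - 12, "more rows\n")
  if (!is.null(x$trait)) {
    cat("\nTrait commonality / situation specificity:\n")
    print(x$trait, row.names = FALSE, digits = digits)
  }
  if (!is.null(x$trait_method)) {
    cat("\nTrait-method commonality / situation specificity:\n")
    print(x$trait_method, row.names = FALSE, digits = digits)
  }
  if (x$inadmissible)
    cat("\nWARNING: solution inadmissible; coefficients may fall outside [0, 1]\n")
  invisible(x)
}

#' Write a coefficient table to CSV
#'
#' @param coeffs an `mmCoefficients` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeCoefficients <- function(coeffs, path) {
  stopifnot(inherits(coeffs, "mmCoefficients"))
  blocks <- list()
  ind <- coeffs$indicators
  ind$block <- "indicator"
  blocks$ind <- data.frame(block = ind$block, name = ind$name,
                           con = ind$con, spe = ind$spe,
                           method_share = ind$method_share, rel = ind$rel,
                           corr = NA_real_, comm = NA_real_, sitspe = NA_real_)
  add_pairs <- function(tab, blockname) {
    if (is.null(tab)) return(NULL)
    data.frame(block = blockname, name = tab$pair, con = NA_real_,
               spe = NA_real_, method_share = NA_real_, rel = NA_real_,
               corr = tab$corr, comm = tab$comm, sitspe = tab$sitspe)
  }
  blocks$trait <- add_pairs(coeffs$trait, "trait_commonality")
  blocks$tm <- add_pairs(coeffs$trait_method, "trait_method_commonality")
  utils::write.csv(do.call(rbind, blocks), path, row.names = FALSE, na = "")
  invisible(path)
}
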