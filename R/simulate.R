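#' Template of population parameter values for a model
#'
#' Returns the model's free-parameter vector (named as in
#' [parameterNames()]) filled with the builder's default start values, to be
#' edited into a population for [simulateData()].
#'
#' @param model an `mmModel` object.
#' @return named numeric vector.
#' @export
trueValues <- function(model) {
  stopifnot_model(model)
  stats::setNames(pt_start(model$partable), pt_param_names(model$partable))
}

psd_sqrt <- function(S, tol = 1e-8) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  if (min(e$values) < -tol * max(abs(e$values), 1))
    stop("config error: latent/residual covariance structure is not ",
         "positive semidefinite (smallest eigenvalue ",
         format(min(e$values), digits = 3), ")", call. = FALSE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Simulate wide-format data from a parameterized model
#'
#' Generates subjects from the model's generative form: all latent variables
#' and errors are drawn as jointly normal shocks with the model's means and
#' (co)variances, propagated through the latent regressions, and composed
#' into manifest variables through the measurement loadings. An MCAR mask is
#' applied afterwards if requested.
#'
#' @param model an `mmModel` object.
#' @param theta population parameter vector (free-parameter order or named);
#'   defaults to [trueValues()].
#' @param n number of subjects.
#' @param seed optional integer seed (set for reproducibility).
#' @param mcar_rate probability that any one cell is missing completely at
#'   random (0 = complete data).
#' @return an `mmData` object.
#' @export
simulateData <- function(model, theta = NULL, n, seed = NULL, mcar_rate = 0) {
  stopifnot_model(model)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(theta)) theta <- trueValues(model)
  nfree <- pt_n_free(model$partable)
  if (!is.null(names(theta)) && length(theta) != nfree) {
    full <- trueValues(model)
    bad <- setdiff(names(theta), names(full))
    if (length(bad))
      stop("unknown parameter name(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    full[names(theta)] <- theta
    theta <- full
  }
  if (length(theta) != nfree)
    stop(sprintf("`theta` must have length %d", nfree), call. = FALSE)
  if (mcar_rate < 0 || mcar_rate >= 1)
    stop("`mcar_rate` must be in [0, 1)", call. = FALSE)

  ram <- compileRAM(model)
  m <- ram_matrices(ram, unname(theta))
  L <- psd_sqrt(m$S)
  Z <- matrix(stats::rnorm(n * ram$nv), n, ram$nv)
  U <- Z %*% L + matrix(m$M, n, ram$nv, byrow = TRUE)
  total_t <- t(solve(diag(ram$nv) - m$A))
  Yall <- U %*% total_t
  Y <- Yall[, seq_len(ram$p), drop = FALSE]
  colnames(Y) <- model$manifests
  if (mcar_rate > 0) {
    mask <- matrix(stats::runif(length(Y)) < mcar_rate, nrow(Y), ncol(Y))
    # keep at least one observation per subject and per column
    for (r in which(rowSums(!mask) == 0)) mask[r, sample(ncol(Y), 1)] <- FALSE
    for (cc in which(colSums(!mask) == 0)) mask[sample(nrow(Y), 1), cc] <- FALSE
    Y[mask] <- NA_real_
  }
  if (!is.null(model$design)) asWideData(Y, model$design)
  else structure(list(values = Y, missing = is.na(Y), design = NULL,
                      n_subjects = nrow(Y)), class = "mmData")
}

#' Reference population for recovery studies
#'
#' A fixed, documented population for Monte-Carlo recovery work on a given
#' design: every variance source is clearly present (trait 0.5, occasion 0.3,
#' trait-method 0.3, occasion-method 0.15, error 0.3) and free loadings are
#' spread over 0.8..1.2, so that all parameters are well identified under the
#' default occasion-method equivalence.
#'
#' @param model an `mmModel` object.
#' @return named numeric vector of population parameter values.
#' @export
recoveryPopulation <- function(model) {
  stopifnot_model(model)
  th <- trueValues(model)
  pt <- model$partable
  ids <- pt_free_ids(pt)
  set_fam <- function(th, fam, values) {
    ks <- unique(ids[pt$family == fam & pt$free])
    th[ks] <- rep_len(values, length(ks))
    th
  }
  th <- set_fam(th, "loading_trait", c(0.9, 1.1, 1.0, 0.8, 1.2))
  th <- set_fam(th, "loading_occasion", c(1.1, 0.9, 1.0, 1.2, 0.8))
  th <- set_fam(th, "loading_om", c(0.9, 1.1, 1.0))
  th <- set_fam(th, "var_trait", 0.5)
  th <- set_fam(th, "var_occasion", 0.3)
  th <- set_fam(th, "var_tm", 0.3)
  th <- set_fam(th, "var_om", 0.15)
  th <- set_fam(th, "var_error", 0.3)
  th <- set_fam(th, "var_resid_diff", 0.2)
  th <- set_fam(th, "slope_trait", -0.3)
  th <- set_fam(th, "slope_tm", 0.2)
  th <- set_fam(th, "cov_latent", 0.3)
  th
}

# Population used by the example-data generators: loadings spread around 1,
# moderate trait generalizability across situations, small occasion and
# occasion-method variance, substantial trait-method variance.
example_population <- function(which = c("simulated_like", "real_like")) {
  which <- match.arg(which)
  if (which == "simulated_like") {
    design <- mmDesign(indicators = 3, methods = 2, occasions = 3, situations = 2)
    options <- mmOptions(cov_trait = TRUE,
                         equivalence_trait = "congeneric",
                         equivalence_occasion = "congeneric",
                         equivalence_om = "congeneric")
  } else {
    design <- mmDesign(indicators = 3, methods = 2, occasions = 2, situations = 2)
    options <- mmOptions(structural = "trait_interactions",
                         include_om_factors = FALSE, mean_structure = TRUE,
                         cov_occasion = TRUE,
                         equivalence_trait = "congeneric",
                         equivalence_occasion = "congeneric",
                         equivalence_om = "congeneric")
  }
  model <- buildModel(design, options)
  th <- trueValues(model)
  pt <- model$partable
  ids <- pt_free_ids(pt)
  set_fam <- function(th, fam, values) {
    rows <- which(pt$family == fam & pt$free)
    ks <- unique(ids[rows])
    th[ks] <- rep_len(values, length(ks))
    th
  }
  th <- set_fam(th, "loading_trait", c(0.9, 1.1, 1.0, 0.8, 1.2))
  th <- set_fam(th, "loading_occasion", c(1.1, 0.9, 1.0, 1.2, 0.8))
  th <- set_fam(th, "loading_om", c(0.9, 1.1, 1.0))
  th <- set_fam(th, "var_trait", 0.5)
  th <- set_fam(th, "var_occasion", 0.12)
  th <- set_fam(th, "var_tm", 0.45)
  th <- set_fam(th, "var_om", 0.08)
  th <- set_fam(th, "var_error", 0.25)
  if (which == "simulated_like") {
    th <- set_fam(th, "cov_latent", 0.35)     # trait covariance; Corr = 0.7
  } else {
    th <- set_fam(th, "slope_trait", -0.4)    # buffering interaction
    th <- set_fam(th, "var_resid_diff", 0.2)
    # E[T_2 - T_1] = b0 + b1 * E[T_1]: intercept chosen so the marginal
    # situation mean difference is -0.43 scale points at E[T_1] = 3.6
    th <- set_fam(th, "diff_intercept", -0.43 + 0.4 * 3.6)
    th <- set_fam(th, "latent_mean", 3.6)
    th <- set_fam(th, "intercept", c(0.2, -0.2, 0.1, -0.1, 0.15))
    th <- set_fam(th, "cov_latent", 0.05)     # cross-situation occasion covs
  }
  list(design = design, options = options, model = model, theta = th)
}

#' Generate data emulating the packaged example designs
#'
#' `"simulated_like"` produces 500 subjects on the 3-indicator, 2-method,
#' 3-occasion, 2-situation design (36 continuous, complete variables).
#' `"real_like"` produces 425 subjects on the 3-indicator, 2-method,
#' 2-occasion, 2-situation design (24 variables) with responses mapped to a
#' 1..5 rating scale and sporadic missingness; it emulates the design,
#' scale, and qualitative structure of a questionnaire study (situation
#' mean difference, buffering person-by-situation interaction, strong
#' trait-method variance), not any particular dataset's values.
#'
#' @param which `"simulated_like"` or `"real_like"`.
#' @param seed integer seed; the same seed reproduces the same table.
#' @return an `mmData` object.
#' @export
exampleData <- function(which = c("simulated_like", "real_like"), seed = 1) {
  which <- match.arg(which)
  pop <- example_population(which)
  if (which == "simulated_like")
    return(simulateData(pop$model, pop$theta, n = 500, seed = seed))
  dat <- simulateData(pop$model, pop$theta, n = 425, seed = seed,
                      mcar_rate = 0.03)
  Y <- dat$values
  Y <- pmin(pmax(round(Y), 1), 5)   # 5-point rating scale
  asWideData(Y, pop$design)
}

#' Monte-Carlo parameter-recovery study
#'
#' Repeatedly simulates data from a population model and refits it,
#' reporting per-parameter bias, root-mean-square error, coverage of the
#' nominal 95% Wald intervals, and the convergence rate.
#'
#' @param model an `mmModel` object (the fitted model; also the generator).
#' @param theta population parameter vector.
#' @param n subjects per replicate.
#' @param n_replicates number of replicates (>= 2).
#' @param seed master seed; replicate r uses `seed + r`.
#' @param se compute standard errors per replicate (needed for coverage).
#' @param ... passed to [fitModel()].
#' @return a list of class `mmRecovery` with the per-parameter summary table
#'   and the replicate-level estimates.
#' @export
parameterRecovery <- function(model, theta = NULL, n, n_replicates, seed = 1,
                              se = TRUE, ...) {
  stopifnot_model(model)
  if (n_replicates < 2) stop("`n_replicates` must be at least 2", call. = FALSE)
  if (is.null(theta)) theta <- trueValues(model)
  nfree <- pt_n_free(model$partable)
  pnames <- pt_param_names(model$partable)
  est <- ses <- matrix(NA_real_, n_replicates, nfree,
                       dimnames = list(NULL, pnames))
  converged <- logical(n_replicates)
  for (r in seq_len(n_replicates)) {
    dat <- simulateData(model, theta, n = n, seed = seed + r)
    fit <- tryCatch(
      suppressWarnings(fitModel(dat, model, se = se, seed = seed + r, ...)),
      error = function(e) NULL)
    if (is.null(fit)) next
    converged[r] <- fit$converged
    if (fit$converged) {
      est[r, ] <- fit$estimates
      if (se) ses[r, ] <- fit$se
    }
  }
  if (!any(converged))
    stop("harness error: no replicate converged", call. = FALSE)
  thv <- unname(if (!is.null(names(theta))) theta[pnames] else theta)
  ok <- converged
  bias <- colMeans(est[ok, , drop = FALSE]) - thv
  rmse <- sqrt(colMeans(sweep(est[ok, , drop = FALSE], 2, thv)^2))
  coverage <- rep(NA_real_, nfree)
  if (se) {
    lo <- est - 1.96 * ses
    hi <- est + 1.96 * ses
    coverage <- colMeans(sweep(lo[ok, , drop = FALSE], 2, thv, "<=") &
                           sweep(hi[ok, , drop = FALSE], 2, thv, ">="),
                         na.rm = TRUE)
  }
  structure(list(
    summary = data.frame(parameter = pnames, true = thv, bias = bias,
                         rmse = rmse, coverage = coverage, row.names = NULL),
    estimates = est, ses = ses,
    convergence_rate = mean(converged),
    n_replicates = n_replicates, n = n
  ), class = "mmRecovery")
}

#' @export
print.mmRecovery <- function(x, ...) {
  cat(sprintf("Parameter recovery: %d replicates at n = %d (convergence rate %.2f)\n",
              x$n_replicates, x$n, x$convergence_rate))
  cat(sprintf("  max |bias| = %.4f, max RMSE = %.4f\n",
              max(abs(x$summary$bias)), max(x$summary$rmse)))
  if (!all(is.na(x$summary$coverage)))
    cat(sprintf("  95%% coverage range: [%.3f, %.3f]\n",
                min(x$summary$coverage, na.rm = TRUE),
                max(x$summary$coverage, na.rm = TRUE)))
  invisible(x)
}
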