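#' Fit indices with benchmark annotations
#'
#' Computes the incremental and absolute fit indices from a fitted model and
#' its independence baseline (fit with the same estimator): CFI, TLI, RMSEA
#' with a 90% confidence interval, SRMR (covariance residuals only), AIC and
#' BIC, plus annotations against the conventional acceptable-fit benchmarks
#' chi-square/df <= 3, CFI and TLI >= 0.90, RMSEA <= 0.08, SRMR <= 0.10.
#'
#' @param fit an `mmFit` object.
#' @param baseline optional `mmFit` of an alternative baseline model; by
#'   default the independence baseline computed during fitting is used.
#' @return a list of class `mmIndices`.
#' @export
fitIndices <- function(fit, baseline = NULL) {
  stopifnot(inherits(fit, "mmFit"))
  chisq <- fit$chisq; df <- fit$df; n <- fit$n
  if (is.null(baseline)) {
    chisq_b <- fit$chisq_base; df_b <- fit$df_base
  } else {
    stopifnot(inherits(baseline, "mmFit"))
    chisq_b <- baseline$chisq; df_b <- baseline$df
  }
  out_of_range <- chisq_b < chisq

  d_m <- max(chisq - df, 0)
  if (d_m < 1e-6) d_m <- 0   # below the convergence tolerance: perfect fit
  d_b <- max(chisq_b - df_b, 0)
  cfi <- if (max(d_m, d_b) == 0) 1 else 1 - d_m / max(d_b, d_m)
  tli <- if (df > 0 && df_b > 0 && chisq_b / df_b > 1) {
    min(1, (chisq_b / df_b - chisq / df) / (chisq_b / df_b - 1))
  } else 1
  rmsea <- if (df > 0) sqrt(max(chisq - df, 0) / (df * n)) else 0

  # 90% CI via the noncentral chi-square (ncp inversion)
  rmsea_ci <- c(NA_real_, NA_real_)
  if (df > 0 && chisq > 0) {
    find_ncp <- function(prob) {
      if (stats::pchisq(chisq, df, ncp = 0) < prob) return(0)
      upper <- max(chisq * 3, df * n, 100)
      tryCatch(stats::uniroot(function(l) stats::pchisq(chisq, df, ncp = l) - prob,
                              c(0, upper), tol = 1e-8)$root,
               error = function(e) NA_real_)
    }
    rmsea_ci <- c(sqrt(max(find_ncp(0.95), 0) / (df * n)),
                  sqrt(max(find_ncp(0.05), 0) / (df * n)))
  } else if (df > 0) rmsea_ci <- c(0, 0)

  S <- fit$sample_Sigma; Sg <- fit$Sigma_hat
  sd_ <- sqrt(diag(S))
  std_res <- (S - Sg) / tcrossprod(sd_)
  srmr <- sqrt(mean(std_res[upper.tri(std_res, diag = TRUE)]^2))

  k <- fit$n_free
  aic <- -2 * fit$loglik + 2 * k
  bic <- -2 * fit$loglik + k * log(n)

  chisq_df_ratio <- if (df > 0) chisq / df else NA_real_
  structure(list(
    chisq = chisq, df = df, pvalue = fit$pvalue,
    chisq_baseline = chisq_b, df_baseline = df_b,
    chisq_df_ratio = chisq_df_ratio,
    cfi = cfi, tli = tli, rmsea = rmsea, rmsea_ci = rmsea_ci, srmr = srmr,
    aic = aic, bic = bic, out_of_range = out_of_range,
    benchmarks = list(
      chisq_df_ok = is.na(chisq_df_ratio) || chisq_df_ratio <= 3,
      cfi_ok = cfi >= 0.90, tli_ok = tli >= 0.90,
      rmsea_ok = rmsea <= 0.08, srmr_ok = srmr <= 0.10)
  ), class = "mmIndices")
}

#' @export
print.mmIndices <- function(x, ...) {
  mark <- function(ok) if (isTRUE(ok)) "acceptable" else "poor"
  cat(sprintf("chisq = %.3f, df = %d, p = %.4g (chisq/df = %.2f, %s)\n",
              x$chisq, x$df, x$pvalue, x$chisq_df_ratio,
              mark(x$benchmarks$chisq_df_ok)))
  cat(sprintf("CFI = %.3f (%s), TLI = %.3f (%s)\n", x$cfi,
              mark(x$benchmarks$cfi_ok), x$tli, mark(x$benchmarks$tli_ok)))
  cat(sprintf("RMSEA = %.3f [%.3f, %.3f] (%s), SRMR = %.3f (%s)\n",
              x$rmsea, x$rmsea_ci[1], x$rmsea_ci[2],
              mark(x$benchmarks$rmsea_ok), x$srmr, mark(x$benchmarks$srmr_ok)))
  cat(sprintf("AIC = %.2f, BIC = %.2f\n", x$aic, x$bic))
  if (x$out_of_range)
    cat("NOTE: baseline chisq below model chisq; incremental indices out of range\n")
  invisible(x)
}

#' Chi-square difference test for nested models
#'
#' Compares a restricted model against a less restricted one fitted to the
#' same data with the same estimator.
#'
#' @param fit_restricted,fit_free `mmFit` objects; the restricted model must
#'   be nested in the free one (fewer free parameters).
#' @return list with `dchisq`, `ddf`, `pvalue`.
#' @export
chisqDiffTest <- function(fit_restricted, fit_free) {
  stopifnot(inherits(fit_restricted, "mmFit"), inherits(fit_free, "mmFit"))
  if (fit_restricted$n != fit_free$n)
    stop("models were fit to different numbers of subjects", call. = FALSE)
  ddf <- fit_restricted$df - fit_free$df
  dchisq <- fit_restricted$chisq - fit_free$chisq
  if (ddf < 0)
    stop("nesting error: the restricted model has fewer degrees of freedom",
         call. = FALSE)
  if (ddf == 0 && abs(dchisq) > 1e-6)
    warning("models have equal df but different chisq; not nested?",
            call. = FALSE)
  if (dchisq < -1e-4)
    warning("negative chisq difference beyond tolerance; possible local optimum",
            call. = FALSE)
  dchisq <- max(dchisq, 0)
  list(dchisq = dchisq, ddf = ddf,
       pvalue = if (ddf > 0) stats::pchisq(dchisq, ddf, lower.tail = FALSE)
       else NA_real_)
}
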