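# Maximum-likelihood estimation of an mmModel: listwise (complete-case)
# normal-theory ML or full-information ML (casewise likelihood grouped by
# missing-data pattern), with a jittered-restart schedule, observed-
# information standard errors, and admissibility diagnostics.

chol_logdet_inv <- function(Sigma) {
  R <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  list(logdet = 2 * sum(log(diag(R))), inv = chol2inv(R))
}

# sufficient statistics of the complete cases (ML covariance, divisor n)
listwise_stats <- function(Y) {
  keep <- stats::complete.cases(Y)
  if (!any(keep))
    stop("empty-sample error: no complete cases for listwise estimation",
         call. = FALSE)
  Yc <- Y[keep, , drop = FALSE]
  n <- nrow(Yc)
  m <- colMeans(Yc)
  Yc <- sweep(Yc, 2, m)
  list(n = n, m = m, S = crossprod(Yc) / n)
}

# per-missing-pattern sufficient statistics for FIML
pattern_stats <- function(Y) {
  obs <- !is.na(Y)
  if (any(rowSums(obs) == 0))
    stop("empty-sample error: subject(s) with no observed values", call. = FALSE)
  key <- apply(obs, 1, paste, collapse = "")
  pats <- list()
  for (k in unique(key)) {
    rows <- which(key == k)
    o <- which(obs[rows[1], ])
    Yk <- Y[rows, o, drop = FALSE]
    nk <- length(rows)
    mk <- colMeans(Yk)
    Sk <- crossprod(sweep(Yk, 2, mk)) / nk
    pats[[k]] <- list(idx = o, n = nk, m = mk, S = Sk)
  }
  pats
}

loglik_listwise <- function(Sigma, mu, st, with_means) {
  cli <- chol_logdet_inv(Sigma)
  if (is.null(cli)) return(-Inf)
  p <- ncol(Sigma)
  q <- cli$logdet + sum(cli$inv * st$S)
  if (with_means) {
    d <- st$m - mu
    q <- q + sum(d * (cli$inv %*% d))
  }
  -st$n / 2 * (p * log(2 * pi) + q)
}

loglik_fiml <- function(Sigma, mu, pats) {
  ll <- 0
  for (pk in pats) {
    o <- pk$idx
    cli <- chol_logdet_inv(Sigma[o, o, drop = FALSE])
    if (is.null(cli)) return(-Inf)
    d <- pk$m - mu[o]
    ll <- ll - pk$n / 2 * (length(o) * log(2 * pi) + cli$logdet +
                             sum(cli$inv * pk$S) + sum(d * (cli$inv %*% d)))
  }
  ll
}

# EM for the saturated multivariate-normal model under missing data;
# returns the FIML-saturated mean, covariance, and log-likelihood.
em_saturated <- function(Y, max_iter = 500, tol = 1e-8) {
  p <- ncol(Y); n <- nrow(Y)
  mu <- colMeans(Y, na.rm = TRUE)
  v <- apply(Y, 2, stats::var, na.rm = TRUE)
  v[!is.finite(v) | v <= 0] <- 1
  Sigma <- diag(v, p)
  pats_rows <- split(seq_len(n), apply(!is.na(Y), 1, paste, collapse = ""))
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    sum_y <- numeric(p)
    sum_yy <- matrix(0, p, p)
    for (rows in pats_rows) {
      o <- which(!is.na(Y[rows[1], ]))
      u <- setdiff(seq_len(p), o)
      Yo <- Y[rows, o, drop = FALSE]
      nk <- length(rows)
      if (!length(u)) {
        sum_y[o] <- sum_y[o] + colSums(Yo)
        sum_yy[o, o] <- sum_yy[o, o] + crossprod(Yo)
        next
      }
      Soo_inv <- solve(Sigma[o, o, drop = FALSE])
      B <- Sigma[u, o, drop = FALSE] %*% Soo_inv
      Eu <- matrix(mu[u], nk, length(u), byrow = TRUE) +
        sweep(Yo, 2, mu[o]) %*% t(B)
      Cuu <- Sigma[u, u, drop = FALSE] - B %*% Sigma[o, u, drop = FALSE]
      sum_y[o] <- sum_y[o] + colSums(Yo)
      sum_y[u] <- sum_y[u] + colSums(Eu)
      sum_yy[o, o] <- sum_yy[o, o] + crossprod(Yo)
      sum_yy[o, u] <- sum_yy[o, u] + crossprod(Yo, Eu)
      sum_yy[u, o] <- t(sum_yy[o, u, drop = FALSE])
      sum_yy[u, u] <- sum_yy[u, u] + crossprod(Eu) + nk * Cuu
    }
    mu <- sum_y / n
    Sigma <- sum_yy / n - tcrossprod(mu)
    Sigma <- (Sigma + t(Sigma)) / 2
    ll <- loglik_fiml(Sigma, mu, pattern_stats(Y))
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) break
    ll_old <- ll
  }
  list(mu = mu, Sigma = Sigma, loglik = ll)
}

# FIML log-likelihood of the independence (baseline) model; factorizes into
# per-variable univariate normal likelihoods over the observed cases.
baseline_fiml <- function(Y) {
  ll <- 0
  for (j in seq_len(ncol(Y))) {
    y <- Y[, j]; y <- y[!is.na(y)]
    nj <- length(y)
    vj <- sum((y - mean(y))^2) / nj
    ll <- ll - nj / 2 * (log(2 * pi) + log(vj) + 1)
  }
  ll
}

# data-informed start values (loadings 1, intercepts at sample means,
# latent variances at half the reference-manifest variance, error variances
# at half the own variance, slopes and covariances 0)
start_values <- function(model, Y) {
  pt <- model$partable
  v <- apply(Y, 2, stats::var, na.rm = TRUE)
  v[!is.finite(v) | v <= 0] <- 1
  mns <- colMeans(Y, na.rm = TRUE)
  cn <- model$manifests
  ref_var <- function(s) {
    if (is.null(model$design)) return(stats::median(v))
    lay <- manifestLayout(model$design)
    v[which(lay$i == 1 & lay$m == 1 & lay$t == 1 & lay$s == s)]
  }
  for (r in seq_len(nrow(pt))) {
    if (!pt$free[r]) next
    fam <- pt$family[r]
    if (fam == "var_error") {
      pt$value[r] <- 0.5 * v[match(pt$lhs[r], cn)]
    } else if (fam %in% c("var_trait", "var_occasion", "var_tm", "var_om",
                          "var_resid_diff")) {
      s <- pt$s[r]
      pt$value[r] <- 0.5 * ref_var(if (is.na(s)) 1L else s)
    } else if (fam == "intercept") {
      pt$value[r] <- mns[match(pt$lhs[r], cn)]
    } else if (fam == "latent_mean") {
      s <- pt$s[r]
      if (!is.null(model$design)) {
        lay <- manifestLayout(model$design)
        pt$value[r] <- mns[which(lay$i == 1 & lay$m == 1 & lay$t == 1 &
                                   lay$s == s)]
      }
    } else if (fam %in% c("slope_trait", "slope_tm", "cov_latent",
                          "diff_intercept")) {
      pt$value[r] <- 0
    } else if (fam %in% c("custom", "intercept_saturated", "")) {
      # rows added by custom lines or parsed syntax: infer from shape
      j <- match(pt$lhs[r], cn)
      if (pt$op[r] == "~~" && pt$lhs[r] == pt$rhs[r] && !is.na(j)) {
        pt$value[r] <- 0.5 * v[j]
      } else if (pt$op[r] == "~~" && pt$lhs[r] != pt$rhs[r]) {
        cv <- if (!is.na(j) && pt$rhs[r] %in% cn)
          stats::cov(Y[, pt$lhs[r]], Y[, pt$rhs[r]],
                     use = "pairwise.complete.obs") else 0
        pt$value[r] <- if (is.finite(cv)) cv else 0
      } else if (pt$op[r] == "~1" && !is.na(j)) {
        pt$value[r] <- mns[j]
      }
    } else if (pt$op[r] == "=~") {
      pt$value[r] <- 1
    }
  }
  model$partable <- pt
  model
}

# add saturated free manifest means (used by FIML when the model itself has
# no mean structure; keeps chi-square and df unchanged)
augment_saturated_means <- function(model) {
  pt <- model$partable
  for (y in model$manifests)
    pt <- pt_bind(pt, pt_row(y, "~1", "", free = TRUE, value = 0,
                             family = "intercept_saturated"))
  model$partable <- pt
  model$options$mean_structure <- TRUE
  model
}

#' Fit an MM-LST-RF model by maximum likelihood
#'
#' Minimizes the normal-theory maximum-likelihood discrepancy, either on the
#' complete cases (`missing = "listwise"`) or by full-information maximum
#' likelihood over the observed-data patterns (`missing = "fiml"`; unbiased
#' under missing-at-random). With FIML and no model mean structure, manifest
#' means enter the likelihood saturated, leaving the chi-square and degrees
#' of freedom unchanged.
#'
#' Variances are estimated unbounded so that inadmissible (Heywood) solutions
#' surface as negative variance estimates -- a diagnostic signal, flagged in
#' the result rather than silently constrained away. A seeded jittered
#' restart schedule guards against local minima.
#'
#' @param data an `mmData` object (or numeric matrix with the model's column
#'   count).
#' @param model an `mmModel` object.
#' @param missing `"listwise"` or `"fiml"`; defaults to the model option.
#' @param se compute observed-information standard errors.
#' @param start optional start vector overriding the data-informed defaults.
#' @param n_restarts maximum jittered restarts after a failed convergence.
#' @param seed seed for the restart jitter.
#' @param control passed to [stats::nlminb()].
#' @return an object of class `mmFit`.
#' @export
fitModel <- function(data, model, missing = NULL, se = TRUE, start = NULL,
                     n_restarts = 3, seed = 1,
                     control = list(iter.max = 5000, eval.max = 20000,
                                    rel.tol = 1e-10)) {
  stopifnot_model(model)
  if (inherits(data, "mmData")) Y <- data$values
  else if (is.matrix(data)) Y <- data
  else stop("`data` must be an mmData object or numeric matrix", call. = FALSE)
  p <- length(model$manifests)
  if (ncol(Y) != p)
    stop(sprintf("data has %d columns but the model expects %d", ncol(Y), p),
         call. = FALSE)
  colnames(Y) <- model$manifests
  if (is.null(missing)) {
    missing <- if (!is.null(model$options$missing)) model$options$missing
    else "listwise"
  }
  missing <- match.arg(missing, c("listwise", "fiml"))

  if (missing == "fiml" && !any(model$partable$op == "~1"))
    model <- augment_saturated_means(model)
  with_means <- any(model$partable$op == "~1")
  model <- start_values(model, Y)
  ram <- compileRAM(model)
  pseq <- seq_len(p)

  if (missing == "listwise") {
    st <- listwise_stats(Y)
    n_used <- st$n
    sat_cli <- chol_logdet_inv(st$S)
    if (is.null(sat_cli))
      stop("sample covariance matrix of the complete cases is singular",
           call. = FALSE)
    ll_sat <- -st$n / 2 * (p * log(2 * pi) + sat_cli$logdet + p)
    negll <- function(theta) {
      mm <- tryCatch(ram_moments_all(ram, theta), error = function(e) NULL)
      if (is.null(mm)) return(1e12)
      ll <- loglik_listwise(mm$V[pseq, pseq, drop = FALSE], mm$mu[pseq], st,
                            with_means)
      if (!is.finite(ll)) return(1e12)
      -ll
    }
    dl_moments <- neg_dldmoments_listwise(st, with_means)
    sample_Sigma <- st$S; sample_mean <- st$m
  } else {
    pats <- pattern_stats(Y)
    n_used <- nrow(Y)
    sat <- em_saturated(Y)
    ll_sat <- sat$loglik
    negll <- function(theta) {
      mm <- tryCatch(ram_moments_all(ram, theta), error = function(e) NULL)
      if (is.null(mm)) return(1e12)
      ll <- loglik_fiml(mm$V[pseq, pseq, drop = FALSE], mm$mu[pseq], pats)
      if (!is.finite(ll)) return(1e12)
      -ll
    }
    dl_moments <- neg_dldmoments_fiml(pats, p)
    sample_Sigma <- sat$Sigma; sample_mean <- sat$mu
  }
  negll_grad <- function(theta) {
    g <- tryCatch(ram_grad_negll(ram, theta, dl_moments),
                  error = function(e) NULL)
    if (is.null(g)) num_gradient(negll, theta) else g
  }

  theta0 <- if (is.null(start)) pt_start(model$partable) else start
  nfree <- pt_n_free(model$partable)
  if (length(theta0) != nfree)
    stop(sprintf("start vector must have length %d", nfree), call. = FALSE)
  scale_n <- n_used / 2  # optimize on the discrepancy scale, gradients O(1)
  fobj <- function(theta) negll(theta) / scale_n
  fgrad <- function(theta) negll_grad(theta) / scale_n

  best <- NULL
  rng <- local({set.seed(seed); function(n, lo, hi) stats::runif(n, lo, hi)})
  variance_rows <- model$partable$op == "~~" &
    model$partable$lhs == model$partable$rhs & model$partable$free
  var_par <- unique(pt_free_ids(model$partable)[variance_rows])
  for (attempt in 0:n_restarts) {
    th_start <- theta0
    if (attempt > 0) {
      jit <- rng(nfree, -0.2, 0.2)
      th_start <- theta0 + jit
      th_start[var_par] <- pmax(theta0[var_par], 0.05) * exp(jit[var_par] * 2)
    }
    opt <- tryCatch(stats::nlminb(th_start, fobj, gradient = fgrad,
                                  control = control),
                    error = function(e) NULL)
    if (is.null(opt)) next
    grad <- fgrad(opt$par)
    ok <- is.finite(opt$objective) && max(abs(grad)) < 1e-4
    if (is.null(best) || opt$objective < best$objective - 1e-10) {
      best <- opt; best$grad_max <- max(abs(grad)); best$ok <- ok
    }
    if (ok && attempt >= 0 && opt$convergence == 0) break
  }
  if (is.null(best))
    stop("convergence error: optimizer failed on all attempts", call. = FALSE)
  # polish pass from the optimum at a tighter tolerance
  pol <- tryCatch(stats::nlminb(best$par, fobj, gradient = fgrad,
                                control = list(rel.tol = 1e-13,
                                               iter.max = 1000,
                                               eval.max = 5000)),
                  error = function(e) NULL)
  if (!is.null(pol) && is.finite(pol$objective) &&
        pol$objective <= best$objective) {
    best$par <- pol$par
    best$objective <- pol$objective
    grad <- fgrad(pol$par)
    best$grad_max <- max(abs(grad))
    best$ok <- best$ok || best$grad_max < 1e-4
  }
  theta_hat <- best$par
  converged <- isTRUE(best$ok)
  if (!converged)
    warning("convergence not certain (max |gradient| = ",
            format(best$grad_max, digits = 3), "); best solution returned",
            call. = FALSE)

  ll <- -negll(theta_hat)
  pnames <- pt_param_names(model$partable)
  est <- stats::setNames(theta_hat, pnames)

  se_vec <- z_vec <- rep(NA_real_, nfree)
  info_singular <- FALSE
  if (se) {
    H <- tryCatch(stats::optimHess(theta_hat, negll, gr = negll_grad),
                  error = function(e) NULL)
    V <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL) else NULL
    if (is.null(V) || any(!is.finite(diag(V))) || any(diag(V) < 0)) {
      info_singular <- TRUE
    } else {
      se_vec <- sqrt(diag(V))
      z_vec <- theta_hat / se_vec
    }
  }

  mm_hat <- ram_moments_all(ram, theta_hat)
  Sigma_hat <- mm_hat$V[pseq, pseq, drop = FALSE]
  mu_hat <- if (with_means) mm_hat$mu[pseq] else NULL

  # admissibility: negative variance estimates; non-PSD latent covariance
  ids <- pt_free_ids(model$partable)
  neg_var <- character(0)
  for (r in which(variance_rows))
    if (est[ids[r]] < 0) neg_var <- c(neg_var, model$partable$lhs[r])
  neg_var <- unique(neg_var)
  lat_idx <- seq_len(ram$nv)[-pseq]
  latent_psd <- TRUE
  if (length(lat_idx)) {
    ev <- eigen(mm_hat$V[lat_idx, lat_idx, drop = FALSE],
                symmetric = TRUE, only.values = TRUE)$values
    latent_psd <- min(ev) > -1e-6
  }

  # baseline (independence) model with the same estimator
  if (missing == "listwise") {
    ll_base <- loglik_listwise(diag(diag(sample_Sigma), p), sample_mean,
                               listwise_stats(Y), with_means = FALSE)
  } else {
    ll_base <- baseline_fiml(Y)
  }
  df <- degreesOfFreedom(model)
  df_base <- p * (p + 1) / 2 - p
  chisq <- max(0, 2 * (ll_sat - ll))
  chisq_base <- max(0, 2 * (ll_sat - ll_base))

  fit <- structure(list(
    model = model, estimates = est, se = stats::setNames(se_vec, pnames),
    z = stats::setNames(z_vec, pnames),
    loglik = ll, loglik_sat = ll_sat, loglik_base = ll_base,
    chisq = chisq, df = df, pvalue = stats::pchisq(chisq, df, lower.tail = FALSE),
    chisq_base = chisq_base, df_base = df_base,
    n = n_used, n_free = nfree,
    estimator = if (missing == "fiml") "fiml" else "ml_listwise",
    converged = converged, grad_max = best$grad_max,
    info_singular = info_singular,
    negative_variances = neg_var, latent_psd = latent_psd,
    admissible = converged && !length(neg_var) && latent_psd,
    Sigma_hat = Sigma_hat, mu_hat = mu_hat,
    Sigma_all = mm_hat$V, mu_all = mm_hat$mu,
    sample_Sigma = sample_Sigma, sample_mean = sample_mean,
    with_means = with_means,
    objective = negll
  ), class = "mmFit")
  fit$indices <- fitIndices(fit)
  fit
}

# Analytic gradient of the negative log-likelihood via the RAM chain rule.
# With P = F(I-A)^-1, W = (I-A)^-1 S (I-A)^-T, Sigma = (PW-block),
# dSigma/dS_ij and dSigma/dA_ij reduce to outer products of columns of P and
# W, so <dL/dSigma, dSigma/dtheta> collapses into two nv x nv matrix
# products. `Gfun(Sigma, mu)` must return the derivatives of -loglik with
# respect to Sigma (symmetric matrix) and mu (vector).
ram_grad_negll <- function(ram, theta, Gfun) {
  m <- ram_matrices(ram, theta)
  nv <- ram$nv; p <- ram$p; pseq <- seq_len(p)
  Tm <- solve(diag(nv) - m$A)
  P <- Tm[pseq, , drop = FALSE]
  W <- Tm %*% m$S %*% t(Tm)
  Sigma <- W[pseq, pseq, drop = FALSE]
  nu <- as.numeric(Tm %*% m$M)
  gg <- Gfun(Sigma, nu[pseq])
  if (is.null(gg)) return(NULL)
  PtG <- crossprod(P, gg$G)                    # nv x p
  Q <- PtG %*% W[pseq, , drop = FALSE]         # <G, dSigma/dA>, W symmetric
  R <- PtG %*% P                               # <G, dSigma/dS>
  Pg <- as.numeric(crossprod(P, gg$gmu))
  nfree <- max(ram$free_ids)
  out <- numeric(nfree)
  for (r in seq_along(ram$slot)) {
    k <- ram$free_ids[r]
    if (k == 0) next
    pos <- ram$rowpos[[r]]
    val <- switch(ram$slot[r],
                  A = 2 * Q[pos[1], pos[2]] + Pg[pos[1]] * nu[pos[2]],
                  S = if (pos[1] == pos[2]) R[pos[1], pos[1]]
                  else 2 * R[pos[1], pos[2]],
                  M = Pg[pos[1]])
    out[k] <- out[k] + val
  }
  out
}

# dL/dSigma, dL/dmu of the negative listwise log-likelihood
neg_dldmoments_listwise <- function(st, with_means) {
  function(Sigma, mu) {
    cli <- chol_logdet_inv(Sigma)
    if (is.null(cli)) return(NULL)
    Si <- cli$inv
    A <- st$S
    gmu <- numeric(length(mu))
    if (with_means) {
      d <- st$m - mu
      A <- A + tcrossprod(d)
      gmu <- -st$n * as.numeric(Si %*% d)
    }
    list(G = st$n / 2 * (Si - Si %*% A %*% Si), gmu = gmu)
  }
}

# dL/dSigma, dL/dmu of the negative FIML log-likelihood (pattern-wise)
neg_dldmoments_fiml <- function(pats, p) {
  function(Sigma, mu) {
    G <- matrix(0, p, p)
    gmu <- numeric(p)
    for (pk in pats) {
      o <- pk$idx
      cli <- chol_logdet_inv(Sigma[o, o, drop = FALSE])
      if (is.null(cli)) return(NULL)
      Si <- cli$inv
      d <- pk$m - mu[o]
      G[o, o] <- G[o, o] +
        pk$n / 2 * (Si - Si %*% (pk$S + tcrossprod(d)) %*% Si)
      gmu[o] <- gmu[o] - pk$n * as.numeric(Si %*% d)
    }
    list(G = G, gmu = gmu)
  }
}

num_gradient <- function(f, x, h = 1e-6) {
  g <- numeric(length(x))
  for (k in seq_along(x)) {
    e <- numeric(length(x)); e[k] <- h * max(1, abs(x[k]))
    g[k] <- (f(x + e) - f(x - e)) / (2 * e[k])
  }
  g
}

#' @export
print.mmFit <- function(x, ...) {
  cat("MM-LST-RF model fit (", x$estimator, ")\n", sep = "")
  cat(sprintf("  n = %d, free parameters = %d\n", x$n, x$n_free))
  cat(sprintf("  loglik = %.3f, chisq = %.3f, df = %d, p = %.4g\n",
              x$loglik, x$chisq, x$df, x$pvalue))
  ix <- x$indices
  cat(sprintf("  CFI = %.3f, TLI = %.3f, RMSEA = %.3f, SRMR = %.3f\n",
              ix$cfi, ix$tli, ix$rmsea, ix$srmr))
  if (!x$converged) cat("  WARNING: convergence not certain\n")
  if (length(x$negative_variances))
    cat("  WARNING: negative variance estimate(s):",
        paste(x$negative_variances, collapse = ", "), "\n")
  if (!x$latent_psd)
    cat("  WARNING: latent covariance matrix not positive semidefinite\n")
  invisible(x)
}

#' Parameter estimates, standard errors, and z statistics
#'
#' Observed-information standard errors (inverse numerical Hessian of the
#' negative log-likelihood at the optimum) with Wald z = estimate / se.
#' Fixed parameters do not appear. If the information matrix is singular the
#' per-parameter entries are `NA` and the non-identification flag is set.
#'
#' @param fit an `mmFit` object.
#' @return data.frame with columns `parameter`, `estimate`, `se`, `z`,
#'   `pvalue`.
#' @export
standardErrors <- function(fit) {
  stopifnot(inherits(fit, "mmFit"))
  if (all(is.na(fit$se)) && !fit$info_singular) {
    H <- tryCatch(stats::optimHess(unname(fit$estimates), fit$objective),
                  error = function(e) NULL)
    V <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL) else NULL
    if (!is.null(V) && all(is.finite(diag(V))) && all(diag(V) >= 0)) {
      fit$se <- stats::setNames(sqrt(diag(V)), names(fit$estimates))
      fit$z <- fit$estimates / fit$se
    } else fit$info_singular <- TRUE
  }
  data.frame(parameter = names(fit$estimates),
             estimate = unname(fit$estimates),
             se = unname(fit$se), z = unname(fit$z),
             pvalue = 2 * stats::pnorm(-abs(unname(fit$z))),
             row.names = NULL)
}
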