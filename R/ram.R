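# Reticular-action-model (RAM) compilation of a parameter table.
# Variables are ordered manifests first, then latents. Three matrices:
#   A  directed coefficients (loadings y <- factor, regressions lv <- lv)
#   S  symmetric (variances / covariances of exogenous shocks & residuals)
#   M  intercept / mean vector
# Implied moments over all variables: V = (I - A)^-1 S (I - A)^-T,
# mu_all = (I - A)^-1 M; the manifest block is the model-implied covariance.

compileRAM <- function(model) {
  pt <- model$partable
  vars <- c(model$manifests, model$latents$name)
  nv <- length(vars)
  vidx <- stats::setNames(seq_len(nv), vars)

  pos_A <- matrix(integer(0), 0, 2)
  pos_S <- matrix(integer(0), 0, 2)
  pos_M <- integer(0)
  slot <- character(nrow(pt))   # which matrix each row writes to
  rowpos <- vector("list", nrow(pt))
  for (r in seq_len(nrow(pt))) {
    op <- pt$op[r]
    if (op == "=~") {
      slot[r] <- "A"; rowpos[[r]] <- c(vidx[[pt$rhs[r]]], vidx[[pt$lhs[r]]])
    } else if (op == "~") {
      slot[r] <- "A"; rowpos[[r]] <- c(vidx[[pt$lhs[r]]], vidx[[pt$rhs[r]]])
    } else if (op == "~~") {
      slot[r] <- "S"; rowpos[[r]] <- c(vidx[[pt$lhs[r]]], vidx[[pt$rhs[r]]])
    } else if (op == "~1") {
      slot[r] <- "M"; rowpos[[r]] <- vidx[[pt$lhs[r]]]
    } else stop("unknown operator in parameter table: ", op)
  }
  list(vars = vars, nv = nv, p = length(model$manifests),
       slot = slot, rowpos = rowpos,
       free_ids = pt_free_ids(pt), fixed = pt$value)
}

ram_matrices <- function(ram, theta) {
  nv <- ram$nv
  A <- matrix(0, nv, nv); S <- matrix(0, nv, nv); M <- numeric(nv)
  vals <- ifelse(ram$free_ids > 0, theta[pmax(ram$free_ids, 1L)], ram$fixed)
  for (r in seq_along(vals)) {
    pos <- ram$rowpos[[r]]
    if (ram$slot[r] == "A") A[pos[1], pos[2]] <- vals[r]
    else if (ram$slot[r] == "S") {
      S[pos[1], pos[2]] <- vals[r]; S[pos[2], pos[1]] <- vals[r]
    } else M[pos[1]] <- vals[r]
  }
  list(A = A, S = S, M = M)
}

ram_moments_all <- function(ram, theta) {
  m <- ram_matrices(ram, theta)
  IA <- diag(ram$nv) - m$A
  tot <- tryCatch(solve(IA), error = function(e)
    stop("structural-cycle error: (I - A) is singular", call. = FALSE))
  V <- tot %*% m$S %*% t(tot)
  mu <- as.numeric(tot %*% m$M)
  dimnames(V) <- list(ram$vars, ram$vars)
  names(mu) <- ram$vars
  list(V = V, mu = mu)
}

#' Model-implied moments
#'
#' Computes the model-implied covariance matrix (and mean vector, when the
#' model has a mean structure) of the manifest variables at a parameter
#' vector, by path-rule algebra: latent regressions are reduced to their
#' reduced form, then mapped through the measurement loadings.
#'
#' @param model an `mmModel` object.
#' @param theta numeric vector of free-parameter values, in
#'   [parameterNames()] order; defaults to the model's start values.
#' @return list with `Sigma` (p x p), `mu` (length p, `NULL` when no mean
#'   structure), and `Sigma_all`/`mu_all` over manifest and latent variables.
#' @export
impliedMoments <- function(model, theta = NULL) {
  stopifnot_model(model)
  ram <- compileRAM(model)
  if (is.null(theta)) theta <- pt_start(model$partable)
  nfree <- pt_n_free(model$partable)
  if (length(theta) != nfree)
    stop(sprintf("`theta` must have length %d, got %d", nfree, length(theta)),
         call. = FALSE)
  mm <- ram_moments_all(ram, theta)
  p <- ram$p
  list(Sigma = mm$V[seq_len(p), seq_len(p), drop = FALSE],
       mu = if (model$options$mean_structure || any(model$partable$op == "~1"))
         mm$mu[seq_len(p)] else NULL,
       Sigma_all = mm$V, mu_all = mm$mu)
}

# Structural association check: is Cov(a, b) identically zero over generic
# parameter values? Evaluated at deterministic generic values (distinct,
# nonzero; variances positive), which is exact up to measure-zero
# coincidences.
structurallyAssociated <- function(model, a, b) {
  ram <- compileRAM(model)
  pt <- model$partable
  ids <- pt_free_ids(pt)
  n <- pt_n_free(pt)
  th <- 0.37 + 0.013 * seq_len(n)
  # keep variances positive, leave others as generic nonzero values
  mm <- ram_moments_all(ram, th)
  abs(mm$V[a, b]) > 1e-10
}
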