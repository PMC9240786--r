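#' Fit marker effects by ridge / Bayesian ridge regression
#'
#' Estimates genome-wide marker effects for one phenotype column under a
#' Gaussian prior common to all markers. Two modes:
#'
#' * `"fast"` (default): the closed-form ridge posterior mean
#'   `beta = (Z'Z + lambda I)^-1 Z' (y - ybar)` on column-centred
#'   genotypes, with `lambda = sigma_e^2 / sigma_beta^2` from plug-in
#'   variances: `sigma_e^2 = (1 - h2) Var(y)` and
#'   `sigma_beta^2 = h2 Var(y) / sum(2 p_j (1 - p_j))`. Deterministic.
#' * `"gibbs"`: a Gibbs sampler with scaled-inverse-chi-squared priors on
#'   the marker-effect and residual variances; returns posterior means
#'   after burn-in.
#'
#' @param y numeric phenotype vector (one trait-environment column).
#' @param Z marker incidence matrix (individuals x markers, 0/1/2).
#' @param method "fast" or "gibbs".
#' @param h2 heritability used for the plug-in variances (fast mode and
#'   Gibbs initialisation).
#' @param lambda optional explicit ridge parameter (overrides the plug-in).
#' @param iter,burnin Gibbs iterations and burn-in.
#' @param df_prior,scale_mult prior degrees of freedom and a multiplier on
#'   the plug-in variances used as prior scales (weakly informative).
#' @param fixed_variances if TRUE the Gibbs sampler keeps the plug-in
#'   variance components fixed (its posterior mean then coincides with the
#'   closed-form ridge solution up to Monte-Carlo error).
#' @return object of class `marker_model`: list with `beta`, `intercept`,
#'   `centers` (marker column means), `lambda`, `method`, and for Gibbs
#'   mode the posterior-mean variance components.
#' @export
fit_marker_effects <- function(y, Z, method = c("fast", "gibbs"),
                               h2 = 0.5, lambda = NULL,
                               iter = 2000L, burnin = 500L,
                               df_prior = 5, scale_mult = 1,
                               fixed_variances = FALSE) {
  method <- match.arg(method)
  y <- as.numeric(y)
  if (length(y) != nrow(Z)) stop("length(y) must equal nrow(Z)")
  if (length(y) < 2) stop("need at least two training records")
  vy <- stats::var(y)
  if (vy == 0) stop("phenotypes have zero variance")
  p <- colMeans(Z) / 2
  het <- sum(2 * p * (1 - p))
  if (het == 0) stop("all markers are monomorphic in the training set")
  sigma_e2 <- (1 - h2) * vy
  sigma_b2 <- h2 * vy / het
  if (is.null(lambda)) lambda <- sigma_e2 / sigma_b2
  centers <- colMeans(Z)
  Zc <- sweep(Z, 2L, centers)
  yc <- y - mean(y)
  if (method == "fast") {
    ZtZ <- crossprod(Zc)
    diag(ZtZ) <- diag(ZtZ) + lambda
    beta <- drop(solve(ZtZ, crossprod(Zc, yc)))
    out <- list(beta = beta, intercept = mean(y), centers = centers,
                lambda = lambda, method = "fast")
  } else {
    if (iter <= burnin) stop("iter must exceed burnin")
    out <- brr_gibbs(yc, Zc, sigma_e2, sigma_b2, iter, burnin,
                     df_prior, scale_mult, fixed_variances)
    out$intercept <- mean(y)
    out$centers <- centers
    out$lambda <- lambda
    out$method <- "gibbs"
  }
  structure(out, class = "marker_model")
}

# Single-site Gibbs sampler for the Bayesian ridge model
#   y = Z beta + e,  beta_j ~ N(0, sigma_b2),  e ~ N(0, sigma_e2 I)
# with scaled-inverse-chi-squared priors on both variances.
brr_gibbs <- function(yc, Zc, sigma_e2, sigma_b2, iter, burnin,
                      df_prior, scale_mult, fixed_variances = FALSE) {
  n <- nrow(Zc)
  m <- ncol(Zc)
  czz <- colSums(Zc^2)
  S_b <- sigma_b2 * scale_mult * (df_prior + 2)  # prior mode at plug-in
  S_e <- sigma_e2 * scale_mult * (df_prior + 2)
  beta <- rep(0, m)
  resid <- yc
  beta_sum <- rep(0, m)
  sb_sum <- se_sum <- 0
  kept <- 0L
  for (it in seq_len(iter)) {
    for (j in seq_len(m)) {
      zj <- Zc[, j]
      rhs <- sum(zj * resid) + czz[j] * beta[j]
      cj <- czz[j] + sigma_e2 / sigma_b2
      mean_j <- rhs / cj
      new_b <- stats::rnorm(1, mean_j, sqrt(sigma_e2 / cj))
      resid <- resid - zj * (new_b - beta[j])
      beta[j] <- new_b
    }
    if (!fixed_variances) {
      sigma_b2 <- (sum(beta^2) + S_b) /
        stats::rchisq(1, df = m + df_prior)
      sigma_e2 <- (sum(resid^2) + S_e) /
        stats::rchisq(1, df = n + df_prior)
    }
    if (it > burnin) {
      beta_sum <- beta_sum + beta
      sb_sum <- sb_sum + sigma_b2
      se_sum <- se_sum + sigma_e2
      kept <- kept + 1L
    }
  }
  list(beta = beta_sum / kept, sigma_b2 = sb_sum / kept,
       sigma_e2 = se_sum / kept)
}

#' Genomic estimated breeding values
#'
#' Linear combination of estimated marker effects, `u = intercept +
#' (Z - centers) beta`, using the marker panel and ordering of the
#' training data.
#'
#' @param Z marker incidence matrix (individuals x markers).
#' @param model a `marker_model`.
#' @return numeric vector of GEBVs.
#' @export
gebv <- function(Z, model) {
  if (ncol(Z) != length(model$beta)) {
    stop("marker panel mismatch: model has ", length(model$beta),
         " markers, genotypes have ", ncol(Z))
  }
  drop(model$intercept + sweep(Z, 2L, model$centers) %*% model$beta)
}

#' Prediction accuracy
#'
#' Pearson correlation between predicted and true breeding values. The
#' caller is responsible for the lagged-effects protocol (the model must
#' have been fitted without the phenotypes of the individuals being
#' ranked).
#'
#' @param u GEBV vector.
#' @param g_true TBV vector.
#' @return Pearson correlation in \[-1, 1\].
#' @export
prediction_accuracy <- function(u, g_true) {
  if (length(u) != length(g_true)) stop("length mismatch")
  if (length(u) < 3) stop("need at least 3 individuals")
  if (stats::sd(u) == 0 || stats::sd(g_true) == 0) {
    stop("zero variance in GEBVs or TBVs")
  }
  stats::cor(u, g_true)
}
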