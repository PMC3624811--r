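#' Posterior of a regression subset under the per-predictor g-prior
#'
#' Bayesian linear regression with a Zellner-style g-prior extended to one
#' positive weight `g_j` per predictor. The posterior mean of the
#' coefficients shrinks the OLS solution towards the prior guess,
#' `beta_tilde_j = beta0_j + g_j/(g_j + 1) * (beta_hat_j - beta0_j)`,
#' so `g -> Inf` recovers OLS and `g -> 0` returns the prior mean. The
#' error variance has an Inverse-Gamma posterior with `shape = n/2` and
#' `scale = (SSR + (beta_hat - beta0)' W (beta_hat - beta0)) / 2`, where
#' `W = G^{1/2} (X'X) G^{1/2}` and `G` is diagonal with entries
#' `1/(g_j + 1)`. `g_j = Inf` is handled analytically.
#'
#' @param X Design matrix for the subset (full column rank).
#' @param y Response vector.
#' @param g Positive prior weight(s), recycled to `ncol(X)`. A value of 1
#'   treats all predictors equally ("no priors"); larger values let the
#'   corresponding predictors explain more response variance.
#' @param beta0 Prior mean of the coefficients (default all 0, reflecting
#'   a sparse-network belief).
#' @return List with `beta_hat`, `beta_tilde`, `ssr`, `shape`, `scale`,
#'   `sigma2` (posterior expectation of the error variance) and `bic`.
#' @export
g_posterior <- function(X, y, g, beta0 = rep(0, ncol(X))) {
  X <- as.matrix(X)
  n <- nrow(X)
  k <- ncol(X)
  if (n <= k + 1)
    stop("need n > k + 1 observations", call. = FALSE)
  g <- rep_len(g, k)
  if (any(is.na(g) | g <= 0))
    stop("g weights must be positive (Inf allowed)", call. = FALSE)
  if (k == 0) {
    ssr <- sum(y^2)
    shape <- n / 2
    scale <- ssr / 2
    sigma2 <- expected_sigma2(shape, scale)
    return(list(beta_hat = numeric(0), beta_tilde = numeric(0),
                ssr = ssr, shape = shape, scale = scale, sigma2 = sigma2,
                bic = bic_score(sigma2, n, 0)))
  }
  qrX <- qr(X)
  if (qrX$rank < k)
    stop("design subset is rank deficient", call. = FALSE)
  beta_hat <- qr.coef(qrX, y)
  resid <- y - X %*% beta_hat
  ssr <- sum(resid^2)
  shrink <- ifelse(is.infinite(g), 1, g / (g + 1))
  Gdiag <- ifelse(is.infinite(g), 0, 1 / (g + 1))
  beta_tilde <- beta0 + shrink * (beta_hat - beta0)
  d <- sqrt(Gdiag) * (beta_hat - beta0)
  scale <- 0.5 * (ssr + drop(crossprod(d, crossprod(X) %*% d)))
  shape <- n / 2
  sigma2 <- expected_sigma2(shape, scale)
  list(beta_hat = beta_hat, beta_tilde = beta_tilde, ssr = ssr,
       shape = shape, scale = scale, sigma2 = sigma2,
       bic = bic_score(sigma2, n, k))
}

#' Posterior expectation of the error variance
#'
#' Mean of the Inverse-Gamma posterior, `scale / (shape - 1)`. For the
#' degenerate case `shape <= 1` (no finite mean) the mode
#' `scale / (shape + 1)` is used instead, with a warning.
#'
#' @param shape,scale Inverse-Gamma posterior parameters.
#' @return Expected error variance.
#' @export
expected_sigma2 <- function(shape, scale) {
  if (scale < 0) stop("scale must be non-negative", call. = FALSE)
  if (shape > 1) return(scale / (shape - 1))
  warning("posterior shape <= 1: using the mode of sigma^2",
          call. = FALSE)
  scale / (shape + 1)
}

#' BIC from the expected error variance
#'
#' `BIC = n * log(sigma2) + k * log(n)`; a zero variance (perfect fit)
#' maps to `-Inf`, which model selection resolves in favour of fewer
#' predictors.
#'
#' @param sigma2 Expected error variance.
#' @param n Number of observations.
#' @param k Number of predictors in the model.
#' @return The BIC value.
#' @export
bic_score <- function(sigma2, n, k) {
  if (sigma2 < 0) stop("sigma2 must be non-negative", call. = FALSE)
  if (sigma2 == 0) return(-Inf)
  n * log(sigma2) + k * log(n)
}

#' Exhaustive best-subset regression under the g-prior
#'
#' Enumerates every subset of the candidate predictors (including the
#' empty model), scores each by [bic_score()] using the posterior
#' expectation of the error variance from [g_posterior()], and returns
#' the minimum-BIC model. Near-perfect fits (expected variance below
#' `sentinel_tol` times the response variance) are treated as exact and
#' resolved by fewer predictors, then enumeration order (increasing
#' size, lexicographic). Rank-deficient and under-determined subsets are
#' skipped.
#'
#' @param y Response vector (scaled).
#' @param X Design matrix of candidate predictors (scaled columns); at
#'   most 10 columns are expected (apply [initial_filtration()] first for
#'   larger candidate sets).
#' @param g Per-predictor prior weights, recycled to `ncol(X)`; `Inf`
#'   selects the analytic infinite-weight limit.
#' @param sentinel_tol Relative tolerance for the perfect-fit sentinel.
#' @return A `grn_regfit` list: `selected`, `betas` (posterior-mean
#'   coefficients), `beta_full`, `residual_variance` (expected error
#'   variance of the chosen model), `model_score` (its BIC).
#' @export
best_subset <- function(y, X, g = 1, sentinel_tol = 1e-9) {
  X <- as.matrix(X)
  p <- ncol(X)
  n <- nrow(X)
  if (p == 0 || stats::sd(y) < 1e-12)
    return(empty_regfit(colnames(X), n, y, "bbsr"))
  if (p > 25)
    stop("refusing to enumerate 2^", p, " subsets; filter candidates",
         call. = FALSE)
  g <- rep_len(g, p)
  if (any(is.na(g) | g <= 0))
    stop("g weights must be positive (Inf allowed)", call. = FALSE)
  Gdiag <- ifelse(is.infinite(g), 0, 1 / (g + 1))
  shrink <- ifelse(is.infinite(g), 1, g / (g + 1))
  fit <- bbsr_enumerate(X, as.numeric(y), Gdiag, shrink, sentinel_tol)
  if (!fit$any_valid) {
    warning("no valid subset could be scored; returning the empty model",
            call. = FALSE)
    return(empty_regfit(colnames(X), n, y, "bbsr"))
  }
  sel <- fit$subset
  beta <- stats::setNames(numeric(p), colnames(X))
  if (length(sel)) beta[sel] <- fit$beta_tilde
  structure(list(selected = colnames(X)[sel],
                 betas = beta[sel],
                 beta_full = beta,
                 residual_variance = fit$sigma2,
                 model_score = fit$bic, ssr = fit$ssr,
                 scale = fit$scale, n_scored = fit$n_scored,
                 method = "bbsr"),
            class = "grn_regfit")
}

#' Reduce a large candidate set to the most promising predictors
#'
#' When a gene has more than `limit` candidate regulators, keeps the
#' `limit` predictors with the best single-predictor BIC (marginal fit
#' under the same g-prior), always retaining predictors with prior
#' knowledge; if the priors alone exceed `limit`, the best-fitting
#' `limit` priors are kept.
#'
#' @param y Response vector.
#' @param X Candidate design matrix.
#' @param prior 0/1 flags per candidate.
#' @param g Per-candidate prior weights (as in [best_subset()]).
#' @param limit Maximum number of candidates retained (default 10).
#' @return Character vector of retained predictor names.
#' @export
initial_filtration <- function(y, X, prior = rep(0, ncol(X)), g = 1,
                               limit = 10) {
  p <- ncol(X)
  nm <- colnames(X)
  if (p <= limit) return(nm)
  g <- rep_len(g, p)
  marginal <- vapply(seq_len(p), function(j) {
    fit <- try(g_posterior(X[, j, drop = FALSE], y, g[j]), silent = TRUE)
    if (inherits(fit, "try-error")) Inf else fit$bic
  }, numeric(1))
  ord <- order(marginal, nm)
  is_prior <- prior != 0
  if (sum(is_prior) >= limit) {
    keep <- nm[ord][is_prior[ord]][seq_len(limit)]
  } else {
    priors <- nm[is_prior]
    fill <- nm[ord][!is_prior[ord]]
    keep <- c(priors, fill[seq_len(limit - length(priors))])
  }
  nm[nm %in% keep]
}

#' Modified best-subset fit for one gene
#'
#' Applies [initial_filtration()] when the candidate set exceeds `limit`,
#' builds the per-predictor g vector (`g_prior` for predictors with prior
#' knowledge, `g_no_prior` for the rest) and runs [best_subset()].
#'
#' @inheritParams initial_filtration
#' @param g_prior Weight for predictors with prior knowledge.
#' @param g_no_prior Weight for the remaining predictors (default 1).
#' @param sentinel_tol Passed to [best_subset()].
#' @return A `grn_regfit` over the original candidate set (filtered-out
#'   predictors have zero coefficients).
#' @export
bbsr_fit <- function(y, X, prior = rep(0, ncol(X)), g_prior = 1.26,
                     g_no_prior = 1, limit = 10, sentinel_tol = 1e-9) {
  nm <- colnames(X)
  prior <- stats::setNames(rep_len(prior, ncol(X)), nm)
  g <- ifelse(prior != 0, g_prior, g_no_prior)
  keep <- initial_filtration(y, X, prior, g, limit)
  fit <- best_subset(y, X[, keep, drop = FALSE],
                     g[match(keep, nm)], sentinel_tol)
  beta <- stats::setNames(numeric(length(nm)), nm)
  beta[names(fit$beta_full)] <- fit$beta_full
  fit$beta_full <- beta
  fit
}
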