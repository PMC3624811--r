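#' Control parameters for modified elastic net model selection
#'
#' @param xi_grid Grid of penalty-balance values in `[0, 1]`; `xi = 1` is
#'   the lasso endpoint, `xi = 0` the ridge endpoint.
#' @param s_grid Grid of shrinkage fractions in `[0, 1]`, expressed as the
#'   fraction of the l1 norm of the ordinary least squares solution
#'   retained by the fit (`s = 0` empty model, `s = 1` no shrinkage).
#' @param theta_prior Shrinkage modifier applied to the l1 penalty of
#'   predictors with prior knowledge (`0 < theta <= 1`; default 0.5, the
#'   low-weight setting; 0.01 is the high-weight setting). Predictors
#'   without priors keep `theta = 1`; the l2 term is never modified.
#' @param cv_folds Number of cross-validation folds (default 10). When a
#'   problem has fewer rows than folds, folds are reduced to the row count
#'   (leave-one-out floor) with a warning.
#' @param n_lambda,lambda_min_ratio Internal penalty path resolution: the
#'   `s` grid is realised on a log-spaced path of `n_lambda` penalty
#'   levels down to `lambda_min_ratio` of the smallest all-zero level,
#'   plus the unpenalized endpoint.
#' @param tol,max_sweeps Coordinate-descent convergence tolerance on the
#'   maximum coefficient change, and sweep cap.
#' @return A list of class `men_control`.
#' @export
men_control <- function(xi_grid = seq(0, 1, by = 0.1),
                        s_grid = seq(0, 1, length.out = 100),
                        theta_prior = 0.5, cv_folds = 10,
                        n_lambda = 100, lambda_min_ratio = 1e-4,
                        tol = 1e-7, max_sweeps = 1e5) {
  stopifnot(length(xi_grid) >= 1, all(xi_grid >= 0 & xi_grid <= 1),
            length(s_grid) >= 1, all(s_grid >= 0 & s_grid <= 1),
            theta_prior > 0, theta_prior <= 1, cv_folds >= 2)
  structure(list(xi_grid = sort(xi_grid), s_grid = sort(s_grid),
                 theta_prior = theta_prior, cv_folds = cv_folds,
                 n_lambda = n_lambda, lambda_min_ratio = lambda_min_ratio,
                 tol = tol, max_sweeps = as.integer(max_sweeps)),
            class = "men_control")
}

# Penalty levels for one xi: log-spaced from the smallest level that
# zeroes every coefficient (under the weighted l1 term) down to
# lambda_min_ratio of it, with the unpenalized endpoint appended. For the
# pure-ridge endpoint (xi = 0) no finite level gives an empty model, so
# the lasso-scale maximum is inflated to cover near-total shrinkage.
men_lambda_grid <- function(Xty, n, theta, xi, control) {
  lam0 <- max(abs(Xty) / (n * pmax(theta, 1e-12)))
  if (xi > 0) {
    lam_max <- lam0 / xi
    ratio <- control$lambda_min_ratio
  } else {
    # ridge shrinks only asymptotically: start far above the lasso scale
    # and descend far below it so the path spans s in (0, ~1)
    lam_max <- lam0 * 1e3
    ratio <- control$lambda_min_ratio * 1e-3
  }
  exp(seq(log(lam_max), log(lam_max * ratio),
          length.out = control$n_lambda))
}

#' Weighted elastic-net solution path
#'
#' Solves the modified elastic net over a decreasing penalty sequence by
#' cyclic coordinate descent: the residual sum of squares (scaled by
#' `1/(2n)`) is minimized under the penalty
#' `lambda * (xi * sum(theta_j * |beta_j|) + (1 - xi)/2 * sum(beta_j^2))`.
#' With all `theta_j = 1` this is the standard elastic net; `theta_j < 1`
#' lowers the l1 penalty of predictor j so it is shrunk out of the model
#' later than an otherwise equivalent predictor.
#'
#' @param X Design matrix (rows x predictors), typically scaled.
#' @param y Response vector.
#' @param theta Per-predictor l1 weights (length `ncol(X)`).
#' @param xi Penalty balance in `[0, 1]` (1 = lasso, 0 = ridge).
#' @param lambda Decreasing penalty sequence.
#' @param tol,max_sweeps Convergence controls.
#' @return Matrix of coefficients, `ncol(X)` x `length(lambda)`.
#' @export
men_path <- function(X, y, theta, xi, lambda, tol = 1e-7,
                     max_sweeps = 1e5) {
  out <- men_cd_path(crossprod(X), crossprod(X, y), nrow(X), theta, xi,
                     lambda, tol, as.integer(max_sweeps))
  rownames(out) <- colnames(X)
  out
}

# Cyclic fold assignment over rows in condition order with a seeded
# offset: stratifies folds across the time-series/steady-state layout.
cv_fold_assignment <- function(n, folds, seed) {
  offset <- sample_one(seed, folds)
  ((seq_len(n) - 1L + offset) %% folds) + 1L
}

# One deterministic draw in 1..k from a seed, without touching the
# caller's RNG stream.
sample_one <- function(seed, k) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  sample.int(k, 1)
}

#' Modified elastic net fit for one gene
#'
#' Grid search over `(xi, s)`: for every penalty balance `xi` the full
#' weighted elastic-net path is computed, the shrinkage-fraction grid `s`
#' (fraction of the OLS l1 norm) is mapped onto path positions, and
#' `cv_folds`-fold cross-validation picks the pair minimizing mean squared
#' prediction error. Coefficients are the penalized estimates at the
#' chosen grid point; exact zeros count as not selected.
#'
#' @param y Response vector (scaled).
#' @param X Design matrix of candidate regulators (scaled columns).
#' @param prior 0/1 vector flagging predictors with prior knowledge
#'   (length `ncol(X)`); prior predictors get `theta = theta_prior`.
#' @param control A [men_control()] list.
#' @param seed Seed for the cross-validation fold assignment.
#' @return A list of class `grn_regfit`: `selected` (predictor names),
#'   `betas` (coefficients of selected predictors), `beta_full`,
#'   `residual_variance`, `model_score` (the CV error), `xi`, `s`,
#'   `lambda`, `method = "men"`.
#' @export
men_fit <- function(y, X, prior = rep(0, ncol(X)),
                    control = men_control(), seed = 1) {
  p <- ncol(X)
  n <- nrow(X)
  if (p == 0 || stats::sd(y) < 1e-12)
    return(empty_regfit(colnames(X), n, y, "men"))
  theta <- ifelse(prior != 0, control$theta_prior, 1)
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)

  ols <- qr.coef(qr(X), y)
  ols[is.na(ols)] <- 0
  l1_ols <- sum(abs(ols))
  if (l1_ols < 1e-12)
    return(empty_regfit(colnames(X), n, y, "men"))

  folds <- control$cv_folds
  if (n < folds) {
    warning("reducing CV folds to the number of rows (", n, ")",
            call. = FALSE)
    folds <- n
  }
  fold_id <- cv_fold_assignment(n, folds, seed)

  best <- list(err = Inf)
  ols_fold <- function(Xtr, ytr) {
    b <- qr.coef(qr(Xtr), ytr)
    b[is.na(b)] <- 0
    b
  }
  for (xi in control$xi_grid) {
    # penalty path plus the exact unpenalized endpoint (s = 1)
    lambda <- c(men_lambda_grid(Xty, n, theta, xi, control), 0)
    path <- men_cd_path(XtX, Xty, n, theta, xi, lambda[-length(lambda)],
                        control$tol, control$max_sweeps)
    path <- cbind(path, ols)
    s_frac <- colSums(abs(path)) / l1_ols
    # map each s in the grid to the nearest path position
    s_col <- vapply(control$s_grid,
                    function(s) which.min(abs(s_frac - s)), integer(1))
    sse <- numeric(length(lambda))
    for (f in seq_len(folds)) {
      te <- fold_id == f
      Xtr <- X[!te, , drop = FALSE]
      ytr <- y[!te]
      p_tr <- men_cd_path(crossprod(Xtr), crossprod(Xtr, ytr),
                          nrow(Xtr), theta, xi,
                          lambda[-length(lambda)],
                          control$tol, control$max_sweeps)
      p_tr <- cbind(p_tr, ols_fold(Xtr, ytr))
      resid <- X[te, , drop = FALSE] %*% p_tr - y[te]
      sse <- sse + colSums(resid^2)
    }
    cv_err <- (sse / n)[s_col]
    i <- which.min(cv_err)
    if (cv_err[i] < best$err) {
      best <- list(err = cv_err[i], xi = xi, s = control$s_grid[i],
                   lambda = lambda[s_col[i]],
                   beta = path[, s_col[i]])
    }
  }

  beta <- best$beta
  names(beta) <- colnames(X)
  sel <- beta != 0
  res <- y - X %*% beta
  structure(list(selected = colnames(X)[sel], betas = beta[sel],
                 beta_full = beta,
                 residual_variance = sum(res^2) / (n - 1),
                 model_score = best$err, xi = best$xi, s = best$s,
                 lambda = best$lambda, method = "men"),
            class = "grn_regfit")
}

# The empty model: no predictors selected, residual variance = var(y).
empty_regfit <- function(predictors, n, y, method) {
  beta <- stats::setNames(numeric(length(predictors)), predictors)
  structure(list(selected = character(0), betas = numeric(0),
                 beta_full = beta,
                 residual_variance = sum((y - mean(y))^2) / max(n - 1, 1),
                 model_score = NA_real_, method = method),
            class = "grn_regfit")
}

#' @export
print.grn_regfit <- function(x, ...) {
  cat("grn_regfit (", x$method, "): ", length(x$selected),
      " predictor(s) selected", sep = "")
  if (length(x$selected))
    cat(": ", paste(x$selected, collapse = ", "), sep = "")
  cat("\n  residual variance ", signif(x$residual_variance, 4), "\n",
      sep = "")
  invisible(x)
}
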