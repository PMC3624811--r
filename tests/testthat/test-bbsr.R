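test_that("the g-prior posterior interpolates between beta0 and OLS", {
  set.seed(2)
  n <- 30
  X <- matrix(rnorm(n * 3), n, 3)
  colnames(X) <- paste0("T", 1:3)
  y <- drop(X %*% c(1, -0.5, 0.25) + rnorm(n, 0, 0.3))
  ols <- qr.coef(qr(X), y)

  # scalar algebra: g = 1 halves the OLS solution
  p1 <- g_posterior(X[, 1, drop = FALSE], y, g = 1)
  expect_equal(p1$beta_tilde, p1$beta_hat / 2)

  # large g: OLS limit, scale -> SSR/2
  pb <- g_posterior(X, y, g = 1e12)
  expect_equal(unname(pb$beta_tilde), unname(ols), tolerance = 1e-8)
  expect_equal(pb$scale, pb$ssr / 2, tolerance = 1e-6)
  pinf <- g_posterior(X, y, g = Inf)
  expect_equal(unname(pinf$beta_tilde), unname(ols))
  expect_identical(pinf$scale, pinf$ssr / 2)

  # tiny g: prior-mean limit, scale -> total sum of squares / 2
  ps <- g_posterior(X, y, g = 1e-12)
  expect_lt(max(abs(ps$beta_tilde)), 1e-8)
  expect_equal(ps$scale, sum(y^2) / 2, tolerance = 1e-6)

  expect_error(g_posterior(X, y, g = -1), "positive")
  expect_error(g_posterior(X[1:3, ], y[1:3], g = 1), "n > k")
})

test_that("expected sigma^2 is the Inverse-Gamma mean", {
  expect_equal(expected_sigma2(3, 4), 2)
  expect_equal(expected_sigma2(2, 0), 0)
  expect_warning(m <- expected_sigma2(0.5, 3), "mode")
  expect_equal(m, 2)

  # Monte-Carlo oracle: 1/Gamma(shape, rate = 1/scale) draws
  set.seed(99)
  draws <- 1 / rgamma(1e6, shape = 4, rate = 3)
  expect_equal(expected_sigma2(4, 3), mean(draws), tolerance = 0.01)
})

test_that("BIC scores penalize size and reward fit", {
  expect_equal(bic_score(1, 10, 0), 0)
  expect_equal(bic_score(0.5, 20, 2), 20 * log(0.5) + 2 * log(20))
  expect_equal(bic_score(0.7, 25, 3) - bic_score(0.7, 25, 2), log(25))
  expect_identical(bic_score(0, 10, 1), -Inf)
  expect_error(bic_score(-1, 10, 1), "non-negative")
})

test_that("best subset matches the brute-force oracle on random problems", {
  set.seed(123)
  for (rep in 1:20) {
    n <- sample(15:40, 1)
    p <- sample(2:6, 1)
    X <- scale(matrix(rnorm(n * p), n, p))
    colnames(X) <- paste0("T", seq_len(p))
    k_true <- sample.int(p, 1)
    beta <- numeric(p)
    beta[sample.int(p, k_true)] <- runif(k_true, -2, 2)
    y <- drop(scale(X %*% beta + rnorm(n, 0, 0.7)))
    g <- sample(c(1, 1.26, 4), 1)
    fit <- best_subset(y, X, g)
    oracle <- brute_force_best_subset(y, X, g)
    expect_setequal(fit$selected, colnames(X)[oracle$subset])
  }
})

test_that("exact relations and pure noise select the right subsets", {
  set.seed(31)
  n <- 40
  X <- scale(matrix(rnorm(n * 2), n, 2))
  colnames(X) <- c("x1", "x2")
  y <- 2 * X[, 1]
  fit <- best_subset(y, X, 1)
  expect_identical(fit$selected, "x1")
  # two candidates -> exactly 4 models scored
  expect_equal(fit$n_scored, 4)

  empty <- vapply(1:100, function(s) {
    set.seed(5000 + s)
    Xn <- scale(matrix(rnorm(50 * 4), 50, 4))
    colnames(Xn) <- paste0("T", 1:4)
    yn <- drop(scale(rnorm(50)))
    length(best_subset(yn, Xn, 1)$selected) == 0
  }, logical(1))
  expect_gte(mean(empty), 0.9)
})

test_that("initial filtration caps candidates but never drops priors", {
  set.seed(17)
  n <- 40
  p <- 15
  X <- scale(matrix(rnorm(n * p), n, p))
  colnames(X) <- sprintf("T%02d", seq_len(p))
  y <- drop(scale(X[, 1] + 0.8 * X[, 2] + rnorm(n, 0, 0.4)))

  # two priors chosen to be pure-noise predictors (worst marginal fit is
  # irrelevant: priors are always retained)
  prior <- numeric(p)
  prior[c(14, 15)] <- 1
  keep <- initial_filtration(y, X, prior, g = 1, limit = 10)
  expect_length(keep, 10)
  expect_true(all(c("T14", "T15") %in% keep))
  expect_true(all(c("T01", "T02") %in% keep))

  # at or under the limit: unchanged
  expect_identical(initial_filtration(y, X[, 1:10], numeric(10), 1, 10),
                   colnames(X)[1:10])

  # more priors than the limit: the best-fitting priors win
  prior_all <- rep(1, p)
  keep2 <- initial_filtration(y, X, prior_all, g = 1, limit = 10)
  expect_length(keep2, 10)
  expect_true(all(c("T01", "T02") %in% keep2))
})

test_that("with equal g the prior matrix has no influence", {
  sim <- standard_sim(seed = 6)
  f0 <- grn_infer(sim$dataset, priors = NULL, weight = 1, g_no_prior = 1,
                  half_life = 0.75, n_boot = 3, seed = 9)
  f1 <- grn_infer(sim$dataset, priors = sim$gold, weight = 1,
                  g_no_prior = 1, half_life = 0.75, n_boot = 3, seed = 9)
  expect_equal(f0$network, f1$network)
})

test_that("AUPR rises with the prior weight when priors are the truth", {
  gs <- c(1, 16, 1e6)
  med <- sapply(gs, function(g) {
    median(sapply(1:3, function(s) {
      sim <- standard_sim(seed = s)
      fit <- grn_infer(sim$dataset, priors = sim$gold, weight = g,
                       half_life = 0.75, n_boot = 10, seed = s + 40)
      aupr(fit, sim$gold)$aupr
    }))
  })
  expect_true(all(diff(med) > -0.02))  # non-decreasing up to MC noise
  expect_gt(med[3], med[1])
})
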