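# Shared fixtures, built in code.

# Tiny hand-made dataset: 3 genes, one 2-step time series plus two steady
# states (K = 2 lagged pairs is 1 response row; L = 2).
tiny_dataset <- function() {
  values <- matrix(c(1.0, 2.0, 3.0,
                     1.5, 2.5, 2.0,
                     0.5, 1.0, 4.0,
                     0.7, 1.2, 3.5),
                   nrow = 3,
                   dimnames = list(c("gA", "gB", "gC"),
                                   c("t1", "t2", "s1", "s2")))
  meta <- data.frame(
    condition = c("t1", "t2", "s1", "s2"),
    is_time_series = c(1, 1, 0, 0),
    is_first = c(1, 0, 0, 0),
    prev_condition = c(NA, "t1", NA, NA),
    delta_t = c(NA, 2, NA, NA),
    stringsAsFactors = FALSE)
  grn_dataset(values, meta, c("gA", "gB"))
}

# Standard simulated benchmark used across tests: identifiable two-tier
# topology plus an information-rich condition set.
benchmark_sim <- function(seed = 1, ...) {
  net <- random_network(seed = seed, tf_targets = "non_tf")
  simulate_dataset(net, seed = seed, n_series = 10, n_steady = 80, ...)
}

# The default-condition dataset (general topology, 5 x 6 series + 20
# steady states, noise 0.1).
standard_sim <- function(seed = 1, ...) {
  net <- random_network(seed = seed)
  simulate_dataset(net, seed = seed, ...)
}

# Wrap a design/response pair in a minimal grn_design object.
make_design <- function(X, Y) {
  structure(list(design = X, response = Y,
                 alpha = stats::setNames(rep(1, ncol(Y)), colnames(Y)),
                 condition_index = data.frame(
                   condition = paste0("c", seq_len(nrow(X))),
                   type = "steady_state", stringsAsFactors = FALSE),
                 dropped = character(0), scaled = TRUE,
                 degenerate_genes = character(0),
                 gene_ids = colnames(Y), tf_ids = colnames(X)),
            class = "grn_design")
}

# Independent brute-force best-subset oracle: scores every subset with
# lm.fit plus direct formula evaluation (no shared code with the package
# implementation).
brute_force_best_subset <- function(y, X, g) {
  n <- nrow(X)
  p <- ncol(X)
  g <- rep_len(g, p)
  best <- list(bic = Inf, subset = integer(0))
  subsets <- list(integer(0))
  for (k in seq_len(p))
    subsets <- c(subsets,
                 utils::combn(p, k, simplify = FALSE))
  for (sub in subsets) {
    k <- length(sub)
    if (n <= k + 1) next
    if (k == 0) {
      ssr <- sum(y^2)
      pen <- 0
    } else {
      Xm <- X[, sub, drop = FALSE]
      if (qr(Xm)$rank < k) next
      fit <- stats::lm.fit(Xm, y)
      ssr <- sum(fit$residuals^2)
      bh <- fit$coefficients
      W <- diag(sqrt(1 / (g[sub] + 1)), k) %*% crossprod(Xm) %*%
        diag(sqrt(1 / (g[sub] + 1)), k)
      pen <- drop(t(bh) %*% W %*% bh)
    }
    scl <- (ssr + pen) / 2
    s2 <- scl / (n / 2 - 1)
    bic <- if (s2 <= 1e-9 * (sum(y^2) / (n - 1))) -Inf
           else n * log(s2) + k * log(n)
    if (bic < best$bic) best <- list(bic = bic, subset = sub)
  }
  best
}
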