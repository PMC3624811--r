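#' Random sparse regulatory network
#'
#' Draws a ground-truth network for simulation studies: the first
#' `n_tfs` genes are regulators, each receiving `edges_per_tf` targets
#' drawn uniformly without replacement (never itself). Effect sizes have
#' magnitude uniform on `[0.5, 2] * beta_scale` with random sign. The
#' implied linear system `dx/dt = (B - diag(alpha)) x + basal` must be
#' stable (every eigenvalue of `B - diag(alpha)` with real part below
#' `-stability_margin`); unstable topologies are rejected and redrawn,
#' which preserves the effect-size distribution, with a global shrink of
#' the interaction matrix as a last resort.
#'
#' @param n_genes,n_tfs Numbers of genes and regulators
#'   (`n_tfs <= n_genes`).
#' @param edges_per_tf Out-degree of every regulator.
#' @param beta_scale Multiplier on effect magnitudes.
#' @param half_life mRNA half-life defining the degradation rates
#'   (default 0.75 time units; bacterial-scale mRNA turnover relative to
#'   the sampling interval).
#' @param seed Seed; the same seed reproduces the network exactly.
#' @param stability_margin Required distance of the spectral abscissa
#'   from zero.
#' @param tf_targets `"all"` (default) draws targets uniformly from all
#'   genes, so regulator-regulator edges occur; `"non_tf"` restricts
#'   targets to non-regulator genes, giving a two-tier topology whose
#'   regulator profiles carry no feedback. The two-tier form makes
#'   parameter recovery well posed (steady-state data from coupled
#'   regulators admits exact anti-causal representations that no
#'   model-selection criterion can distinguish from the causal one) and
#'   is used by the recovery and weight-limit experiments.
#' @return An object of class `grn_network`: `adjacency` (signed
#'   TF x gene effect matrix), `alpha` (per-gene degradation rates),
#'   `gene_ids`, `tf_ids`.
#' @export
random_network <- function(n_genes = 20, n_tfs = 10, edges_per_tf = 2,
                           beta_scale = 1, half_life = 0.75, seed = 1,
                           stability_margin = 0.3,
                           tf_targets = c("all", "non_tf")) {
  stopifnot(n_tfs <= n_genes, n_tfs >= 1, edges_per_tf >= 1)
  tf_targets <- match.arg(tf_targets)
  genes <- sprintf("G%02d", seq_len(n_genes))
  tfs <- genes[seq_len(n_tfs)]
  target_pool <- if (tf_targets == "non_tf") setdiff(genes, tfs)
                 else genes
  n_possible <- length(setdiff(target_pool, tfs[1]))
  if (edges_per_tf > n_possible)
    stop("edges_per_tf exceeds the number of possible targets",
         call. = FALSE)
  set.seed(seed)
  alpha <- stats::setNames(rep(degradation_rate(half_life), n_genes),
                           genes)
  abscissa <- function(adj) {
    B <- system_matrix(adj, genes)
    max(Re(eigen(B - diag(alpha), only.values = TRUE)$values))
  }
  draw <- function() {
    adj <- matrix(0, n_tfs, n_genes, dimnames = list(tfs, genes))
    for (tf in tfs) {
      targets <- sample(setdiff(target_pool, tf), edges_per_tf)
      beta <- stats::runif(edges_per_tf, 0.5, 2) * beta_scale *
        sample(c(-1, 1), edges_per_tf, replace = TRUE)
      adj[tf, targets] <- beta
    }
    adj
  }
  # rejection sampling keeps the stated effect-size distribution intact;
  # a global rescale (which shrinks every beta) is the last resort
  adjacency <- draw()
  tries <- 1L
  while (abscissa(adjacency) > -stability_margin && tries < 50L) {
    adjacency <- draw()
    tries <- tries + 1L
  }
  while (abscissa(adjacency) > -stability_margin)
    adjacency <- adjacency * 0.85

  structure(list(adjacency = adjacency, alpha = alpha,
                 gene_ids = genes, tf_ids = tfs,
                 edges_per_tf = edges_per_tf, seed = seed),
            class = "grn_network")
}

# Embed the TF x gene effect matrix into the full N x N system matrix
# B[i, j] = effect of gene j on gene i (nonzero only for TF columns).
system_matrix <- function(adjacency, genes) {
  B <- matrix(0, length(genes), length(genes),
              dimnames = list(genes, genes))
  B[colnames(adjacency), rownames(adjacency)] <-
    t(adjacency)[colnames(adjacency), rownames(adjacency)]
  B
}

#' @export
print.grn_network <- function(x, ...) {
  cat("grn_network: ", length(x$gene_ids), " genes, ",
      length(x$tf_ids), " TFs, ", sum(x$adjacency != 0),
      " edges\n", sep = "")
  invisible(x)
}

#' Gold standard of a simulated network
#'
#' @param network A [random_network()].
#' @return TF x gene 0/1 matrix of the true edges (sign retained in the
#'   `"sign"` attribute).
#' @export
gold_standard <- function(network) {
  stopifnot(inherits(network, "grn_network"))
  finish_edge_matrix(sign(network$adjacency))
}

#' Simulate expression data from a ground-truth network
#'
#' Generates time-series and steady-state observations from the linear
#' kinetics the inference model assumes,
#' `dx_i/dt = -alpha_i x_i + sum_j beta_ij x_j + basal_i`. Basal rates
#' are set so that a positive baseline state (uniform on
#' `baseline_range`) is the unperturbed fixed point. Each time series
#' starts from a globally perturbed initial state (Gaussian, sd
#' `ts_perturb_sd`) and is integrated with a classical fixed-step
#' fourth-order scheme at step `delta_t / 10`, sampled every `delta_t`;
#' levels are floored at 0. Each steady-state condition applies strong
#' basal-synthesis shifts (Gaussian, sd `ss_perturb_sd`) to
#' `ss_n_perturb` randomly chosen regulators — emulating targeted
#' knockdown/over-expression-style perturbations of regulator activity —
#' and solves the linear fixed point. I.i.d. Gaussian measurement noise
#' with sd `noise_sd` is added to all observations. With
#' `saturation = TRUE` the regulatory input passes through a mild tanh
#' nonlinearity (robustness checks only).
#'
#' @param network A [random_network()].
#' @param n_series,series_length Number of time series and observations
#'   per series (the first point of each series never contributes a
#'   response row).
#' @param delta_t Sampling interval (time units; default 0.5, about half
#'   the relaxation time of the default kinetics, so series resolve the
#'   transient).
#' @param n_steady Number of steady-state conditions.
#' @param noise_sd Measurement noise standard deviation.
#' @param seed Seed for perturbations and noise.
#' @param ts_perturb_sd,ss_perturb_sd Perturbation scales (see above).
#' @param ss_n_perturb Number of regulators perturbed per steady-state
#'   condition; `NULL` perturbs all of them (dense, milder
#'   environmental-shift mode).
#' @param baseline_range Range of the unperturbed expression baseline
#'   (log2-intensity-like units; high enough that the positivity floor
#'   is rarely touched).
#' @param saturation Add mild sigmoidal saturation to regulation.
#' @return List with `dataset` (a [grn_dataset()]), `gold` (the
#'   [gold_standard()]) and `network`.
#' @export
simulate_dataset <- function(network, n_series = 5, series_length = 6,
                             delta_t = 0.5, n_steady = 20,
                             noise_sd = 0.1, seed = 1,
                             ts_perturb_sd = 0.75, ss_perturb_sd = 1,
                             ss_n_perturb = 3,
                             baseline_range = c(5, 7),
                             saturation = FALSE) {
  stopifnot(inherits(network, "grn_network"), delta_t > 0,
            n_series >= 0, n_steady >= 0, noise_sd >= 0)
  genes <- network$gene_ids
  tfs <- network$tf_ids
  n <- length(genes)
  alpha <- network$alpha
  B <- system_matrix(network$adjacency, genes)
  A <- B - diag(alpha)
  if (max(Re(eigen(A, only.values = TRUE)$values)) >= 0)
    stop("network is not stable; regenerate with random_network()",
         call. = FALSE)

  set.seed(seed)
  xbar <- stats::runif(n, baseline_range[1], baseline_range[2])
  basal <- drop((diag(alpha) - B) %*% xbar)

  reg_input <- function(x) {
    u <- drop(B %*% x)
    if (saturation) 2 * tanh(u / 2) else u
  }
  deriv <- function(x, b = basal) -alpha * x + reg_input(x) + b

  rk4_step <- function(x, h, b = basal) {
    k1 <- deriv(x, b)
    k2 <- deriv(x + h / 2 * k1, b)
    k3 <- deriv(x + h / 2 * k2, b)
    k4 <- deriv(x + h * k3, b)
    pmax(x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4), 0)
  }

  cond_ids <- character(0)
  values <- matrix(numeric(0), nrow = n)
  meta <- list()

  for (s in seq_len(n_series)) {
    x <- pmax(xbar + stats::rnorm(n, 0, ts_perturb_sd), 0)
    for (k in seq_len(series_length)) {
      id <- sprintf("ts%02d_t%02d", s, k)
      cond_ids <- c(cond_ids, id)
      values <- cbind(values, x)
      meta[[id]] <- data.frame(
        condition = id, is_time_series = 1L,
        is_first = as.integer(k == 1),
        prev_condition = if (k == 1) NA_character_ else
          sprintf("ts%02d_t%02d", s, k - 1),
        delta_t = if (k == 1) NA_real_ else delta_t,
        stringsAsFactors = FALSE)
      if (k < series_length)
        for (sub in seq_len(10)) x <- rk4_step(x, delta_t / 10)
    }
  }

  M <- diag(alpha) - B
  for (c in seq_len(n_steady)) {
    db <- numeric(n)
    if (is.null(ss_n_perturb) || ss_n_perturb >= length(tfs)) {
      db[match(tfs, genes)] <- stats::rnorm(length(tfs), 0,
                                            ss_perturb_sd)
    } else {
      # targeted perturbation: a few regulators get strong shifts
      hit <- sample(match(tfs, genes), ss_n_perturb)
      db[hit] <- stats::rnorm(ss_n_perturb, 0, ss_perturb_sd)
    }
    if (saturation) {
      # nonlinear fixed point by relaxation
      x <- xbar
      h <- 0.2 / max(alpha)
      for (it in seq_len(5000)) {
        x_new <- rk4_step(x, h, basal + db)
        if (max(abs(x_new - x)) < 1e-12) { x <- x_new; break }
        x <- x_new
      }
    } else {
      x <- drop(solve(M, basal + db))
    }
    id <- sprintf("ss%02d", c)
    cond_ids <- c(cond_ids, id)
    values <- cbind(values, x)
    meta[[id]] <- data.frame(
      condition = id, is_time_series = 0L, is_first = 0L,
      prev_condition = NA_character_, delta_t = NA_real_,
      stringsAsFactors = FALSE)
  }

  if (noise_sd > 0)
    values <- values + stats::rnorm(length(values), 0, noise_sd)
  values <- pmax(values, 0)
  dimnames(values) <- list(genes, cond_ids)

  dataset <- grn_dataset(values, do.call(rbind, meta), tfs)
  list(dataset = dataset, gold = gold_standard(network),
       network = network)
}
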