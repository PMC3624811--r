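#' Infer a regulatory network from expression data and structure priors
#'
#' The main fitting function. Expression data are transformed into
#' time-lagged design/response variables under the first-order ODE model
#' ([design_response()]); for each bootstrap resample of the rows, each
#' gene's candidate regulators are restricted by time-lagged CLR scoring
#' plus all prior predictors ([candidate_regulators()]), a sparse
#' regression model is selected by the chosen engine (modified elastic
#' net, [men_fit()], or Bayesian best subset regression, [bbsr_fit()]),
#' and per-edge confidence scores are computed from the variance each
#' selected predictor explains ([confidence_scores()]). The per-bootstrap
#' score matrices are rank-combined ([rank_combine()]) into the final
#' confidence-ranked edge list.
#'
#' @param dataset A [grn_dataset()].
#' @param priors TF x gene 0/1 prior matrix (see [read_edge_matrix()]),
#'   or `NULL` for no priors.
#' @param method `"bbsr"` (default) or `"men"`.
#' @param weight Prior weight: for BBSR the g value given to prior
#'   predictors, for MEN the theta shrinkage modifier. Accepts a number
#'   or the presets `"low"` (g = 1.26 / theta = 0.5, the default) and
#'   `"high"` (g = 2.8 / theta = 0.01). `Inf` (BBSR only) uses the
#'   analytic infinite-weight limit.
#' @param g_no_prior BBSR weight for predictors without priors
#'   (default 1, "no priors" behaviour).
#' @param half_life mRNA half-life passed to [design_response()].
#' @param n_boot Number of bootstrap resamples (default 20).
#' @param seed Run seed; every source of randomness (resampling, CV
#'   folds) derives from it.
#' @param max_k Number of top-scoring candidate regulators kept per gene
#'   in addition to all prior regulators (default 10).
#' @param resample If `FALSE`, every "bootstrap" uses the original rows
#'   (no-resample mode, useful for deterministic single fits).
#' @param control A [men_control()] list (MEN only).
#' @param verbose Print per-bootstrap progress.
#' @return An object of class `grn_fit`; see [print.grn_fit()],
#'   [summary.grn_fit()], [coef.grn_fit()], [predict.grn_fit()],
#'   [plot.grn_fit()] and the `network` element, a data frame with
#'   columns `tf`, `gene`, `combined_score`, `mean_rank`, `sign` sorted
#'   by descending confidence.
#' @export
grn_infer <- function(dataset, priors = NULL,
                      method = c("bbsr", "men"), weight = "low",
                      g_no_prior = 1, half_life = 10, n_boot = 20,
                      seed = 1, max_k = 10, resample = TRUE,
                      control = men_control(), verbose = FALSE) {
  stopifnot(inherits(dataset, "grn_dataset"))
  method <- match.arg(method)
  weight <- resolve_weight(weight, method)
  if (is.null(priors)) priors <- empty_edge_matrix(dataset)
  stopifnot(n_boot >= 1)

  dr_raw <- design_response(dataset, half_life = half_life, scale = FALSE)
  n_rows <- nrow(dr_raw$design)

  set.seed(seed)
  boot_seeds <- sample.int(.Machine$integer.max - 1, n_boot)

  s_list <- vector("list", n_boot)
  sel_count <- NULL
  for (b in seq_len(n_boot)) {
    set.seed(boot_seeds[b])
    idx <- if (resample) sample.int(n_rows, n_rows, replace = TRUE)
           else seq_len(n_rows)
    run <- single_run(dr_raw, idx, priors, method, weight,
                      g_no_prior, max_k, control,
                      fit_seed = boot_seeds[b])
    s_list[[b]] <- run$scores
    sel_count <- if (is.null(sel_count)) run$selected + 0
                 else sel_count + run$selected
    if (verbose)
      message("bootstrap ", b, "/", n_boot, ": ",
              sum(s_list[[b]] > 0), " edges with support")
  }

  full <- single_run(dr_raw, seq_len(n_rows), priors, method, weight,
                     g_no_prior, max_k, control, fit_seed = seed)
  combined <- rank_combine(s_list)
  sign_mat <- sign(full$beta)
  combined$network$sign <- sign_mat[cbind(combined$network$tf,
                                          combined$network$gene)]

  structure(list(network = combined$network,
                 mean_rank = combined$mean_rank,
                 s_matrices = s_list,
                 selection_count = sel_count,
                 coefficients = full$beta,
                 full_scores = full$scores,
                 full_fits = full$fits,
                 design = full$dr,
                 dataset = dataset, priors = priors,
                 method = method, weight = weight,
                 g_no_prior = g_no_prior, half_life = half_life,
                 n_boot = n_boot, seed = seed, resample = resample,
                 call = match.call()),
            class = "grn_fit")
}

resolve_weight <- function(weight, method) {
  if (is.character(weight)) {
    presets <- list(bbsr = c(low = 1.26, high = 2.8),
                    men = c(low = 0.5, high = 0.01))
    w <- presets[[method]][match.arg(weight, c("low", "high"))]
    return(unname(w))
  }
  stopifnot(is.numeric(weight), length(weight) == 1, weight > 0)
  if (method == "men" && weight > 1)
    stop("MEN's theta must lie in (0, 1]", call. = FALSE)
  weight
}

# One full model-selection pass (filter -> fit -> score) on a row
# resample of the raw design/response.
single_run <- function(dr_raw, idx, priors, method, weight, g_no_prior,
                       max_k, control, fit_seed) {
  all_tfs <- colnames(dr_raw$design)
  dr <- suppressWarnings(scale_design_response(resample_rows(dr_raw,
                                                             idx)))
  scores <- tlclr_scores(dr)
  genes <- dr$gene_ids
  tfs <- colnames(dr$design)  # zero-variance columns may have dropped
  fits <- vector("list", length(genes))
  names(fits) <- genes
  beta <- matrix(0, length(all_tfs), length(genes),
                 dimnames = list(all_tfs, genes))
  for (gi in seq_along(genes)) {
    gene <- genes[gi]
    if (gene %in% dr$degenerate_genes) {
      fits[[gi]] <- empty_regfit(character(0), nrow(dr$design),
                                 dr$response[, gene], method)
      next
    }
    cand <- candidate_regulators(scores, priors, gene, max_k)
    cand <- intersect(cand, tfs)
    if (!length(cand)) {
      fits[[gi]] <- empty_regfit(character(0), nrow(dr$design),
                                 dr$response[, gene], method)
      next
    }
    y <- dr$response[, gene]
    X <- dr$design[, cand, drop = FALSE]
    pr <- priors[cand, gene]
    fit <- if (method == "bbsr") {
      bbsr_fit(y, X, prior = pr, g_prior = weight,
               g_no_prior = g_no_prior, limit = max_k)
    } else {
      men_fit(y, X, prior = pr, control = men_control(
        xi_grid = control$xi_grid, s_grid = control$s_grid,
        theta_prior = weight, cv_folds = control$cv_folds,
        n_lambda = control$n_lambda,
        lambda_min_ratio = control$lambda_min_ratio,
        tol = control$tol, max_sweeps = control$max_sweeps),
        seed = fit_seed)
    }
    fits[[gi]] <- fit
    if (length(fit$selected)) beta[fit$selected, gene] <- fit$betas
  }
  S <- matrix(0, length(all_tfs), length(genes),
              dimnames = list(all_tfs, genes))
  S[tfs, ] <- confidence_scores(fits, dr)
  list(scores = S, fits = fits, beta = beta,
       selected = beta != 0, dr = dr)
}

#' Per-edge confidence from explained variance
#'
#' For every predictor j selected for gene i, the model is refit by OLS
#' on its support with and without j, and the confidence is the drop in
#' residual variance: `S_ij = 1 - sigma2_full / sigma2_without_j`,
#' clipped to `[0, 1]`. Non-selected edges score 0, as do edges where
#' both variances vanish (no evidence either way). The score reflects
#' both the model's overall performance and the share of variance the
#' predictor explains.
#'
#' @param fits Named list of `grn_regfit` objects (one per gene).
#' @param dr The scaled `grn_design` the fits were computed on.
#' @return TF x gene confidence matrix.
#' @export
confidence_scores <- function(fits, dr) {
  tfs <- colnames(dr$design)
  genes <- dr$gene_ids
  S <- matrix(0, length(tfs), length(genes),
              dimnames = list(tfs, genes))
  n <- nrow(dr$design)
  for (gene in genes) {
    fit <- fits[[gene]]
    sel <- intersect(fit$selected, tfs)
    if (!length(sel)) next
    y <- dr$response[, gene]
    s2_full <- refit_variance(y, dr$design[, sel, drop = FALSE], n)
    for (j in sel) {
      rest <- setdiff(sel, j)
      s2_red <- refit_variance(y, dr$design[, rest, drop = FALSE], n)
      if (s2_red <= 0) next  # no evidence either way
      S[j, gene] <- min(max(1 - s2_full / s2_red, 0), 1)
    }
  }
  S
}

refit_variance <- function(y, X, n) {
  if (ncol(X) == 0) return(sum((y - mean(y))^2) / (n - 1))
  beta <- qr.coef(qr(X), y)
  beta[is.na(beta)] <- 0
  sum((y - X %*% beta)^2) / (n - 1)
}

#' Rank-combine bootstrap confidence matrices
#'
#' Within each bootstrap the edges (all TF x gene pairs, self excluded)
#' are ranked by descending confidence with ties given their average
#' rank; the final score of an edge is its mean rank across bootstraps
#' (lower = more confident). The combination is invariant to the order of
#' the bootstrap list.
#'
#' @param s_list List of TF x gene confidence matrices on common axes.
#' @return List with `network` (data frame `tf`, `gene`,
#'   `combined_score`, `mean_rank`, best first) and `mean_rank` (matrix).
#' @export
rank_combine <- function(s_list) {
  stopifnot(length(s_list) >= 1)
  tfs <- rownames(s_list[[1]])
  genes <- colnames(s_list[[1]])
  for (s in s_list)
    if (!identical(dimnames(s), list(tfs, genes)))
      stop("confidence matrices have mismatched axes", call. = FALSE)
  pairs <- expand.grid(tf = tfs, gene = genes, stringsAsFactors = FALSE,
                       KEEP.OUT.ATTRS = FALSE)
  keep <- pairs$tf != pairs$gene
  pairs <- pairs[keep, , drop = FALSE]
  ij <- cbind(match(pairs$tf, tfs), match(pairs$gene, genes))
  rank_sum <- numeric(nrow(pairs))
  for (s in s_list)
    rank_sum <- rank_sum + rank(-s[ij], ties.method = "average")
  mean_rank <- rank_sum / length(s_list)
  m <- nrow(pairs)
  net <- data.frame(tf = pairs$tf, gene = pairs$gene,
                    combined_score = (m - mean_rank + 1) / m,
                    mean_rank = mean_rank, stringsAsFactors = FALSE)
  net <- net[order(net$mean_rank, net$tf, net$gene), , drop = FALSE]
  rownames(net) <- NULL
  mr <- matrix(NA_real_, length(tfs), length(genes),
               dimnames = list(tfs, genes))
  mr[ij] <- mean_rank
  list(network = net, mean_rank = mr)
}

#' Write a ranked network to TSV
#'
#' Emits the edge list of a fitted model (`tf`, `gene`,
#' `combined_score`, `mean_rank`, `sign`), best edge first.
#'
#' @param fit A `grn_fit` object.
#' @param path Output path.
#' @return Invisibly, the network data frame.
#' @export
write_network <- function(fit, path) {
  stopifnot(inherits(fit, "grn_fit"))
  utils::write.table(fit$network, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(fit$network)
}
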