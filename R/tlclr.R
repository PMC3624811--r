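#' Time-lagged CLR relevance scores
#'
#' Scores every (regulator, target) pair by the mutual information
#' between the time-lagged design column of the regulator and the target's
#' response, under a Gaussian approximation:
#' `r = -1/2 * log(1 - rho^2)` with `rho` the Pearson correlation. Raw
#' relevances are background-corrected as in CLR: each entry is z-scored
#' against the distribution of relevances involving the same target and
#' against the distribution involving the same regulator, negative
#' z-scores are floored at zero, and the two are combined as
#' `z = sqrt(z_target^2 + z_regulator^2)`. Self-pairs are excluded (`NA`).
#'
#' @param dr A `grn_design` object from [design_response()].
#' @return An object of class `grn_scores`: list with `z` (TF x gene CLR
#'   scores), `rho` (time-lagged correlations) and `relevance`.
#' @export
tlclr_scores <- function(dr) {
  stopifnot(inherits(dr, "grn_design"))
  rho <- suppressWarnings(stats::cor(dr$design, dr$response))
  rho[is.na(rho)] <- 0  # constant design column or response: no signal
  shared <- intersect(rownames(rho), colnames(rho))
  rho[cbind(shared, shared)] <- NA  # never score self-regulation
  rho2 <- pmin(rho^2, 1 - 1e-12)
  rel <- -0.5 * log(1 - rho2)

  zscore <- function(m, margin) {
    mu <- apply(m, margin, mean, na.rm = TRUE)
    sd <- apply(m, margin, stats::sd, na.rm = TRUE)
    sd[!is.finite(sd) | sd < 1e-300] <- Inf  # flat background: z = 0
    z <- sweep(sweep(m, margin, mu), margin, sd, "/")
    z[z < 0] <- 0
    z
  }
  z_tf <- zscore(rel, 1)      # background over targets of the same TF
  z_gene <- zscore(rel, 2)    # background over TFs of the same target
  z <- sqrt(z_tf^2 + z_gene^2)

  structure(list(z = z, rho = rho, relevance = rel), class = "grn_scores")
}

#' @export
print.grn_scores <- function(x, ...) {
  cat("grn_scores: ", nrow(x$z), " TFs x ", ncol(x$z),
      " genes, tlCLR z-scores in [", 0, ", ",
      round(max(x$z, na.rm = TRUE), 2), "]\n", sep = "")
  invisible(x)
}

#' Candidate regulator set for one gene
#'
#' Restricts a gene's candidate regulators to the union of the `max_k`
#' highest-scoring predictors and all predictors with prior knowledge, so
#' prior edges are never filtered out. The gene itself is always
#' excluded. Score ties are broken by larger absolute time-lagged
#' correlation, then lexicographic TF identifier.
#'
#' @param scores A `grn_scores` object from [tlclr_scores()].
#' @param priors TF x gene 0/1 prior matrix (or `NULL` for no priors).
#' @param gene Target gene identifier.
#' @param max_k Number of top-scoring predictors kept (default 10).
#' @return Character vector of candidate TF identifiers.
#' @export
candidate_regulators <- function(scores, priors, gene, max_k = 10) {
  stopifnot(inherits(scores, "grn_scores"))
  tfs <- setdiff(rownames(scores$z), gene)
  if (!length(tfs)) return(character(0))
  z <- scores$z[tfs, gene]
  rho <- abs(scores$rho[tfs, gene])
  ord <- tfs[order(-z, -rho, tfs)]
  top <- ord[seq_len(min(max_k, length(ord)))]
  prior_tfs <- character(0)
  if (!is.null(priors)) {
    pr <- priors[, gene]
    prior_tfs <- intersect(rownames(priors)[pr != 0], tfs)
  }
  union(top, prior_tfs)
}
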