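#' @export
print.grn_fit <- function(x, ...) {
  cat("Regulatory network fit (", toupper(x$method), ")\n", sep = "")
  cat("  ", length(x$dataset$gene_ids), " genes, ",
      length(x$dataset$tf_ids), " candidate TFs, ",
      nrow(x$design$design), " design rows\n", sep = "")
  cat("  prior edges: ", sum(x$priors != 0), ", prior weight ",
      format(x$weight), "\n", sep = "")
  cat("  bootstraps: ", x$n_boot,
      if (!x$resample) " (no resampling)", "\n", sep = "")
  cat("  edges with bootstrap support: ",
      sum(x$selection_count > 0), " of ", nrow(x$network), "\n", sep = "")
  invisible(x)
}

#' Summarize a fitted regulatory network
#'
#' @param object A `grn_fit`.
#' @param n_top Number of top edges to tabulate (default 10).
#' @param ... Unused.
#' @return A `summary.grn_fit` list with the top edges, per-gene selected
#'   model sizes and run settings.
#' @export
summary.grn_fit <- function(object, n_top = 10, ...) {
  sizes <- vapply(object$full_fits, function(f) length(f$selected),
                  integer(1))
  structure(list(top = utils::head(object$network, n_top),
                 model_sizes = sizes,
                 n_supported = sum(object$selection_count > 0),
                 n_edges = nrow(object$network),
                 method = object$method, weight = object$weight,
                 n_boot = object$n_boot), class = "summary.grn_fit")
}

#' @export
print.summary.grn_fit <- function(x, ...) {
  cat("Method ", toupper(x$method), ", prior weight ", format(x$weight),
      ", ", x$n_boot, " bootstraps\n", sep = "")
  cat("Edges with bootstrap support: ", x$n_supported, " of ",
      x$n_edges, "\n", sep = "")
  cat("Selected predictors per gene: median ",
      stats::median(x$model_sizes), " (max ", max(x$model_sizes),
      ")\n\nTop edges:\n", sep = "")
  print(x$top)
  invisible(x)
}

#' Coefficients of the full-data fit
#'
#' @param object A `grn_fit`.
#' @param ... Unused.
#' @return TF x gene matrix of dynamical parameters (regression
#'   coefficients on the scaled design/response; zero where a predictor
#'   was not selected).
#' @export
coef.grn_fit <- function(object, ...) object$coefficients

#' Fitted response values
#'
#' @param object A `grn_fit`.
#' @param ... Unused.
#' @return Rows x genes matrix of fitted (scaled) response values from
#'   the full-data fit.
#' @export
fitted.grn_fit <- function(object, ...) {
  object$design$design %*% object$coefficients
}

#' Response residuals of the full-data fit
#'
#' @param object A `grn_fit`.
#' @param ... Unused.
#' @return Rows x genes matrix of response residuals.
#' @export
residuals.grn_fit <- function(object, ...) {
  object$design$response[, colnames(object$coefficients),
                         drop = FALSE] - fitted(object)
}

#' Predict ODE-model responses for new data
#'
#' Builds design/response variables for a new dataset (same half-life as
#' the fit) and applies the full-data coefficient matrix, returning the
#' predicted scaled response of every gene in every usable condition.
#'
#' @param object A `grn_fit`.
#' @param newdata A [grn_dataset()]; default: the training data (returns
#'   [fitted.grn_fit()]).
#' @param ... Unused.
#' @return Rows x genes matrix of predicted responses.
#' @export
predict.grn_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(fitted(object))
  stopifnot(inherits(newdata, "grn_dataset"))
  dr <- design_response(newdata, half_life = object$half_life)
  tfs <- rownames(object$coefficients)
  missing_tf <- setdiff(tfs, colnames(dr$design))
  if (length(missing_tf))
    stop("new data lacks regulators: ",
         paste(missing_tf, collapse = ", "), call. = FALSE)
  dr$design[, tfs, drop = FALSE] %*% object$coefficients
}

#' Plot a fitted network's confidence profile or precision-recall curve
#'
#' With a gold standard, draws the precision-recall curve of the ranked
#' edge list (see [aupr()]); without one, plots the sorted combined
#' confidence scores with the bootstrap-supported edges marked.
#'
#' @param x A `grn_fit`.
#' @param gold Optional TF x gene gold-standard matrix.
#' @param ... Passed to the underlying plot call.
#' @return Invisibly, the `grn_pr` result (with `gold`) or `NULL`.
#' @export
plot.grn_fit <- function(x, gold = NULL, ...) {
  if (!is.null(gold)) {
    pr <- aupr(x, gold)
    plot(pr, ...)
    return(invisible(pr))
  }
  sc <- x$network$combined_score
  supported <- x$selection_count[cbind(x$network$tf, x$network$gene)] > 0
  graphics::plot(seq_along(sc), sc, type = "l", log = "x",
                 xlab = "edge rank", ylab = "combined confidence", ...)
  graphics::points(which(supported), sc[supported], pch = 20, cex = 0.4)
  invisible(NULL)
}
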