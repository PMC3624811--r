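#' First-order degradation rate from mRNA half-life
#'
#' The core model assumes transcript decay proportional to abundance, so
#' the degradation rate is `alpha = ln(2) / half_life`.
#'
#' @param half_life Positive half-life in the time units of the dataset's
#'   `delta_t`. `Inf` yields `alpha = 0` (no degradation term).
#' @return Degradation rate(s), same length as `half_life`.
#' @export
degradation_rate <- function(half_life) {
  if (!is.numeric(half_life) || any(is.na(half_life)) ||
      any(half_life <= 0))
    stop("half_life must be positive", call. = FALSE)
  log(2) / half_life
}

#' Time-series response under the finite-difference ODE model
#'
#' For consecutive time points `t_k`, `t_{k+1}` of a series, the response
#' of gene i is `(x_i(t_{k+1}) - x_i(t_k)) / delta_t + alpha * x_i(t_k)`,
#' paired with the regulator expression at `t_k` (the design is lagged one
#' time point behind the response).
#'
#' @param x_prev,x_curr Expression at the earlier / later time point.
#' @param delta_t Positive time step between them.
#' @param alpha Degradation rate.
#' @return Response value(s).
#' @export
time_series_response <- function(x_prev, x_curr, delta_t, alpha) {
  if (any(delta_t <= 0)) stop("delta_t must be > 0", call. = FALSE)
  (x_curr - x_prev) / delta_t + alpha * x_prev
}

#' Steady-state response under the ODE model
#'
#' At steady state the derivative vanishes, leaving `alpha * x_i` as the
#' response, paired with same-condition regulator expression.
#'
#' @param x Expression at the steady-state condition.
#' @param alpha Degradation rate.
#' @return Response value(s).
#' @export
steady_state_response <- function(x, alpha) alpha * x

#' Build time-lagged design and response variables
#'
#' Transforms a dataset into the regression variables of the core ODE
#' model. Each usable observation ("row") is either a consecutive
#' time-series pair — response at `t_{k+1}` as in
#' [time_series_response()], design at `t_k` — or a steady-state condition
#' — response `alpha * x_i`, unlagged design. Time-series and steady-state
#' rows are concatenated; the first condition of every series contributes
#' a design row only. Responses (one vector per gene) and design columns
#' (one per regulator) are then centered and scaled to zero mean and unit
#' variance; zero-variance design columns are dropped with a warning and
#' recorded in `dropped`.
#'
#' @param dataset A [grn_dataset()].
#' @param half_life Global or per-gene mRNA half-life (recycled to the
#'   number of genes), converted via [degradation_rate()]. Default 10 time
#'   units.
#' @param regulators Candidate regulators to keep as design columns
#'   (default: all the dataset's TFs). A gene's own column is excluded at
#'   fit time, not here.
#' @param scale If `FALSE`, return unscaled variables (used internally by
#'   the bootstrap, which rescales after resampling rows).
#' @return An object of class `grn_design`: list with `design` (rows x
#'   regulators), `response` (rows x genes), `alpha` (per gene),
#'   `condition_index` (data frame mapping rows to source conditions and
#'   type), `dropped` (zero-variance regulators), `scaled` flag.
#' @export
design_response <- function(dataset, half_life = 10,
                            regulators = dataset$tf_ids, scale = TRUE) {
  stopifnot(inherits(dataset, "grn_dataset"))
  regulators <- as.character(regulators)
  if (!all(regulators %in% dataset$tf_ids))
    stop("regulators must be among the dataset's TFs", call. = FALSE)
  n_genes <- length(dataset$gene_ids)
  alpha <- rep_len(degradation_rate(half_life), n_genes)
  names(alpha) <- dataset$gene_ids

  meta <- dataset$meta
  vals <- dataset$values
  ts_rows <- which(meta$is_time_series & !meta$is_first)
  ss_rows <- which(!meta$is_time_series)
  n_rows <- length(ts_rows) + length(ss_rows)
  if (n_rows < 2)
    stop("fewer than 2 usable conditions", call. = FALSE)

  design <- matrix(NA_real_, n_rows, length(regulators),
                   dimnames = list(NULL, regulators))
  response <- matrix(NA_real_, n_rows, n_genes,
                     dimnames = list(NULL, dataset$gene_ids))
  cond <- character(n_rows)
  type <- character(n_rows)

  r <- 0L
  for (k in ts_rows) {
    r <- r + 1L
    prev <- meta$prev_condition[k]
    dt <- meta$delta_t[k]
    design[r, ] <- vals[regulators, prev]
    response[r, ] <- time_series_response(vals[, prev], vals[, k], dt,
                                          alpha)
    cond[r] <- meta$condition[k]
    type[r] <- "time_series"
  }
  for (k in ss_rows) {
    r <- r + 1L
    design[r, ] <- vals[regulators, meta$condition[k]]
    response[r, ] <- steady_state_response(vals[, k], alpha)
    cond[r] <- meta$condition[k]
    type[r] <- "steady_state"
  }

  out <- structure(list(design = design, response = response,
                        alpha = alpha,
                        condition_index = data.frame(
                          condition = cond, type = type,
                          stringsAsFactors = FALSE),
                        dropped = character(0), scaled = FALSE,
                        gene_ids = dataset$gene_ids,
                        tf_ids = regulators),
                   class = "grn_design")
  if (scale) out <- scale_design_response(out) else out
}

#' Center and scale design/response variables
#'
#' Gives every design column and every per-gene response vector zero mean
#' and unit variance (sample standard deviation). Zero-variance design
#' columns are dropped with a warning; zero-variance responses are left
#' centered at zero and flagged in `degenerate_genes` (such genes can only
#' receive the empty model). Scaling is idempotent.
#'
#' @param dr A `grn_design` object.
#' @return The scaled `grn_design`.
#' @export
scale_design_response <- function(dr) {
  stopifnot(inherits(dr, "grn_design"))
  d_sd <- apply(dr$design, 2, stats::sd)
  dead <- d_sd < 1e-12 * pmax(1, abs(colMeans(dr$design)))
  if (any(dead)) {
    warning("dropping zero-variance design columns: ",
            paste(colnames(dr$design)[dead], collapse = ", "),
            call. = FALSE)
    dr$dropped <- union(dr$dropped, colnames(dr$design)[dead])
    dr$design <- dr$design[, !dead, drop = FALSE]
    d_sd <- d_sd[!dead]
  }
  dr$design <- scale(dr$design)
  attr(dr$design, "scaled:center") <- NULL
  attr(dr$design, "scaled:scale") <- NULL

  r_sd <- apply(dr$response, 2, stats::sd)
  degenerate <- r_sd < 1e-12
  r_sd[degenerate] <- 1
  dr$response <- sweep(sweep(dr$response, 2, colMeans(dr$response)),
                       2, r_sd, "/")
  dr$degenerate_genes <- colnames(dr$response)[degenerate]
  dr$scaled <- TRUE
  dr
}

#' @export
print.grn_design <- function(x, ...) {
  cat("grn_design: ", nrow(x$design), " rows (",
      sum(x$condition_index$type == "time_series"), " time-lagged, ",
      sum(x$condition_index$type == "steady_state"), " steady-state), ",
      ncol(x$design), " regulator columns, ",
      if (x$scaled) "scaled" else "unscaled", "\n", sep = "")
  invisible(x)
}

# Resample design/response rows (bootstrap unit = lag-preserving row
# pair), keeping the condition index in sync. Returns an unscaled object;
# callers rescale.
resample_rows <- function(dr, idx) {
  dr$design <- dr$design[idx, , drop = FALSE]
  dr$response <- dr$response[idx, , drop = FALSE]
  dr$condition_index <- dr$condition_index[idx, , drop = FALSE]
  dr$scaled <- FALSE
  dr
}
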