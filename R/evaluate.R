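#' Area under the precision-recall curve of a ranked edge list
#'
#' Evaluation follows DREAM practice: the evaluation universe is
#' restricted to (TF, gene) pairs whose TF has at least one gold-standard
#' edge and whose gene has at least one gold-standard edge (self-pairs
#' excluded). Ranked edges outside the universe are dropped; universe
#' pairs missing from the ranking are appended after it in seeded random
#' order, so recall always reaches 1. Walking down the list,
#' `precision_k = TP_k / k` and `recall_k = TP_k / n_gold`; the area is
#' the step-wise (non-interpolated) sum
#' `sum((recall_k - recall_{k-1}) * precision_k)`. Score ties are broken
#' by a seeded permutation; with `tie_reps > 1` the AUPR is averaged over
#' several tie permutations and their standard deviation reported.
#'
#' @param x A `grn_fit`, or a data frame with columns `tf`, `gene` and a
#'   score column (higher = more confident) named by `score_col`.
#' @param gold TF x gene 0/1 gold-standard matrix.
#' @param exclude Optional TF x gene 0/1 matrix of pairs to remove from
#'   the universe entirely (used by [leave_out_aupr()]).
#' @param seed Seed for tie permutation and the appended-pair order.
#' @param tie_reps Number of tie permutations to average over.
#' @param score_col Name of the score column (default `combined_score`).
#' @return An object of class `grn_pr`: `precision`, `recall`, `aupr`,
#'   `n_gold`, `n_eval` and (if `tie_reps > 1`) `aupr_sd`.
#' @export
aupr <- function(x, gold, exclude = NULL, seed = 1, tie_reps = 1,
                 score_col = "combined_score") {
  if (inherits(x, "grn_fit")) x <- x$network
  stopifnot(is.data.frame(x), all(c("tf", "gene") %in% names(x)),
            score_col %in% names(x))
  edges <- data.frame(tf = as.character(x$tf),
                      gene = as.character(x$gene),
                      score = as.numeric(x[[score_col]]),
                      stringsAsFactors = FALSE)

  universe <- pr_universe(gold, exclude)
  if (!nrow(universe$pairs))
    stop("empty evaluation universe", call. = FALSE)
  n_gold <- sum(universe$positive)
  if (n_gold == 0)
    stop("no gold-standard edges inside the evaluation universe",
         call. = FALSE)

  key <- function(tf, gene) paste(tf, gene, sep = "\r")
  uni_key <- key(universe$pairs$tf, universe$pairs$gene)
  edges <- edges[key(edges$tf, edges$gene) %in% uni_key, , drop = FALSE]

  run_once <- function(rep_seed) {
    set.seed(rep_seed)
    tie_break <- stats::runif(nrow(edges))
    ord <- order(-edges$score, tie_break)
    ranked_key <- key(edges$tf, edges$gene)[ord]
    rest <- setdiff(uni_key, ranked_key)
    if (length(rest)) rest <- sample(rest)
    full <- c(ranked_key, rest)
    hits <- full %in% uni_key[universe$positive]
    tp <- cumsum(hits)
    prec <- tp / seq_along(tp)
    rec <- tp / n_gold
    list(prec = prec, rec = rec,
         aupr = sum(diff(c(0, rec)) * prec))
  }

  reps <- lapply(seq_len(tie_reps), function(r) run_once(seed + r - 1))
  first <- reps[[1]]
  res <- list(precision = first$prec, recall = first$rec,
              aupr = mean(vapply(reps, `[[`, numeric(1), "aupr")),
              n_gold = n_gold, n_eval = length(uni_key))
  if (tie_reps > 1)
    res$aupr_sd <- stats::sd(vapply(reps, `[[`, numeric(1), "aupr"))
  structure(res, class = "grn_pr")
}

# Evaluation universe: pairs with >= 1 gold edge on both axes, self
# excluded, minus explicitly excluded pairs; flags the positives.
pr_universe <- function(gold, exclude = NULL) {
  stopifnot(is.matrix(gold))
  tfs <- rownames(gold)[rowSums(gold != 0) > 0]
  genes <- colnames(gold)[colSums(gold != 0) > 0]
  pairs <- expand.grid(tf = tfs, gene = genes, stringsAsFactors = FALSE,
                       KEEP.OUT.ATTRS = FALSE)
  pairs <- pairs[pairs$tf != pairs$gene, , drop = FALSE]
  if (!is.null(exclude)) {
    drop <- exclude[cbind(pairs$tf, pairs$gene)] != 0
    pairs <- pairs[!drop, , drop = FALSE]
  }
  list(pairs = pairs,
       positive = gold[cbind(pairs$tf, pairs$gene)] != 0)
}

#' @export
print.grn_pr <- function(x, ...) {
  cat("AUPR ", format(round(x$aupr, 4)), " over ", x$n_eval,
      " evaluated pairs (", x$n_gold, " gold edges)\n", sep = "")
  if (!is.null(x$aupr_sd))
    cat("  tie-permutation sd: ", format(signif(x$aupr_sd, 3)), "\n",
        sep = "")
  invisible(x)
}

#' @export
plot.grn_pr <- function(x, ...) {
  graphics::plot(x$recall, x$precision, type = "s", xlim = c(0, 1),
                 ylim = c(0, 1), xlab = "recall", ylab = "precision",
                 ...)
  graphics::abline(h = x$n_gold / x$n_eval, lty = 3)
  invisible(x)
}

#' AUPR on the leave-out set
#'
#' Measures whether supplying priors damages the discovery of novel
#' edges: the positives are the gold-standard edges NOT supplied as
#' priors, and all prior pairs are removed from the evaluation universe
#' entirely.
#'
#' @inheritParams aupr
#' @param pki TF x gene 0/1 matrix of the prior known interactions.
#' @return A `grn_pr` object.
#' @export
leave_out_aupr <- function(x, gold, pki, seed = 1, tie_reps = 1,
                           score_col = "combined_score") {
  stopifnot(identical(dim(gold), dim(pki)))
  positives <- (gold != 0) & (pki == 0)
  if (!any(positives))
    stop("leave-out set is empty (all gold edges were priors)",
         call. = FALSE)
  gold_lo <- gold
  mode(gold_lo) <- "numeric"
  aupr(x, gold_lo, exclude = pki, seed = seed, tie_reps = tie_reps,
       score_col = score_col)
}

#' Corrupt a gold standard into a noisy prior set
#'
#' Emulates error-laden prior knowledge: a fraction of the gold-standard
#' edges is kept as true prior interactions (TPIs) and `fpi_ratio`
#' random non-gold pairs per TPI are added as false prior interactions
#' (FPIs). At the harshest published ratio (1:10) about 91% of the
#' resulting prior is erroneous.
#'
#' @param gold TF x gene 0/1 gold-standard matrix.
#' @param tpi_fraction Fraction of gold edges kept as TPIs (default 0.5).
#' @param fpi_ratio Number of FPIs added per TPI (0, 2, 5, 10 in the
#'   published experiments).
#' @param seed Seed for both samples.
#' @return A TF x gene 0/1 prior matrix with attributes `tpi` and `fpi`
#'   (data frames of the sampled pairs) and `erroneous_fraction`.
#' @export
corrupt_priors <- function(gold, tpi_fraction = 0.5, fpi_ratio = 10,
                           seed = 1) {
  stopifnot(is.matrix(gold), tpi_fraction > 0, tpi_fraction <= 1,
            fpi_ratio >= 0)
  set.seed(seed)
  gold_idx <- which(gold != 0, arr.ind = TRUE)
  n_gold <- nrow(gold_idx)
  if (n_gold == 0) stop("gold standard has no edges", call. = FALSE)
  n_tpi <- max(1, round(tpi_fraction * n_gold))
  tpi <- gold_idx[sample.int(n_gold, n_tpi), , drop = FALSE]

  self <- outer(rownames(gold), colnames(gold), "==")
  candidates <- which(gold == 0 & !self)
  n_fpi <- round(fpi_ratio * n_tpi)
  if (length(candidates) < n_fpi)
    stop("not enough non-gold pairs to sample ", n_fpi, " FPIs",
         call. = FALSE)
  fpi_flat <- if (n_fpi > 0) sample(candidates, n_fpi) else integer(0)

  priors <- matrix(0, nrow(gold), ncol(gold), dimnames = dimnames(gold))
  priors[tpi] <- 1
  priors[fpi_flat] <- 1
  fpi <- arrayInd(fpi_flat, dim(gold))
  to_df <- function(idx) data.frame(
    tf = rownames(gold)[idx[, 1]], gene = colnames(gold)[idx[, 2]],
    stringsAsFactors = FALSE)
  attr(priors, "tpi") <- to_df(tpi)
  attr(priors, "fpi") <- to_df(fpi)
  attr(priors, "erroneous_fraction") <- n_fpi / (n_tpi + n_fpi)
  priors
}

#' Naive prior-first edge ranking
#'
#' The baseline ranking that places all prior pairs at the top of the
#' list (in seeded random order) and all remaining universe pairs after
#' them (seeded random order). With error-free complete priors this
#' scores perfectly; with corrupted priors it degrades quickly, which is
#' what the inference methods are measured against.
#'
#' @param priors TF x gene 0/1 prior matrix.
#' @param gold TF x gene gold-standard matrix defining the evaluation
#'   universe.
#' @param seed Seed for both orders.
#' @return Data frame `tf`, `gene`, `combined_score` (strictly
#'   decreasing), ready for [aupr()].
#' @export
naive_prior_ranking <- function(priors, gold, seed = 1) {
  universe <- pr_universe(gold)$pairs
  set.seed(seed)
  is_prior <- priors[cbind(universe$tf, universe$gene)] != 0
  top <- universe[is_prior, , drop = FALSE]
  rest <- universe[!is_prior, , drop = FALSE]
  top <- top[sample.int(nrow(top)), , drop = FALSE]
  rest <- rest[sample.int(nrow(rest)), , drop = FALSE]
  out <- rbind(top, rest)
  out$combined_score <- rev(seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

#' Random subsets of a gold standard as prior sets
#'
#' Draws `reps` independent uniform subsamples of the gold-standard
#' edges at each requested fraction, reproducibly from the seed; used by
#' the leave-out experiments.
#'
#' @param gold TF x gene 0/1 gold-standard matrix.
#' @param fractions Fractions of edges to keep.
#' @param reps Repetitions per fraction.
#' @param seed Base seed; repetition r of fraction f is reproducible
#'   from `(seed, f, r)`.
#' @return Nested list: `result[[as.character(f)]][[r]]` is a prior
#'   matrix.
#' @export
subsample_priors <- function(gold, fractions = c(0.2, 0.4, 0.6, 0.8),
                             reps = 5, seed = 1) {
  gold_idx <- which(gold != 0)
  n_gold <- length(gold_idx)
  if (n_gold == 0) stop("gold standard has no edges", call. = FALSE)
  out <- list()
  for (f in fractions) {
    sets <- vector("list", reps)
    for (r in seq_len(reps)) {
      set.seed((seed + round(1e4 * f)) %% .Machine$integer.max + r)
      keep <- sample(gold_idx, round(f * n_gold))
      m <- matrix(0, nrow(gold), ncol(gold), dimnames = dimnames(gold))
      m[keep] <- 1
      sets[[r]] <- m
    }
    out[[as.character(f)]] <- sets
  }
  out
}
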