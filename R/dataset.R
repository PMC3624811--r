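#' Assemble an expression dataset with condition metadata
#'
#' Bundles a genes x conditions expression matrix with per-condition
#' time-series annotations and the list of candidate regulators
#' (transcription factors). This is the central input container: every
#' downstream step (design/response construction, candidate filtering,
#' model selection) operates on a validated `grn_dataset`.
#'
#' @param values Numeric matrix, rows = genes, columns = conditions, with
#'   row and column names. Expression is used as supplied (the methods are
#'   agnostic to log vs linear scale). Missing values are rejected.
#' @param meta Data frame with one row per condition and columns
#'   `condition`, `is_time_series`, `is_first`, `prev_condition`,
#'   `delta_t`. For a condition inside a time series (`is_time_series`
#'   true, `is_first` false), `prev_condition` names the preceding time
#'   point and `delta_t` gives the time elapsed since it; steady-state
#'   conditions leave both unset.
#' @param tf_ids Character vector of gene identifiers designated as
#'   candidate regulators; must be a subset of `rownames(values)`.
#'
#' @return An object of class `grn_dataset`: a list with elements
#'   `values`, `gene_ids`, `condition_ids`, `meta` (aligned to column
#'   order) and `tf_ids`.
#' @seealso [read_grn_dataset()], [design_response()], [grn_infer()]
#' @export
grn_dataset <- function(values, meta, tf_ids) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene row names and condition column names",
         call. = FALSE)
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values)))
    stop("duplicated gene or condition identifiers", call. = FALSE)
  if (anyNA(values))
    stop("expression matrix contains missing values", call. = FALSE)

  meta <- validate_meta(meta, colnames(values))
  tf_ids <- as.character(tf_ids)
  unknown_tf <- setdiff(tf_ids, rownames(values))
  if (length(unknown_tf))
    stop("tf_ids not present in expression matrix: ",
         paste(unknown_tf, collapse = ", "), call. = FALSE)
  if (!length(tf_ids))
    stop("at least one candidate regulator is required", call. = FALSE)

  structure(list(values = values,
                 gene_ids = rownames(values),
                 condition_ids = colnames(values),
                 meta = meta,
                 tf_ids = tf_ids),
            class = "grn_dataset")
}

# Normalize and check condition metadata against the expression columns.
validate_meta <- function(meta, condition_ids) {
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  need <- c("condition", "is_time_series", "is_first", "prev_condition",
            "delta_t")
  missing_cols <- setdiff(need, names(meta))
  if (length(missing_cols))
    stop("metadata lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  meta$condition <- as.character(meta$condition)
  if (!setequal(meta$condition, condition_ids) ||
      nrow(meta) != length(condition_ids))
    stop("metadata conditions do not match expression columns",
         call. = FALSE)
  meta <- meta[match(condition_ids, meta$condition), need, drop = FALSE]
  rownames(meta) <- NULL

  to_flag <- function(x) {
    if (is.logical(x)) return(x)
    x <- as.integer(x)
    if (anyNA(x) || any(!x %in% c(0L, 1L)))
      stop("metadata flags must be 0/1 or logical", call. = FALSE)
    x == 1L
  }
  meta$is_time_series <- to_flag(meta$is_time_series)
  meta$is_first <- to_flag(meta$is_first)
  meta$prev_condition <- as.character(meta$prev_condition)
  meta$prev_condition[!is.na(meta$prev_condition) &
                        meta$prev_condition == ""] <- NA_character_
  meta$delta_t <- suppressWarnings(as.numeric(meta$delta_t))

  interior <- meta$is_time_series & !meta$is_first
  if (any(interior & is.na(meta$prev_condition)))
    stop("time-series condition lacks prev_condition", call. = FALSE)
  if (any(interior & (is.na(meta$delta_t) | meta$delta_t <= 0)))
    stop("time-series condition needs delta_t > 0", call. = FALSE)
  bad_prev <- interior & !is.na(meta$prev_condition) &
    !(meta$prev_condition %in% condition_ids)
  if (any(bad_prev))
    stop("unknown prev_condition: ",
         paste(unique(meta$prev_condition[bad_prev]), collapse = ", "),
         call. = FALSE)
  if (any(!interior & !is.na(meta$prev_condition)))
    stop("prev_condition set for a steady-state or first time point",
         call. = FALSE)
  meta
}

#' @export
print.grn_dataset <- function(x, ...) {
  n_ts <- sum(x$meta$is_time_series)
  n_resp <- sum(x$meta$is_time_series & !x$meta$is_first)
  cat("grn_dataset: ", length(x$gene_ids), " genes x ",
      length(x$condition_ids), " conditions\n", sep = "")
  cat("  candidate regulators: ", length(x$tf_ids), "\n", sep = "")
  cat("  time-series conditions: ", n_ts, " (", n_resp,
      " lagged pairs), steady-state: ",
      sum(!x$meta$is_time_series), "\n", sep = "")
  invisible(x)
}

#' Read an expression dataset from TSV files
#'
#' Expects a tab-separated expression table (header row of condition
#' identifiers, first column of gene identifiers), a condition metadata
#' table with columns `condition`, `is_time_series`, `is_first`,
#' `prev_condition`, `delta_t`, and a plain-text file with one candidate
#' regulator identifier per line. Column order of the expression table is
#' preserved. Non-numeric expression cells, condition sets that disagree
#' between expression and metadata, and dangling `prev_condition`
#' references are format errors.
#'
#' @param expression_path,meta_path,tf_path Paths to the three files.
#' @return A validated [grn_dataset()].
#' @export
read_grn_dataset <- function(expression_path, meta_path, tf_path) {
  expr <- utils::read.delim(expression_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
  if (ncol(expr) < 2)
    stop("expression table needs a gene id column plus conditions",
         call. = FALSE)
  gene_ids <- as.character(expr[[1]])
  vals <- expr[, -1, drop = FALSE]
  num <- vapply(vals, function(col) {
    if (is.numeric(col)) col
    else suppressWarnings(as.numeric(as.character(col)))
  }, numeric(nrow(vals)))
  num <- matrix(num, nrow = nrow(vals))
  if (anyNA(num) && !anyNA(vals))
    stop("non-numeric expression cell in ", expression_path, call. = FALSE)
  if (anyNA(num))
    stop("missing expression values in ", expression_path, call. = FALSE)
  values <- num
  dimnames(values) <- list(gene_ids, colnames(vals))

  meta <- utils::read.delim(meta_path, check.names = FALSE,
                            stringsAsFactors = FALSE,
                            colClasses = "character")
  tfs <- readLines(tf_path, warn = FALSE)
  tfs <- trimws(tfs)
  tfs <- tfs[nzchar(tfs)]
  grn_dataset(values, meta, tfs)
}

#' Write an expression dataset to TSV files
#'
#' Inverse of [read_grn_dataset()]; a write/read round trip reproduces the
#' dataset exactly (values are serialized at full precision).
#'
#' @param x A [grn_dataset()].
#' @param expression_path,meta_path,tf_path Output paths.
#' @return Invisibly, `x`.
#' @export
write_grn_dataset <- function(x, expression_path, meta_path, tf_path) {
  stopifnot(inherits(x, "grn_dataset"))
  df <- data.frame(gene = x$gene_ids, check.names = FALSE,
                   stringsAsFactors = FALSE)
  vals <- as.data.frame(x$values, check.names = FALSE)
  vals[] <- lapply(vals, format_full)
  df <- cbind(df, vals)
  utils::write.table(df, expression_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- x$meta
  meta$is_time_series <- as.integer(meta$is_time_series)
  meta$is_first <- as.integer(meta$is_first)
  meta$prev_condition[is.na(meta$prev_condition)] <- ""
  meta$delta_t <- ifelse(is.na(meta$delta_t), "", format_full(meta$delta_t))
  utils::write.table(meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(x$tf_ids, tf_path)
  invisible(x)
}

# Full-precision serialization (17 significant digits) so TSV round
# trips are bit exact.
format_full <- function(x) sprintf("%.17g", x)
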