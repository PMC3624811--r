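#' Read a prior or gold-standard interaction matrix
#'
#' Accepts either a TSV matrix (rows = TFs with identifiers in the first
#' column, columns = genes named in the header) or a three-column edge
#' list (`tf`, `gene`/`target`, `value`). Values must lie in \{-1, 0, 1\};
#' the sign is retained as an annotation but only presence/absence of an
#' edge drives prior weighting downstream (structure priors carry
#' connectivity, not strength). The result is aligned to the dataset's
#' TF x gene axes, with self-interactions zeroed (self-regulation is never
#' inferred). An empty file yields an all-zero matrix ("no priors").
#'
#' @param path Path to the TSV file.
#' @param dataset A [grn_dataset()] supplying the axes.
#' @param strict If `TRUE` (default) edges that reference unknown TFs or
#'   genes are an error; if `FALSE` they are dropped with a warning.
#' @return A TF x gene numeric 0/1 matrix with attribute `"sign"` holding
#'   the signed entries.
#' @export
read_edge_matrix <- function(path, dataset, strict = TRUE) {
  stopifnot(inherits(dataset, "grn_dataset"))
  if (file.size(path) == 0)
    return(empty_edge_matrix(dataset))
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (nrow(tab) == 0)
    return(empty_edge_matrix(dataset))

  edge_names <- function(nm) {
    length(nm) == 3 &&
      tolower(nm[1]) %in% c("tf", "regulator", "source") &&
      tolower(nm[2]) %in% c("gene", "target") &&
      tolower(nm[3]) %in% c("value", "sign", "weight")
  }
  numeric_body <- all(vapply(tab[, -1, drop = FALSE], is.numeric,
                             logical(1)))
  if (edge_names(names(tab))) {
    edges <- data.frame(tf = as.character(tab[[1]]),
                        gene = as.character(tab[[2]]),
                        value = as.numeric(tab[[3]]),
                        stringsAsFactors = FALSE)
    edge_matrix_from_edges(edges, dataset, strict = strict)
  } else if (ncol(tab) >= 2 && numeric_body) {
    m <- as.matrix(tab[, -1, drop = FALSE])
    rownames(m) <- as.character(tab[[1]])
    align_edge_matrix(m, dataset, strict = strict)
  } else {
    stop("cannot tell whether ", path,
         " is a TF x gene matrix or an edge list", call. = FALSE)
  }
}

#' Build an interaction matrix from an edge list
#'
#' @param edges Data frame with columns `tf`, `gene`, `value` (values in
#'   \{-1, 0, 1\}).
#' @inheritParams read_edge_matrix
#' @return As [read_edge_matrix()].
#' @export
edge_matrix_from_edges <- function(edges, dataset, strict = TRUE) {
  stopifnot(inherits(dataset, "grn_dataset"))
  bad_tf <- !(edges$tf %in% dataset$tf_ids)
  bad_gene <- !(edges$gene %in% dataset$gene_ids)
  if (any(bad_tf | bad_gene)) {
    culprits <- unique(c(edges$tf[bad_tf], edges$gene[bad_gene]))
    if (strict)
      stop("edges reference unknown identifiers: ",
           paste(culprits, collapse = ", "), call. = FALSE)
    warning("dropping edges with unknown identifiers: ",
            paste(culprits, collapse = ", "), call. = FALSE)
    edges <- edges[!(bad_tf | bad_gene), , drop = FALSE]
  }
  sgn <- matrix(0, length(dataset$tf_ids), length(dataset$gene_ids),
                dimnames = list(dataset$tf_ids, dataset$gene_ids))
  if (nrow(edges)) {
    check_edge_values(edges$value)
    sgn[cbind(edges$tf, edges$gene)] <- edges$value
  }
  finish_edge_matrix(sgn)
}

# Align a raw TF x gene matrix (arbitrary sub-axes) onto dataset axes.
align_edge_matrix <- function(m, dataset, strict = TRUE) {
  check_edge_values(m)
  bad_tf <- setdiff(rownames(m), dataset$tf_ids)
  bad_gene <- setdiff(colnames(m), dataset$gene_ids)
  if (length(bad_tf) || length(bad_gene)) {
    if (strict)
      stop("matrix axes reference unknown identifiers: ",
           paste(c(bad_tf, bad_gene), collapse = ", "), call. = FALSE)
    warning("dropping rows/columns with unknown identifiers: ",
            paste(c(bad_tf, bad_gene), collapse = ", "), call. = FALSE)
    m <- m[setdiff(rownames(m), bad_tf),
           setdiff(colnames(m), bad_gene), drop = FALSE]
  }
  sgn <- matrix(0, length(dataset$tf_ids), length(dataset$gene_ids),
                dimnames = list(dataset$tf_ids, dataset$gene_ids))
  sgn[rownames(m), colnames(m)] <- m
  finish_edge_matrix(sgn)
}

#' All-zero interaction matrix on a dataset's axes
#'
#' @inheritParams read_edge_matrix
#' @return A TF x gene zero matrix (the "no priors" input).
#' @export
empty_edge_matrix <- function(dataset) {
  stopifnot(inherits(dataset, "grn_dataset"))
  finish_edge_matrix(
    matrix(0, length(dataset$tf_ids), length(dataset$gene_ids),
           dimnames = list(dataset$tf_ids, dataset$gene_ids)))
}

check_edge_values <- function(v) {
  if (anyNA(v) || !all(v %in% c(-1, 0, 1)))
    stop("interaction values must be in {-1, 0, 1}", call. = FALSE)
  invisible(v)
}

# Zero the self-pairs and split presence from sign.
finish_edge_matrix <- function(sgn) {
  shared <- intersect(rownames(sgn), colnames(sgn))
  sgn[cbind(shared, shared)] <- 0
  out <- abs(sgn)
  attr(out, "sign") <- sgn
  out
}

#' Write an interaction matrix to TSV
#'
#' @param m TF x gene matrix as returned by [read_edge_matrix()]; the
#'   `"sign"` attribute is written when present, otherwise the 0/1 body.
#' @param path Output path.
#' @param format `"matrix"` (default) writes the full TF x gene table;
#'   `"edges"` writes the nonzero entries as a `tf`, `gene`, `value` list.
#' @return Invisibly, `m`.
#' @export
write_edge_matrix <- function(m, path, format = c("matrix", "edges")) {
  format <- match.arg(format)
  body <- attr(m, "sign")
  if (is.null(body)) body <- m
  if (format == "matrix") {
    df <- data.frame(tf = rownames(body), check.names = FALSE,
                     stringsAsFactors = FALSE)
    df <- cbind(df, as.data.frame(body, check.names = FALSE))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    idx <- which(body != 0, arr.ind = TRUE)
    df <- data.frame(tf = rownames(body)[idx[, 1]],
                     gene = colnames(body)[idx[, 2]],
                     value = body[idx],
                     stringsAsFactors = FALSE)
    df <- df[order(df$tf, df$gene), , drop = FALSE]
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(m)
}
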