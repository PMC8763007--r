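#' Count matrix container
#'
#' Wraps a genes x cells matrix of non-negative integer UMI counts together
#' with unique gene and cell identifiers. The matrix may be dense or a
#' \pkg{Matrix} sparse matrix; it is stored as given.
#'
#' @param values genes x cells matrix (base matrix or Matrix sparse matrix)
#'   of non-negative integer counts.
#' @param gene_ids character vector of unique gene identifiers; defaults to
#'   `rownames(values)`.
#' @param cell_ids character vector of unique cell identifiers; defaults to
#'   `colnames(values)`.
#' @return An object of class `tme_counts` with elements `values`,
#'   `gene_ids`, `cell_ids`.
#' @export
count_matrix <- function(values, gene_ids = rownames(values),
                         cell_ids = colnames(values)) {
  if (is.null(gene_ids) || is.null(cell_ids)) {
    stop("gene_ids and cell_ids are required (or set dimnames on `values`)")
  }
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != nrow(values) || length(cell_ids) != ncol(values)) {
    stop("identifier lengths do not match matrix dimensions")
  }
  if (anyDuplicated(gene_ids)) stop("gene_ids must be unique")
  if (anyDuplicated(cell_ids)) stop("cell_ids must be unique")
  v <- if (inherits(values, "sparseMatrix")) min(values@x, 0) else min(values, 0)
  if (v < 0) stop("counts must be non-negative")
  chk <- if (inherits(values, "sparseMatrix")) values@x else values
  if (length(chk) && any(abs(chk - round(chk)) > 1e-8)) {
    stop("counts must be integers")
  }
  dimnames(values) <- list(gene_ids, cell_ids)
  structure(list(values = values, gene_ids = gene_ids, cell_ids = cell_ids),
            class = "tme_counts")
}

#' Expression matrix container
#'
#' A genes x cells matrix of real expression values tagged with the
#' transform that produced it, so downstream steps can verify they receive
#' the convention they expect.
#'
#' @param values genes x cells numeric matrix.
#' @param transform one of `"raw_tpm"`, `"lognorm10k"`, `"log2tpm10"`,
#'   `"scaled"`.
#' @param gene_ids,cell_ids identifiers; default to dimnames of `values`.
#' @return An object of class `tme_expr` with elements `values`, `gene_ids`,
#'   `cell_ids`, `transform`.
#' @export
expression_matrix <- function(values, transform,
                              gene_ids = rownames(values),
                              cell_ids = colnames(values)) {
  transform <- match.arg(transform,
                         c("raw_tpm", "lognorm10k", "log2tpm10", "scaled"))
  if (is.null(gene_ids) || is.null(cell_ids)) {
    stop("gene_ids and cell_ids are required")
  }
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != nrow(values) || length(cell_ids) != ncol(values)) {
    stop("identifier lengths do not match matrix dimensions")
  }
  if (anyDuplicated(gene_ids)) stop("gene_ids must be unique")
  if (anyDuplicated(cell_ids)) stop("cell_ids must be unique")
  dimnames(values) <- list(gene_ids, cell_ids)
  structure(list(values = values, gene_ids = gene_ids, cell_ids = cell_ids,
                 transform = transform),
            class = "tme_expr")
}

#' @export
print.tme_counts <- function(x, ...) {
  cat(sprintf("<tme_counts> %d genes x %d cells, %s storage\n",
              length(x$gene_ids), length(x$cell_ids),
              if (inherits(x$values, "sparseMatrix")) "sparse" else "dense"))
  invisible(x)
}

#' @export
print.tme_expr <- function(x, ...) {
  cat(sprintf("<tme_expr:%s> %d genes x %d cells\n",
              x$transform, length(x$gene_ids), length(x$cell_ids)))
  invisible(x)
}

#' @export
dim.tme_counts <- function(x) dim(x$values)

#' @export
dim.tme_expr <- function(x) dim(x$values)

#' Subset a count or expression matrix by genes and/or cells
#'
#' @param x a `tme_counts` or `tme_expr` object.
#' @param genes,cells character vectors of identifiers to keep (`NULL` keeps
#'   all). Order of the result follows the order of the arguments.
#' @return An object of the same class.
#' @export
subset_matrix <- function(x, genes = NULL, cells = NULL) {
  stopifnot(inherits(x, c("tme_counts", "tme_expr")))
  g <- if (is.null(genes)) x$gene_ids else {
    missing <- setdiff(genes, x$gene_ids)
    if (length(missing)) stop("unknown genes: ", paste(utils::head(missing, 5), collapse = ", "))
    genes
  }
  cc <- if (is.null(cells)) x$cell_ids else {
    missing <- setdiff(cells, x$cell_ids)
    if (length(missing)) stop("unknown cells: ", paste(utils::head(missing, 5), collapse = ", "))
    cells
  }
  v <- x$values[g, cc, drop = FALSE]
  if (inherits(x, "tme_counts")) count_matrix(v, g, cc)
  else expression_matrix(v, x$transform, g, cc)
}
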