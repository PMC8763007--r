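#' Build subtype centroid models from a reference dataset
#'
#' The model for each subtype is the per-gene mean expression over that
#' subtype's reference cells, restricted to the union of all signature
#' genes; the gene axis is identical across subtypes. Reference expression
#' should be `lognorm10k` (UMI platforms) or `log2tpm10` (full-length).
#'
#' @param reference_expr an [expression_matrix()].
#' @param reference_labels character vector of subtype labels, one per
#'   reference cell (`NA` cells are ignored).
#' @param signatures named list: subtype -> signature genes.
#' @param min_cells minimum reference cells per subtype (default 5).
#' @return A list of class `subtype_models`: `centroids` (genes x subtypes
#'   matrix over the signature-gene union), `genes`, `expression_convention`.
#' @export
build_subtype_models <- function(reference_expr, reference_labels,
                                 signatures, min_cells = 5) {
  stopifnot(inherits(reference_expr, "tme_expr"))
  if (length(reference_labels) != length(reference_expr$cell_ids)) {
    stop("one label per reference cell required")
  }
  if (!length(signatures) || is.null(names(signatures))) {
    stop("signatures must be a named list")
  }
  union_genes <- unique(unlist(signatures))
  present <- intersect(union_genes, reference_expr$gene_ids)
  if (length(present) < 0.5 * length(union_genes)) {
    warning(sprintf("only %d of %d signature genes present in the reference",
                    length(present), length(union_genes)))
  }
  if (!length(present)) stop("no signature genes present in the reference")
  v <- as.matrix(reference_expr$values)[present, , drop = FALSE]
  subtypes <- names(signatures)
  centroids <- matrix(NA_real_, length(present), length(subtypes),
                      dimnames = list(present, subtypes))
  for (s in subtypes) {
    cells <- which(!is.na(reference_labels) & reference_labels == s)
    if (!length(cells)) stop("subtype with no reference cells: ", s)
    if (length(cells) < min_cells) {
      warning(sprintf("subtype %s has only %d reference cells", s,
                      length(cells)))
    }
    centroids[, s] <- rowMeans(v[, cells, drop = FALSE])
  }
  structure(list(centroids = centroids, genes = present,
                 expression_convention = reference_expr$transform),
            class = "subtype_models")
}

#' Build binary indicator models from signature lists alone
#'
#' When no reference expression is available, a subtype model can be the
#' indicator profile of its own signature genes: 1 on the subtype's genes,
#' 0 on the rest of the signature-gene union. Correlation against such a
#' model asks whether the cell's expression is elevated on that subtype's
#' genes relative to the other subtypes' genes.
#'
#' @param signatures named list: subtype -> signature genes.
#' @return A `subtype_models` object with `expression_convention = "indicator"`.
#' @export
build_indicator_models <- function(signatures) {
  if (!length(signatures) || is.null(names(signatures))) {
    stop("signatures must be a named list")
  }
  union_genes <- unique(unlist(signatures))
  centroids <- vapply(signatures,
                      function(g) as.numeric(union_genes %in% g),
                      numeric(length(union_genes)))
  rownames(centroids) <- union_genes
  structure(list(centroids = centroids, genes = union_genes,
                 expression_convention = "indicator"),
            class = "subtype_models")
}

#' Classify cells against subtype models with optional unknown rejection
#'
#' Each cell is compared with every subtype model by Pearson (or Spearman)
#' correlation over the signature-gene union; the cell takes the argmax
#' label. Per-model significance comes from a permutation null: the cell's
#' values over the union are permuted `n_perm` times and the correlation
#' recomputed, giving p = (1 + #(null >= observed)) / (n_perm + 1). With
#' `allow_unknown`, a cell whose p-values all exceed `alpha` is labeled
#' `"unknown"` — its pattern is not significantly similar to any model.
#'
#' @param expr an [expression_matrix()]; its transform should match the
#'   models' convention (indicator models accept either convention).
#' @param models a `subtype_models` object.
#' @param allow_unknown enable rejection (default `FALSE`, the forced-call
#'   regime used for endothelial subtypes; enable for fibroblasts).
#' @param alpha rejection level (default 0.05).
#' @param n_perm permutations per cell (default 1000).
#' @param seed integer seed for the permutation draws.
#' @param method `"pearson"` or `"spearman"`.
#' @return data.frame with `cell_id`, `label`, `similarity` (best
#'   correlation), `p_min` (smallest per-model p-value). Cells with zero
#'   variance over the union are labeled `"unknown"` with a warning.
#' @export
classify_cells <- function(expr, models, allow_unknown = FALSE,
                           alpha = 0.05, n_perm = 1000, seed = 1,
                           method = c("pearson", "spearman")) {
  stopifnot(inherits(expr, "tme_expr"), inherits(models, "subtype_models"))
  method <- match.arg(method)
  if (models$expression_convention != "indicator" &&
      models$expression_convention != expr$transform) {
    stop(sprintf("expression convention mismatch: models built on %s, cells are %s",
                 models$expression_convention, expr$transform))
  }
  genes <- intersect(models$genes, expr$gene_ids)
  if (!length(genes)) stop("no model genes present in the expression matrix")
  E <- as.matrix(expr$values)[genes, , drop = FALSE]
  C <- models$centroids[genes, , drop = FALSE]
  if (method == "spearman") {
    E <- apply(E, 2, rank)
    C <- apply(C, 2, rank)
  }
  ng <- length(genes)
  standardize <- function(m) {
    m <- sweep(m, 2, colMeans(m), "-")
    s <- sqrt(colSums(m^2))
    ok <- s > 0
    m[, ok] <- sweep(m[, ok, drop = FALSE], 2, s[ok], "/")
    list(m = m, ok = ok)
  }
  Cs <- standardize(C)
  if (!all(Cs$ok)) stop("constant centroid(s): ",
                        paste(colnames(C)[!Cs$ok], collapse = ", "))
  Es <- standardize(E)
  sims <- crossprod(Es$m, Cs$m)                     # cells x models
  n_cells <- ncol(E)
  ge_counts <- matrix(0L, n_cells, ncol(C))
  withr::with_seed(seed, {
    for (p in seq_len(n_perm)) {
      perm <- sample.int(ng)
      null_sims <- crossprod(Es$m[perm, , drop = FALSE], Cs$m)
      ge_counts <- ge_counts + (null_sims >= sims)
    }
  })
  pvals <- (1 + ge_counts) / (n_perm + 1)
  best <- max.col(sims, ties.method = "first")
  label <- colnames(C)[best]
  similarity <- sims[cbind(seq_len(n_cells), best)]
  p_min <- apply(pvals, 1, min)
  if (allow_unknown) label[p_min > alpha] <- "unknown"
  if (any(!Es$ok)) {
    warning(sum(!Es$ok), " cell(s) with zero variance over the signature union -> unknown")
    label[!Es$ok] <- "unknown"
    similarity[!Es$ok] <- NA_real_
    p_min[!Es$ok] <- NA_real_
  }
  out <- data.frame(cell_id = expr$cell_ids, label = label,
                    similarity = as.numeric(similarity),
                    p_min = as.numeric(p_min), stringsAsFactors = FALSE)
  dimnames(pvals) <- list(expr$cell_ids, colnames(C))
  attr(out, "p_values") <- pvals
  out
}

#' Signature-gene heatmap matrix ordered by subtype blocks
#'
#' Rows are signature genes grouped by the subtype they mark, columns are
#' cells grouped by assigned label (model subtypes first, then
#' `"unknown"`); values are z-scored per gene across cells. Block extents
#' are returned so the matrix can be exported or drawn with block
#' separators.
#'
#' @param expr an [expression_matrix()].
#' @param assignment data.frame from [classify_cells()].
#' @param signatures named list: subtype -> signature genes.
#' @return A list of class `subtype_heatmap`: `matrix` (genes x cells,
#'   z-scored), `row_blocks` and `col_blocks` (data.frames with `name`,
#'   `start`, `end`; empty subtypes give zero-width blocks).
#' @export
subtype_heatmap_matrix <- function(expr, assignment, signatures) {
  stopifnot(inherits(expr, "tme_expr"))
  row_genes <- character()
  row_blocks <- data.frame(name = character(), start = integer(),
                           end = integer(), stringsAsFactors = FALSE)
  for (s in names(signatures)) {
    g <- intersect(signatures[[s]], expr$gene_ids)
    g <- setdiff(g, row_genes)  # a gene stays in its first subtype block
    start <- length(row_genes) + 1L
    row_genes <- c(row_genes, g)
    row_blocks <- rbind(row_blocks,
                        data.frame(name = s, start = start,
                                   end = length(row_genes)))
  }
  col_order <- character()
  col_blocks <- data.frame(name = character(), start = integer(),
                           end = integer(), stringsAsFactors = FALSE)
  labels <- c(names(signatures),
              setdiff(unique(assignment$label), names(signatures)))
  for (lb in labels) {
    cells <- assignment$cell_id[assignment$label == lb]
    cells <- sort(cells)
    start <- length(col_order) + 1L
    col_order <- c(col_order, cells)
    col_blocks <- rbind(col_blocks,
                        data.frame(name = lb, start = start,
                                   end = length(col_order)))
  }
  m <- as.matrix(expr$values)[row_genes, col_order, drop = FALSE]
  mz <- t(scale(t(m)))
  mz[is.nan(mz)] <- 0
  structure(list(matrix = mz, row_blocks = row_blocks,
                 col_blocks = col_blocks),
            class = "subtype_heatmap")
}
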