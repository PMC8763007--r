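#' Single-sample GSEA score for one cell and one gene set
#'
#' Genes are ranked by expression, descending (ties broken by gene name,
#' lexicographic, so the score is deterministic and invariant to storage
#' order). Walking down the ranked list, the score accumulates the
#' difference between the weighted in-set empirical CDF and the unweighted
#' out-of-set CDF; the in-set weights are rank positions raised to `alpha`
#' (top gene gets the largest weight), which makes the score exactly
#' invariant under strictly monotone transforms of the expression vector.
#' The reported score is the sum of the running differences (the
#' integrated form).
#'
#' @param expr_vector named numeric vector: one cell's expression over the
#'   gene universe.
#' @param gene_set character vector of gene names; its intersection with
#'   the universe must be non-empty and strictly smaller than the universe.
#' @param alpha weight exponent (default 0.25).
#' @return A single numeric enrichment score.
#' @export
ssgsea_score <- function(expr_vector, gene_set, alpha = 0.25) {
  if (is.null(names(expr_vector))) stop("expr_vector must be named")
  universe <- names(expr_vector)
  n <- length(universe)
  inset <- universe %in% gene_set
  k <- sum(inset)
  if (k == 0) stop("gene set has empty intersection with the universe")
  if (k == n) stop("gene set equals the whole universe (degenerate)")
  ord <- order(-expr_vector, universe)
  ind <- inset[ord]
  w <- (n - seq_len(n) + 1)^alpha    # rank weight, largest at the top
  win <- w * ind
  p_in <- cumsum(win) / sum(win)
  p_out <- cumsum(!ind) / (n - k)
  sum(p_in - p_out)
}

#' ssGSEA scores for all cells and gene sets
#'
#' Applies [ssgsea_score()] per cell and set. With `normalize = TRUE` the
#' scores of each set are divided by their (max - min) across the cells of
#' the run; a zero range triggers a warning and leaves that set's scores
#' raw.
#'
#' @param expr an [expression_matrix()] (log-normalized values expected).
#' @param gene_sets named list: set name -> genes.
#' @param normalize range-normalize per set (default `TRUE`).
#' @param alpha weight exponent (default 0.25).
#' @return A list of class `pathway_scores`: `scores` (cells x sets
#'   matrix), `normalized`, `alpha`.
#' @export
ssgsea_matrix <- function(expr, gene_sets, normalize = TRUE, alpha = 0.25) {
  stopifnot(inherits(expr, "tme_expr"))
  if (!length(gene_sets) || is.null(names(gene_sets))) {
    stop("gene_sets must be a named list")
  }
  v <- as.matrix(expr$values)
  scores <- matrix(NA_real_, ncol(v), length(gene_sets),
                   dimnames = list(expr$cell_ids, names(gene_sets)))
  for (ci in seq_len(ncol(v))) {
    vec <- stats::setNames(v[, ci], expr$gene_ids)
    for (s in names(gene_sets)) {
      scores[ci, s] <- ssgsea_score(vec, gene_sets[[s]], alpha = alpha)
    }
  }
  normalized <- rep(FALSE, length(gene_sets))
  if (normalize) {
    for (si in seq_along(gene_sets)) {
      rng <- diff(range(scores[, si]))
      if (rng > 0) {
        scores[, si] <- scores[, si] / rng
        normalized[si] <- TRUE
      } else {
        warning("zero score range for set ", names(gene_sets)[si],
                "; raw scores returned")
      }
    }
  }
  structure(list(scores = scores, normalized = all(normalized),
                 alpha = alpha),
            class = "pathway_scores")
}

#' Summarize pathway scores (or gene expression) by cell group
#'
#' For each group (for example EC subtypes C1-C5, fibroblast subtypes
#' C7-C11, and tumor cells) reports the median and quartiles of every score
#' column. Groups with no cells are skipped with a warning.
#'
#' @param scores a `pathway_scores` object or a cells x columns numeric
#'   matrix with cell ids as rownames.
#' @param groups named character vector: cell id -> group. Cells absent
#'   from `groups` (or with `NA` group) are ignored.
#' @return data.frame with `group`, `score_set`, `n`, `median`, `q25`, `q75`.
#' @export
group_activity_summary <- function(scores, groups) {
  m <- if (inherits(scores, "pathway_scores")) scores$scores else scores
  if (is.null(rownames(m))) stop("scores must have cell ids as rownames")
  if (is.null(names(groups))) stop("groups must be named by cell id")
  groups <- groups[!is.na(groups)]
  cells <- intersect(rownames(m), names(groups))
  out <- list()
  for (g in unique(groups)) {
    gc <- intersect(cells, names(groups)[groups == g])
    if (!length(gc)) {
      warning("empty group skipped: ", g)
      next
    }
    sub <- m[gc, , drop = FALSE]
    for (cn in colnames(m)) {
      q <- stats::quantile(sub[, cn], c(0.25, 0.5, 0.75), names = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        group = g, score_set = cn, n = length(gc),
        median = q[2], q25 = q[1], q75 = q[3], stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(group = character(), score_set = character(),
                      n = integer(), median = numeric(), q25 = numeric(),
                      q75 = numeric()))
  }
  do.call(rbind, out)
}

#' Per-gene expression matrix for group summaries
#'
#' Extracts named genes (e.g. TGFB1, TGFBR2, ACVR1) as a cells x genes
#' matrix suitable for [group_activity_summary()], so individual pathway
#' members can be summarized the same way as set scores.
#'
#' @param expr an [expression_matrix()].
#' @param genes character vector; an absent gene is an error naming it.
#' @return cells x genes numeric matrix with cell ids as rownames.
#' @export
gene_activity_matrix <- function(expr, genes) {
  stopifnot(inherits(expr, "tme_expr"))
  missing <- setdiff(genes, expr$gene_ids)
  if (length(missing)) {
    stop("gene(s) absent from the universe: ",
         paste(missing, collapse = ", "))
  }
  t(as.matrix(expr$values)[genes, , drop = FALSE])
}
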