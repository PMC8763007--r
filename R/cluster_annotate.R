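#' Principal component analysis of the scaled matrix
#'
#' Centered PCA via SVD on the cells x genes matrix (genes are the scaled
#' HVGs). A deterministic sign convention is applied: for each component
#' the loading of largest magnitude is made positive.
#'
#' @param scaled an [expression_matrix()] tagged `scaled` (HVGs x cells).
#' @param max_components number of components to retain (default 50).
#' @return A list of class `tme_embedding`: `scores` (cells x d), `loadings`
#'   (genes x d), `explained_variance_ratio` (full spectrum), `cell_ids`.
#' @export
run_pca <- function(scaled, max_components = 50) {
  stopifnot(inherits(scaled, "tme_expr"))
  X <- t(as.matrix(scaled$values))  # cells x genes
  if (max_components > min(dim(X))) {
    stop("max_components exceeds min(n_cells, n_genes)")
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = max_components)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- pc$x
  loadings <- pc$rotation
  for (k in seq_len(ncol(scores))) {
    j <- which.max(abs(loadings[, k]))
    if (loadings[j, k] < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  rownames(scores) <- scaled$cell_ids
  structure(list(scores = scores, loadings = loadings,
                 explained_variance_ratio = evr,
                 cell_ids = scaled$cell_ids),
            class = "tme_embedding")
}

#' Choose the number of dimensions from the variance spectrum (elbow rule)
#'
#' Returns the smallest component index at which the decrease between
#' consecutive explained-variance ratios falls below `drop_tol`, clamped to
#' `[d_min, d_max]`; `d_max` when the spectrum never flattens.
#'
#' @param explained_variance_ratio non-increasing numeric vector.
#' @param drop_tol flatness tolerance on consecutive differences.
#' @param d_min,d_max clamp bounds (defaults 10 and 50).
#' @return Integer number of dimensions.
#' @export
choose_dims_elbow <- function(explained_variance_ratio, drop_tol = 0.001,
                              d_min = 10, d_max = 50) {
  evr <- explained_variance_ratio
  if (length(evr) < d_min) stop("spectrum shorter than d_min")
  if (any(diff(evr) > 1e-12)) stop("explained_variance_ratio must be non-increasing")
  drops <- -diff(evr)
  flat <- which(drops < drop_tol)
  d <- if (length(flat)) flat[1] else d_max
  as.integer(min(max(d, d_min), min(d_max, length(evr))))
}

#' Graph-based clustering of an embedding
#'
#' Builds a k-nearest-neighbor graph (Euclidean distance in the embedding)
#' and partitions it with multilevel modularity optimization (Louvain).
#'
#' @param embedding a `tme_embedding` from [run_pca()].
#' @param dims number of leading components to use (default: all retained).
#' @param n_neighbors neighbors per cell (default 20).
#' @param resolution modularity resolution parameter (default 0.8).
#' @param seed integer seed; the partition is deterministic under it.
#' @return data.frame with `cell_id` and integer `cluster`.
#' @export
cluster_graph <- function(embedding, dims = NULL, n_neighbors = 20,
                          resolution = 0.8, seed = 1) {
  stopifnot(inherits(embedding, "tme_embedding"))
  S <- embedding$scores
  if (!is.null(dims)) S <- S[, seq_len(dims), drop = FALSE]
  if (ncol(S) < 2) stop("need at least 2 embedding dimensions")
  n <- nrow(S)
  if (n_neighbors >= n) stop("n_neighbors must be < number of cells")
  d2 <- as.matrix(stats::dist(S))^2
  diag(d2) <- Inf
  nn <- t(apply(d2, 1, function(r) order(r)[seq_len(n_neighbors)]))
  edges <- cbind(rep(seq_len(n), each = n_neighbors), as.vector(t(nn)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  cl <- withr::with_seed(seed,
    igraph::cluster_louvain(g, resolution = resolution))
  data.frame(cell_id = embedding$cell_ids,
             cluster = as.integer(igraph::membership(cl)),
             stringsAsFactors = FALSE)
}

#' Annotate clusters with major cell types from marker gene sets
#'
#' For each cluster and marker set, the mean expression of the set genes
#' over the cluster's cells is computed and z-scored across clusters per
#' set (so high-expression sets do not dominate); each cluster is assigned
#' the argmax set. Exact ties go to the lexicographically first type name,
#' with a warning.
#'
#' @param expr an [expression_matrix()] tagged `lognorm10k` or `log2tpm10`.
#' @param labels data.frame from [cluster_graph()] (`cell_id`, `cluster`).
#' @param marker_sets named list: type name -> marker genes. Sets with an
#'   empty intersection with the gene universe are skipped with a warning.
#' @return A list of class `cluster_annotation`: `cells` (data.frame
#'   `cell_id`, `cluster`, `major_type`), `clusters` (data.frame `cluster`,
#'   `major_type`, `score`), `set_scores` (clusters x sets z-score matrix).
#' @export
annotate_clusters <- function(expr, labels, marker_sets) {
  stopifnot(inherits(expr, "tme_expr"))
  if (!expr$transform %in% c("lognorm10k", "log2tpm10")) {
    stop("annotation expects lognorm10k or log2tpm10 expression")
  }
  if (!all(labels$cell_id %in% expr$cell_ids)) {
    stop("labels contain cells absent from the expression matrix")
  }
  keep <- vapply(marker_sets,
                 function(g) length(intersect(g, expr$gene_ids)) > 0,
                 logical(1))
  if (!all(keep)) {
    warning("marker set(s) with empty gene intersection skipped: ",
            paste(names(marker_sets)[!keep], collapse = ", "))
    marker_sets <- marker_sets[keep]
  }
  if (!length(marker_sets)) stop("no usable marker sets")
  v <- as.matrix(expr$values)[, labels$cell_id, drop = FALSE]
  clusters <- sort(unique(labels$cluster))
  m <- matrix(NA_real_, length(clusters), length(marker_sets),
              dimnames = list(clusters, names(marker_sets)))
  for (ci in seq_along(clusters)) {
    cells <- labels$cell_id[labels$cluster == clusters[ci]]
    if (!length(cells)) stop("empty cluster: ", clusters[ci])
    sub <- v[, cells, drop = FALSE]
    for (si in seq_along(marker_sets)) {
      genes <- intersect(marker_sets[[si]], expr$gene_ids)
      m[ci, si] <- mean(sub[genes, , drop = FALSE])
    }
  }
  z <- scale(m)           # z-score across clusters per set
  z[is.nan(z)] <- 0       # a set constant across clusters carries no signal
  assign_one <- function(zrow) {
    best <- which(zrow == max(zrow))
    if (length(best) > 1) {
      warning("annotation tie broken lexicographically: ",
              paste(colnames(z)[best], collapse = " vs "))
      best <- best[order(colnames(z)[best])][1]
    }
    best
  }
  picks <- apply(z, 1, assign_one)
  cl_df <- data.frame(cluster = clusters,
                      major_type = colnames(z)[picks],
                      score = z[cbind(seq_along(picks), picks)],
                      stringsAsFactors = FALSE)
  cells_df <- merge(labels, cl_df[, c("cluster", "major_type")],
                    by = "cluster", sort = FALSE)
  cells_df <- cells_df[match(labels$cell_id, cells_df$cell_id),
                       c("cell_id", "cluster", "major_type")]
  rownames(cells_df) <- NULL
  structure(list(cells = cells_df, clusters = cl_df, set_scores = z),
            class = "cluster_annotation")
}
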