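#' Per-cell quality-control statistics
#'
#' @param counts a [count_matrix()].
#' @param mito_gene_ids character vector of mitochondrial gene ids (subset
#'   of the matrix genes; may be empty, in which case mito fractions are 0
#'   and a warning is emitted).
#' @return data.frame with columns `cell_id`, `n_genes_detected`, `n_umi`,
#'   `mito_fraction`. All-zero cells get `mito_fraction = 0`.
#' @export
compute_cell_qc <- function(counts, mito_gene_ids = character()) {
  stopifnot(inherits(counts, "tme_counts"))
  extra <- setdiff(mito_gene_ids, counts$gene_ids)
  if (length(extra)) stop("mito_gene_ids not in matrix: ",
                          paste(utils::head(extra, 5), collapse = ", "))
  v <- counts$values
  n_umi <- Matrix::colSums(v)
  n_genes <- Matrix::colSums(v > 0)
  if (length(mito_gene_ids)) {
    mito <- Matrix::colSums(v[mito_gene_ids, , drop = FALSE])
  } else {
    warning("no mitochondrial genes supplied; mito_fraction set to 0")
    mito <- rep(0, length(n_umi))
  }
  mito_fraction <- ifelse(n_umi > 0, mito / n_umi, 0)
  data.frame(cell_id = counts$cell_ids,
             n_genes_detected = as.integer(n_genes),
             n_umi = as.integer(n_umi),
             mito_fraction = as.numeric(mito_fraction),
             stringsAsFactors = FALSE)
}

#' Quality-control thresholds
#'
#' All bounds are strict: cells with more than `min_genes` and fewer than
#' `max_genes` detected genes, mitochondrial fraction below `max_mito`,
#' and (UMI platforms only) more than `min_umi` UMIs are kept.
#'
#' @param min_genes,max_genes exclusive bounds on detected genes.
#' @param max_mito exclusive upper bound on mitochondrial fraction.
#' @param min_umi exclusive lower bound on total UMIs (UMI platforms only).
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_genes = 200, max_genes = 6000,
                          max_mito = 0.25, min_umi = 400) {
  if (min_genes >= max_genes) stop("min_genes must be < max_genes")
  if (max_mito <= 0 || max_mito > 1) stop("max_mito must be in (0, 1]")
  structure(list(min_genes = min_genes, max_genes = max_genes,
                 max_mito = max_mito, min_umi = min_umi),
            class = "qc_thresholds")
}

#' Filter cells on QC statistics
#'
#' @param qc data.frame from [compute_cell_qc()].
#' @param thresholds a [qc_thresholds()] object.
#' @param platform `"umi"` (all four criteria) or `"full_length"` (the UMI
#'   criterion is skipped).
#' @return Logical keep-mask over the rows of `qc`, with an `attrition`
#'   attribute recording input/kept/removed counts.
#' @export
filter_cells <- function(qc, thresholds = qc_thresholds(),
                         platform = c("umi", "full_length")) {
  platform <- match.arg(platform)
  stopifnot(inherits(thresholds, "qc_thresholds"))
  keep <- qc$n_genes_detected > thresholds$min_genes &
    qc$n_genes_detected < thresholds$max_genes &
    qc$mito_fraction < thresholds$max_mito
  if (platform == "umi") keep <- keep & qc$n_umi > thresholds$min_umi
  attr(keep, "attrition") <- c(input = length(keep),
                               kept = sum(keep), removed = sum(!keep))
  verbose_message(sprintf("filter_cells: %d -> %d cells (%d removed)",
                          length(keep), sum(keep), sum(!keep)))
  keep
}

#' Log-normalize UMI counts
#'
#' value(g, c) = ln(1 + count(g, c) / total(c) * scale), the standard
#' library-size normalization with natural-log log1p.
#'
#' @param counts a [count_matrix()] with no all-zero cells (filter first).
#' @param scale scale factor (default 10,000).
#' @return An [expression_matrix()] tagged `lognorm10k`.
#' @export
lognormalize <- function(counts, scale = 1e4) {
  stopifnot(inherits(counts, "tme_counts"))
  totals <- Matrix::colSums(counts$values)
  if (any(totals == 0)) {
    stop("all-zero cell(s): ",
         paste(utils::head(counts$cell_ids[totals == 0], 5), collapse = ", "))
  }
  v <- counts$values
  if (inherits(v, "sparseMatrix")) {
    v <- methods::as(methods::as(v, "generalMatrix"), "CsparseMatrix")
    v@x <- log1p(v@x / rep.int(totals, diff(v@p)) * scale)
  } else {
    v <- log1p(sweep(v, 2, totals, "/") * scale)
  }
  expression_matrix(v, "lognorm10k", counts$gene_ids, counts$cell_ids)
}

#' Transform FPKM/TPM tables to log2(TPM/10 + 1)
#'
#' FPKM columns are first rescaled per cell to TPM (each column sums to
#' 1e6); already-TPM input passes through that rescaling unchanged. The
#' returned values are log2(TPM/10 + 1).
#'
#' @param expr an [expression_matrix()] tagged `raw_tpm` (covers raw FPKM
#'   too: the per-cell rescaling makes the two equivalent here).
#' @return An [expression_matrix()] tagged `log2tpm10`.
#' @export
tpm_transform <- function(expr) {
  stopifnot(inherits(expr, "tme_expr"))
  if (expr$transform != "raw_tpm") {
    stop("tpm_transform expects raw TPM/FPKM input, got ", expr$transform)
  }
  v <- as.matrix(expr$values)
  if (any(v < 0)) stop("negative expression values")
  totals <- colSums(v)
  if (any(totals == 0)) {
    stop("cell(s) with zero total expression: ",
         paste(utils::head(expr$cell_ids[totals == 0], 5), collapse = ", "))
  }
  tpm <- sweep(v, 2, totals, "/") * 1e6
  expression_matrix(log2(tpm / 10 + 1), "log2tpm10",
                    expr$gene_ids, expr$cell_ids)
}

#' Cell-cycle phase scores
#'
#' Tirosh-style program scoring: a cell's score for a gene set is the mean
#' expression of the set genes minus the mean expression of control genes.
#' Genes are binned into `n_bins` equal-size bins of average expression and
#' `n_ctrl` controls per set gene are drawn (with replacement) from the
#' matching bin, so the control pool matches the set's expression profile.
#'
#' @param expr an [expression_matrix()] (log-normalized values expected).
#' @param s_genes,g2m_genes character vectors of S-phase and G2M-phase
#'   program genes.
#' @param n_bins number of average-expression bins (default 25).
#' @param n_ctrl control genes drawn per set gene (default 100).
#' @param seed integer seed making the control draw reproducible.
#' @return data.frame with `cell_id`, `s_score`, `g2m_score`.
#' @export
cell_cycle_scores <- function(expr, s_genes, g2m_genes,
                              n_bins = 25, n_ctrl = 100, seed = 1) {
  stopifnot(inherits(expr, "tme_expr"))
  v <- as.matrix(expr$values)
  avg <- rowMeans(v)
  # equal-size bins by rank of average expression
  bin <- ceiling(rank(avg, ties.method = "first") / length(avg) * n_bins)
  score_one <- function(set_genes) {
    set_genes <- intersect(set_genes, expr$gene_ids)
    if (!length(set_genes)) stop("gene set has empty intersection with matrix")
    set_idx <- match(set_genes, expr$gene_ids)
    ctrl_idx <- unlist(lapply(set_idx, function(i) {
      pool <- which(bin == bin[i])
      pool[sample.int(length(pool), n_ctrl, replace = TRUE)]
    }))
    colMeans(v[set_idx, , drop = FALSE]) -
      colMeans(v[ctrl_idx, , drop = FALSE])
  }
  withr::with_seed(seed, {
    s_score <- score_one(s_genes)
    g2m_score <- score_one(g2m_genes)
  })
  data.frame(cell_id = expr$cell_ids, s_score = as.numeric(s_score),
             g2m_score = as.numeric(g2m_score), stringsAsFactors = FALSE)
}

#' Select highly variable genes by variance-stabilizing transformation
#'
#' Fits a loess trend of log10(variance) on log10(mean) over genes with
#' nonzero variance, standardizes each gene's counts by the trend-predicted
#' standard deviation, clips the standardized values at `clip` in absolute
#' value, and ranks genes by the variance of the clipped standardized
#' values.
#'
#' @param counts a [count_matrix()] with at least 2 cells.
#' @param n number of genes to select (default 2,000).
#' @param loess_span span of the mean-variance trend fit (default 0.3).
#' @param clip clip value for standardized counts; default `sqrt(n_cells)`.
#' @return A list of class `hvg_result`: `stats` (per-gene data.frame with
#'   `gene_id`, `mean`, `variance`, `expected_variance`,
#'   `standardized_variance`) and `selected` (the top-`n` gene ids, sorted
#'   by standardized variance, descending).
#' @export
select_hvg_vst <- function(counts, n = 2000, loess_span = 0.3, clip = NULL) {
  stopifnot(inherits(counts, "tme_counts"))
  v <- counts$values
  n_cells <- ncol(v)
  if (n_cells < 2) stop("need at least 2 cells")
  if (is.null(clip)) clip <- sqrt(n_cells)
  mu <- as.numeric(Matrix::rowMeans(v))
  # rowwise variance, sparse-aware
  ex2 <- as.numeric(Matrix::rowMeans(v^2))
  vv <- (ex2 - mu^2) * n_cells / (n_cells - 1)
  vv <- pmax(vv, 0)
  nz <- vv > 0
  if (sum(nz) < 2) stop("fewer than 2 genes with nonzero variance")
  fit <- stats::loess(log10(vv[nz]) ~ log10(mu[nz]), span = loess_span,
                      degree = 2)
  exp_var <- rep(0, length(mu))
  exp_var[nz] <- 10^stats::predict(fit)
  exp_sd <- sqrt(exp_var)

  # variance of clipped standardized values; zeros handled in bulk
  dense <- as.matrix(v)
  std_var <- rep(0, length(mu))
  idx <- which(nz)
  for (g in idx) {
    z <- (dense[g, ] - mu[g]) / exp_sd[g]
    z <- pmin(pmax(z, -clip), clip)
    std_var[g] <- stats::var(z)
  }
  stats_df <- data.frame(gene_id = counts$gene_ids, mean = mu, variance = vv,
                         expected_variance = exp_var,
                         standardized_variance = std_var,
                         stringsAsFactors = FALSE)
  n_avail <- sum(nz)
  if (n_avail < n) {
    warning(sprintf("only %d genes with nonzero variance; selecting all",
                    n_avail))
  }
  ord <- order(-stats_df$standardized_variance, stats_df$gene_id)
  sel <- stats_df$gene_id[ord][seq_len(min(n, n_avail))]
  structure(list(stats = stats_df, selected = sel), class = "hvg_result")
}

#' Regress out nuisance covariates and scale
#'
#' Per gene: ordinary-least-squares residuals against the covariate design
#' (with intercept; factors expand to indicators; rank-deficient designs
#' are handled by the pivoted QR projection), then center to mean 0, scale
#' to unit variance and clip at `+/- clip_value`. Constant genes map to
#' all-zero rows.
#'
#' @param expr an [expression_matrix()].
#' @param covariates data.frame of per-cell covariates (numeric and/or
#'   factor/character columns), rows aligned with the cells of `expr`.
#' @param clip_value clip bound on the scaled residuals (default 10).
#' @return An [expression_matrix()] tagged `scaled`.
#' @export
regress_and_scale <- function(expr, covariates, clip_value = 10) {
  stopifnot(inherits(expr, "tme_expr"))
  if (nrow(covariates) != length(expr$cell_ids)) {
    stop("covariate rows must match the number of cells")
  }
  covariates <- as.data.frame(covariates)
  chr <- vapply(covariates, is.character, logical(1))
  covariates[chr] <- lapply(covariates[chr], factor)
  X <- stats::model.matrix(~ ., data = covariates)
  qrX <- qr(X)
  Y <- t(as.matrix(expr$values))          # cells x genes
  res <- qr.resid(qrX, Y)                 # projection residuals
  res <- scale(res, center = TRUE, scale = FALSE)
  sds <- apply(res, 2, stats::sd)
  keep <- sds > 1e-8   # residual-degenerate genes become all-zero rows
  res[, keep] <- sweep(res[, keep, drop = FALSE], 2, sds[keep], "/")
  res[, !keep] <- 0
  res <- pmin(pmax(res, -clip_value), clip_value)
  expression_matrix(t(res), "scaled", expr$gene_ids, expr$cell_ids)
}
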