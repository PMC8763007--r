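# Small simulation configs and independent reference implementations used
# across the suite. The oracles deliberately share no code with the package:
# they are slow, loop-based transliterations of the defining formulas.

small_sim <- function(n_cells = 400, n_genes = 600, seed = 11, ...) {
  args <- list(n_cells = n_cells, n_genes = n_genes, seed = seed,
               n_signature_genes_per_subtype = 15,
               n_marker_genes_per_type = 10)
  dots <- list(...)
  args[names(dots)] <- dots
  simulate_tme_counts(do.call(sim_config, args))
}

# loop-based ssGSEA: weighted in-set ECDF minus out-of-set ECDF, integrated
ssgsea_brute <- function(expr, set, alpha = 0.25) {
  genes <- names(expr)
  n <- length(genes)
  ord_genes <- genes[order(-expr, genes)]
  rank_score <- stats::setNames(n:1, ord_genes)
  k <- sum(ord_genes %in% set)
  total_w <- 0
  for (g in ord_genes) {
    if (g %in% set) total_w <- total_w + rank_score[[g]]^alpha
  }
  score <- 0
  for (i in seq_len(n)) {
    pin <- 0
    pout <- 0
    for (j in seq_len(i)) {
      gj <- ord_genes[j]
      if (gj %in% set) pin <- pin + rank_score[[gj]]^alpha else pout <- pout + 1
    }
    score <- score + pin / total_w - pout / (n - k)
  }
  score
}

# direct VST ranking: per-gene trend-standardized clipped variance,
# computed gene by gene on a dense matrix
hvg_brute <- function(counts_mat, n_top, span = 0.3, clip = NULL) {
  nc <- ncol(counts_mat)
  if (is.null(clip)) clip <- sqrt(nc)
  mu <- apply(counts_mat, 1, mean)
  vv <- apply(counts_mat, 1, stats::var)
  nz <- which(vv > 0)
  lx <- log10(mu[nz])
  ly <- log10(vv[nz])
  fit <- stats::loess(ly ~ lx, span = span, degree = 2)
  sv <- numeric(nrow(counts_mat))
  for (g in nz) {
    esd <- sqrt(10^stats::predict(fit, data.frame(lx = log10(mu[g]))))
    z <- (counts_mat[g, ] - mu[g]) / esd
    z[z > clip] <- clip
    z[z < -clip] <- -clip
    sv[g] <- stats::var(z)
  }
  ids <- rownames(counts_mat)
  ids[order(-sv, ids)][seq_len(min(n_top, length(nz)))]
}

# adjusted Rand index from the contingency table (closed form)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  idx <- sum_comb(tab)
  e1 <- sum_comb(rowSums(tab))
  e2 <- sum_comb(colSums(tab))
  expected <- e1 * e2 / choose(n, 2)
  (idx - expected) / ((e1 + e2) / 2 - expected)
}
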