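toy_counts <- function(m, genes = sprintf("g%d", seq_len(nrow(m))),
                       cells = sprintf("c%d", seq_len(ncol(m)))) {
  count_matrix(m, genes, cells)
}

test_that("compute_cell_qc does the stated arithmetic", {
  m <- cbind(c(3, 0, 1), c(0, 0, 0))
  cm <- toy_counts(m, genes = c("geneA", "geneB", "MT-1"))
  qc <- compute_cell_qc(cm, "MT-1")
  expect_equal(qc$n_genes_detected, c(2, 0))
  expect_equal(qc$n_umi, c(4, 0))
  expect_equal(qc$mito_fraction, c(0.25, 0))
  expect_warning(qc0 <- compute_cell_qc(cm, character()), "no mitochondrial")
  expect_equal(qc0$mito_fraction, c(0, 0))
})

test_that("filter_cells applies strict bounds, UMI rule only on UMI platforms", {
  qc <- data.frame(
    cell_id = sprintf("c%d", 1:5),
    n_genes_detected = c(201, 200, 5000, 5999, 6000),
    n_umi = c(401, 10000, 500, 401, 5000),
    mito_fraction = c(0.249, 0.0, 0.25, 0.249, 0.1))
  keep <- filter_cells(qc, qc_thresholds(), "umi")
  expect_identical(as.logical(keep), c(TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(attr(keep, "attrition"),
               c(input = 5L, kept = 2L, removed = 3L))

  # the >400 UMI criterion only applies on UMI platforms
  qc_fl <- data.frame(cell_id = "c1", n_genes_detected = 300, n_umi = 10,
                      mito_fraction = 0.01)
  expect_true(filter_cells(qc_fl, qc_thresholds(), "full_length")[1])
  expect_false(filter_cells(qc_fl, qc_thresholds(), "umi")[1])
})

test_that("relaxing any threshold never removes a kept cell", {
  sim <- small_sim(n_cells = 200, n_genes = 300, seed = 17)
  qc <- compute_cell_qc(sim$counts, sim$genes$gene_id[sim$genes$mito])
  base <- filter_cells(qc, qc_thresholds(min_genes = 150, max_genes = 280,
                                         max_mito = 0.02, min_umi = 350),
                       "umi")
  relaxed <- list(
    qc_thresholds(min_genes = 100, max_genes = 280, max_mito = 0.02, min_umi = 350),
    qc_thresholds(min_genes = 150, max_genes = 500, max_mito = 0.02, min_umi = 350),
    qc_thresholds(min_genes = 150, max_genes = 280, max_mito = 0.10, min_umi = 350),
    qc_thresholds(min_genes = 150, max_genes = 280, max_mito = 0.02, min_umi = 100))
  for (th in relaxed) {
    keep2 <- filter_cells(qc, th, "umi")
    expect_true(all(keep2[base]))
  }
})

test_that("lognormalize matches hand arithmetic and its sum identity", {
  m <- cbind(c(5, 5), c(0, 3))
  cm <- toy_counts(m)
  ln <- lognormalize(cm)
  expect_identical(ln$transform, "lognorm10k")
  expect_equal(ln$values[, 1], c(g1 = log(1 + 5000), g2 = log(1 + 5000)))
  expect_equal(as.numeric(ln$values[1, 2]), 0)
  # a single expressed gene always maps to ln(1 + scale)
  expect_equal(as.numeric(ln$values[2, 2]), log(1 + 10000))

  sim <- small_sim(n_cells = 100, n_genes = 300, seed = 23)
  ln2 <- lognormalize(sim$counts)
  sums <- colSums(exp(as.matrix(ln2$values)) - 1)
  expect_true(all(abs(sums - 1e4) / 1e4 < 1e-6))

  cm0 <- toy_counts(cbind(c(1, 0), c(0, 0)))
  expect_error(lognormalize(cm0), "c2")
})

test_that("tpm_transform rescales FPKM and applies log2(TPM/10 + 1)", {
  fpkm <- expression_matrix(cbind(c(1, 1, 2)), "raw_tpm",
                            gene_ids = c("a", "b", "c"), cell_ids = "c1")
  out <- tpm_transform(fpkm)
  expect_identical(out$transform, "log2tpm10")
  expect_equal(as.numeric(out$values),
               c(log2(25001), log2(25001), log2(50001)))
  # TPM = 10 maps exactly to 1; TPM = 0 to 0
  v <- c(10, 1e6 - 10, 0)
  tp <- expression_matrix(cbind(v), "raw_tpm",
                          gene_ids = c("a", "b", "c"), cell_ids = "c1")
  out2 <- tpm_transform(tp)
  expect_equal(as.numeric(out2$values[1, 1]), 1)
  expect_equal(as.numeric(out2$values[3, 1]), 0)
})

test_that("cell-cycle scoring is symmetric, seeded, and finds planted programs", {
  # identically expressed genes: set mean equals control mean exactly
  m <- matrix(rep(c(1, 2, 3, 4), each = 6), 6, 4)
  em <- expression_matrix(m, "lognorm10k", sprintf("g%d", 1:6),
                          sprintf("c%d", 1:4))
  sc <- cell_cycle_scores(em, s_genes = c("g1", "g2"),
                          g2m_genes = c("g5", "g6"), seed = 1)
  expect_true(all(abs(sc$s_score) < 1e-12))
  expect_true(all(abs(sc$g2m_score) < 1e-12))

  sim <- simulate_tme_counts(sim_config(
    n_cells = 600, n_genes = 800, cc_cell_fraction = 0.4,
    cc_log_fold_change = 2, seed = 41))
  ln <- lognormalize(sim$counts)
  sc2 <- cell_cycle_scores(ln, sim$cc_genes$s, sim$cc_genes$g2m, seed = 7)
  s_cells <- sim$cells$phase == "s"
  expect_gte(mean(sc2$s_score[s_cells] > sc2$g2m_score[s_cells]), 0.95)
  g2m_cells <- sim$cells$phase == "g2m"
  expect_gte(mean(sc2$g2m_score[g2m_cells] > sc2$s_score[g2m_cells]), 0.95)

  sc3 <- cell_cycle_scores(ln, sim$cc_genes$s, sim$cc_genes$g2m, seed = 7)
  expect_identical(sc2, sc3)
  expect_error(cell_cycle_scores(em, "absent_gene", c("g5", "g6")),
               "empty intersection")
})

test_that("VST selection matches a brute-force implementation and basic rules", {
  withr::local_seed(51)
  m <- matrix(rnbinom(200 * 60, mu = 3, size = 2), 200, 60,
              dimnames = list(sprintf("g%03d", 1:200), sprintf("c%d", 1:60)))
  m[1, ] <- 7L  # constant gene
  cm <- count_matrix(m, rownames(m), colnames(m))
  res <- select_hvg_vst(cm, n = 40)
  expect_identical(res$selected, hvg_brute(m, 40))
  expect_equal(res$stats$standardized_variance[1], 0)
  expect_false("g001" %in% res$selected)
  # selected list sorted by standardized variance, descending
  sv <- res$stats$standardized_variance[match(res$selected,
                                              res$stats$gene_id)]
  expect_true(all(diff(sv) <= 1e-12))
  expect_warning(res_all <- select_hvg_vst(cm, n = 1000), "nonzero variance")
  expect_equal(length(res_all$selected), 199)
})

test_that("planted overdispersed genes are recovered by VST selection", {
  withr::local_seed(52)
  n_genes <- 500; n_cells <- 300
  mu <- rlnorm(n_genes, 0.5, 0.6)
  disp <- rep(0.2, n_genes)
  hot <- sample.int(n_genes, 25)
  disp[hot] <- 2
  m <- matrix(rnbinom(n_genes * n_cells, mu = rep(mu, n_cells),
                      size = rep(1 / disp, n_cells)), n_genes, n_cells,
              dimnames = list(sprintf("g%03d", 1:n_genes),
                              sprintf("c%d", 1:n_cells)))
  res <- select_hvg_vst(count_matrix(m, rownames(m), colnames(m)), n = 50)
  sens <- mean(rownames(m)[hot] %in% res$selected)
  expect_gte(sens, 0.95)
})

test_that("regression removes covariates and scaling standardizes genes", {
  withr::local_seed(53)
  n <- 80
  x <- rnorm(n)
  xc <- x - mean(x)
  g_orth <- rnorm(n)
  g_orth <- g_orth - mean(g_orth)
  g_orth <- g_orth - xc * sum(g_orth * xc) / sum(xc^2)  # exactly orthogonal
  m <- rbind(g_orth, x, rnorm(n), rnorm(n) + 2 * x)
  em <- expression_matrix(m, "lognorm10k", sprintf("g%d", 1:4),
                          sprintf("c%d", 1:n))
  cov <- data.frame(x = x, batch = rep(c("a", "b"), n / 2))

  # covariate orthogonal to the gene: residuals are the centered expression
  em1 <- expression_matrix(rbind(g1 = g_orth), "lognorm10k", "g1",
                           sprintf("c%d", 1:n))
  got1 <- regress_and_scale(em1, data.frame(x = xc))$values[1, ]
  ref1 <- g_orth / stats::sd(g_orth)
  expect_equal(as.numeric(got1), as.numeric(ref1), tolerance = 1e-8)

  # scaled residuals agree with an lm fit per gene (independent route)
  X <- model.matrix(~ x + batch, cov)
  sc <- regress_and_scale(em, cov)
  for (g in c(1, 3, 4)) {
    ref <- stats::lm.fit(X, m[g, ])$residuals
    ref <- (ref - mean(ref)) / stats::sd(ref)
    expect_equal(as.numeric(sc$values[g, ]), as.numeric(ref),
                 tolerance = 1e-8)
  }

  # a gene exactly equal to a covariate has (unscaled) residuals ~ 0
  raw_resid <- qr.resid(qr(X), m[2, ])
  expect_lt(max(abs(raw_resid)), 1e-8)
  # per-gene mean 0, variance 1 after scaling (non-degenerate genes)
  v <- sc$values
  expect_true(all(abs(rowMeans(v)) < 1e-10))
  expect_true(all(abs(apply(v[c(1, 3, 4), ], 1, stats::var) - 1) < 1e-6))
  expect_true(all(v[2, ] == 0))  # residual-degenerate gene zeroed

  # collinear design is accepted; mismatched cells are not
  cov2 <- cbind(cov, x_dup = x)
  expect_silent(regress_and_scale(em, cov2))
  expect_error(regress_and_scale(em, cov[1:10, ]), "match")
})

test_that("constant genes scale to all-zero rows", {
  m <- rbind(rep(5, 20), rnorm(20))
  em <- expression_matrix(m, "lognorm10k", c("g1", "g2"),
                          sprintf("c%d", 1:20))
  sc <- regress_and_scale(em, data.frame(x = rnorm(20)))
  expect_true(all(sc$values[1, ] == 0))
})
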