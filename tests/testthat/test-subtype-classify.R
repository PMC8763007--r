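ec_sim <- function(n_cells, lfc, seed, n_genes = 1000) {
  simulate_tme_counts(sim_config(
    n_cells = n_cells, n_genes = n_genes,
    major_type_proportions = c(EC = 1),
    signature_log_fold_change = lfc, seed = seed))
}

test_that("centroid models are per-subtype means over the signature union", {
  genes <- sprintf("g%d", 1:6)
  m <- matrix(seq_len(24), 6, 4,
              dimnames = list(genes, sprintf("c%d", 1:4)))
  em <- expression_matrix(m, "lognorm10k", genes, colnames(m))
  sigs <- list(A = c("g1", "g2"), B = c("g3", "g4"))
  labels <- c("A", "A", "B", "B")
  expect_warning(expect_warning(  # < 5 cells warned once per subtype
    models <- build_subtype_models(em, labels, sigs),
    "reference cells"), "reference cells")
  expect_identical(rownames(models$centroids), c("g1", "g2", "g3", "g4"))
  expect_equal(models$centroids[, "A"], rowMeans(m[1:4, 1:2]))
  expect_equal(models$centroids[, "B"], rowMeans(m[1:4, 3:4]))

  # permuting reference cell order leaves centroids unchanged
  perm <- c(3, 1, 4, 2)
  em_p <- expression_matrix(m[, perm], "lognorm10k", genes,
                            colnames(m)[perm])
  models_p <- suppressWarnings(
    build_subtype_models(em_p, labels[perm], sigs))
  expect_equal(models$centroids, models_p$centroids)

  # one cell per subtype: centroids equal those cells' profiles
  em1 <- expression_matrix(m[, 1:2], "lognorm10k", genes, c("c1", "c2"))
  m1 <- suppressWarnings(build_subtype_models(em1, c("A", "B"), sigs))
  expect_equal(unname(m1$centroids[, "A"]), unname(m[1:4, 1]))
  expect_error(suppressWarnings(
    build_subtype_models(em1, c("A", NA), sigs)), "no reference cells")
})

test_that("reference centroids are elevated on their own signature genes", {
  sim <- ec_sim(600, lfc = 2, seed = 71)
  ln <- lognormalize(sim$counts)
  truth <- sim$cells$subtype
  models <- build_subtype_models(ln, truth, sim$signatures)
  for (s in names(sim$signatures)) {
    own <- models$centroids[sim$signatures[[s]], s]
    others <- unlist(lapply(setdiff(names(sim$signatures), s),
                            function(o) models$centroids[sim$signatures[[o]], s]))
    expect_lt(stats::wilcox.test(own, others,
                                 alternative = "greater")$p.value, 0.01)
  }
})

test_that("a cell identical to a centroid is recovered with p = 1/(n_perm+1)", {
  sim <- ec_sim(200, lfc = 2, seed = 72, n_genes = 600)
  ln <- lognormalize(sim$counts)
  models <- build_subtype_models(ln, sim$cells$subtype, sim$signatures)
  em <- expression_matrix(models$centroids[, "C3_CA4", drop = FALSE],
                          "lognorm10k", gene_ids = rownames(models$centroids),
                          cell_ids = "probe")
  asg <- classify_cells(em, models, n_perm = 99, seed = 1)
  expect_identical(asg$label, "C3_CA4")
  expect_equal(asg$similarity, 1.0)
  expect_equal(asg$p_min, 1 / 100)
})

test_that("similarity is invariant to per-cell affine transforms", {
  sim <- ec_sim(40, lfc = 2, seed = 73, n_genes = 600)
  ln <- lognormalize(sim$counts)
  models <- suppressWarnings(
    build_subtype_models(ln, sim$cells$subtype, sim$signatures))
  a1 <- classify_cells(ln, models, n_perm = 50, seed = 4)
  shifted <- expression_matrix(as.matrix(ln$values) * 3.7 + 2.2,
                               "lognorm10k", ln$gene_ids, ln$cell_ids)
  a2 <- classify_cells(shifted, models, n_perm = 50, seed = 4)
  expect_equal(a1$similarity, a2$similarity, tolerance = 1e-12)
  expect_identical(a1$label, a2$label)
})

test_that("planted EC subtypes are classified accurately and self-consistently", {
  ref <- ec_sim(600, lfc = 2, seed = 74)
  ref_ln <- lognormalize(ref$counts)
  models <- build_subtype_models(ref_ln, ref$cells$subtype, ref$signatures)

  # self-consistency on the reference cells
  self <- classify_cells(ref_ln, models, n_perm = 100, seed = 5)
  expect_gte(mean(self$label == ref$cells$subtype), 0.95)

  # transfer to an independently simulated query dataset
  qry <- ec_sim(400, lfc = 2, seed = 75)
  qry_ln <- lognormalize(qry$counts)
  asg <- classify_cells(qry_ln, models, n_perm = 100, seed = 6)
  expect_gte(mean(asg$label == qry$cells$subtype), 0.9)
})

test_that("cells with permuted signature values are rejected as unknown", {
  withr::local_seed(76)
  ref <- ec_sim(400, lfc = 2, seed = 70, n_genes = 600)
  models <- build_subtype_models(lognormalize(ref$counts),
                                 ref$cells$subtype, ref$signatures)
  sim <- ec_sim(150, lfc = 2, seed = 77, n_genes = 600)
  ln <- lognormalize(sim$counts)
  v <- as.matrix(ln$values)
  union_genes <- models$genes
  for (ci in seq_len(ncol(v))) {
    v[union_genes, ci] <- v[sample(union_genes), ci]
  }
  shuf <- expression_matrix(v, "lognorm10k", ln$gene_ids, ln$cell_ids)
  asg <- classify_cells(shuf, models, allow_unknown = TRUE,
                        alpha = 0.01, n_perm = 200, seed = 7)
  expect_gte(mean(asg$label == "unknown"), 0.9)
})

test_that("zero-variance cells over the union become unknown with a warning", {
  genes <- sprintf("g%d", 1:4)
  m <- cbind(flat = rep(1, 4), ok = c(5, 1, 0, 0))
  rownames(m) <- genes
  em <- expression_matrix(m, "lognorm10k", genes, colnames(m))
  models <- build_indicator_models(list(A = c("g1", "g2"), B = c("g3", "g4")))
  expect_warning(asg <- classify_cells(em, models, n_perm = 20, seed = 1),
                 "zero variance")
  expect_identical(asg$label, c("unknown", "A"))
  expect_true(is.na(asg$similarity[1]))
})

test_that("classification accuracy is monotone in signature fold change", {
  accs <- vapply(c(0.5, 1.5, 3), function(lfc) {
    sim <- ec_sim(250, lfc = lfc, seed = 78, n_genes = 600)
    ln <- lognormalize(sim$counts)
    asg <- classify_cells(ln, build_indicator_models(sim$signatures),
                          n_perm = 20, seed = 8)
    mean(asg$label == sim$cells$subtype)
  }, numeric(1))
  mc_err <- 3 * sqrt(0.25 / 250)
  expect_true(all(diff(accs) > -mc_err))
})

test_that("heatmap matrix shows block structure and deterministic order", {
  sim <- ec_sim(300, lfc = 2, seed = 79, n_genes = 600)
  ln <- lognormalize(sim$counts)
  asg <- classify_cells(ln, build_indicator_models(sim$signatures),
                        n_perm = 50, seed = 9)
  hm <- subtype_heatmap_matrix(ln, asg, sim$signatures)
  expect_equal(nrow(hm$matrix), length(unique(unlist(sim$signatures))))
  expect_equal(ncol(hm$matrix), nrow(asg))
  # mean z within matching (gene-block, cell-block) exceeds off-block by > 1
  within <- off <- c()
  for (s in names(sim$signatures)) {
    rb <- hm$row_blocks[hm$row_blocks$name == s, ]
    cb <- hm$col_blocks[hm$col_blocks$name == s, ]
    if (cb$end < cb$start) next
    rows <- rb$start:rb$end
    cols <- cb$start:cb$end
    within <- c(within, mean(hm$matrix[rows, cols]))
    off <- c(off, mean(hm$matrix[rows, -cols]))
  }
  expect_gt(mean(within) - mean(off), 1)
  hm2 <- subtype_heatmap_matrix(ln, asg, sim$signatures)
  expect_identical(hm, hm2)

  # empty subtype gives a zero-width block, no error
  asg_drop <- asg
  asg_drop$label[asg_drop$label == "C5_PROX1"] <- "C1_ESM1"
  hm3 <- subtype_heatmap_matrix(ln, asg_drop, sim$signatures)
  b <- hm3$col_blocks[hm3$col_blocks$name == "C5_PROX1", ]
  expect_true(b$end < b$start)
})
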