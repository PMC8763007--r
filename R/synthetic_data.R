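#' Configuration for the synthetic tumor-microenvironment simulator
#'
#' Defines a negative-binomial (gamma-Poisson) scRNA-seq count model with
#' planted major cell types, planted endothelial (EC) and
#' fibroblast/myofibroblast subtypes, per-sample multiplicative batch
#' effects, per-cell sequencing-depth factors, mitochondrial genes and an
#' optional planted cell-cycle program. Defaults describe a mid-sized
#' droplet (UMI) dataset: 2,000 cells, 3,000 genes, six patient samples
#' (half tumor, half adjacent normal), 40 signature genes per stromal
#' subtype at log2 fold change 2.
#'
#' @param n_cells,n_genes positive integers.
#' @param major_type_proportions named fractions over major cell types;
#'   must sum to 1. Names "EC" and "Fibroblast" mark the stromal types
#'   that carry subtypes.
#' @param ec_subtype_proportions,fibro_subtype_proportions named fractions
#'   over stromal subtypes within EC / fibroblast cells; each sums to 1.
#' @param n_signature_genes_per_subtype signature genes planted per stromal
#'   subtype (default 40).
#' @param signature_log_fold_change log2 fold change applied to a cell's
#'   own subtype signature genes.
#' @param n_marker_genes_per_type,marker_log_fold_change the analogous
#'   planted marker program distinguishing major cell types (what cluster
#'   annotation keys on).
#' @param n_samples number of patient samples; cells are assigned to
#'   samples uniformly. `tumor_fraction` of the samples are labeled tumor.
#' @param sample_effect_sd sd (log scale) of the multiplicative per
#'   (sample, gene) batch effect; 0 disables it.
#' @param mito_gene_fraction fraction of genes flagged mitochondrial
#'   (named `MT-*`).
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of the
#'   per-gene baseline mean expression.
#' @param dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2), shared across genes and cells.
#' @param sequencing_depth_mean,sequencing_depth_sd mean and sd of the
#'   log-normal per-cell depth factor.
#' @param cc_cell_fraction fraction of cells given a planted cell-cycle
#'   program (split evenly between S and G2M); 0 disables. Default 0.15,
#'   a typical cycling fraction in tumor tissue.
#' @param n_cc_genes genes per cell-cycle program (S and G2M each).
#' @param cc_log_fold_change log2 fold change of the planted cycle program.
#' @param tumor_fraction fraction of samples labeled tumor.
#' @param age_range integer pair; each sample's patient age is uniform on
#'   this range (all cells of a sample share one age).
#' @param platform `"umi"` or `"full_length"`.
#' @param seed integer seed; identical configs give bit-identical data.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_cells = 2000,
                       n_genes = 3000,
                       major_type_proportions = c(
                         B = 0.12, EC = 0.10, Epithelial = 0.25,
                         Fibroblast = 0.10, Myeloid = 0.13, T = 0.30),
                       ec_subtype_proportions = c(
                         C1_ESM1 = 0.2, C2_ACKR1 = 0.2, C3_CA4 = 0.2,
                         C4_FBLN5 = 0.2, C5_PROX1 = 0.2),
                       fibro_subtype_proportions = c(
                         C7_MYH11 = 0.2, C8_RGS5 = 0.2, C9_CFD = 0.2,
                         C10_COMP = 0.2, C11_SERPINE1 = 0.2),
                       n_signature_genes_per_subtype = 40,
                       signature_log_fold_change = 2,
                       n_marker_genes_per_type = 25,
                       marker_log_fold_change = 2,
                       n_samples = 6,
                       sample_effect_sd = 0.15,
                       mito_gene_fraction = 0.01,
                       baseline_meanlog = 0,
                       baseline_sdlog = 1,
                       dispersion = 0.5,
                       sequencing_depth_mean = 1.5,
                       sequencing_depth_sd = 0.3,
                       cc_cell_fraction = 0.15,
                       n_cc_genes = 20,
                       cc_log_fold_change = 1.5,
                       tumor_fraction = 0.5,
                       age_range = c(30, 85),
                       platform = c("umi", "full_length"),
                       seed = 1) {
  platform <- match.arg(platform)
  cfg <- list(
    n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
    major_type_proportions = major_type_proportions,
    ec_subtype_proportions = ec_subtype_proportions,
    fibro_subtype_proportions = fibro_subtype_proportions,
    n_signature_genes_per_subtype = as.integer(n_signature_genes_per_subtype),
    signature_log_fold_change = signature_log_fold_change,
    n_marker_genes_per_type = as.integer(n_marker_genes_per_type),
    marker_log_fold_change = marker_log_fold_change,
    n_samples = as.integer(n_samples),
    sample_effect_sd = sample_effect_sd,
    mito_gene_fraction = mito_gene_fraction,
    baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog,
    dispersion = dispersion,
    sequencing_depth_mean = sequencing_depth_mean,
    sequencing_depth_sd = sequencing_depth_sd,
    cc_cell_fraction = cc_cell_fraction,
    n_cc_genes = as.integer(n_cc_genes),
    cc_log_fold_change = cc_log_fold_change,
    tumor_fraction = tumor_fraction,
    age_range = as.integer(age_range),
    platform = platform, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_cells <= 0 || cfg$n_genes <= 0) stop("n_cells and n_genes must be positive")
  check_props <- function(p, what) {
    if (is.null(names(p)) || any(!nzchar(names(p)))) {
      stop(what, " must be a named vector")
    }
    if (any(p < 0)) stop(what, " must be non-negative")
    if (abs(sum(p) - 1) > 1e-9) stop(what, " must sum to 1 (got ", sum(p), ")")
  }
  check_props(cfg$major_type_proportions, "major_type_proportions")
  check_props(cfg$ec_subtype_proportions, "ec_subtype_proportions")
  check_props(cfg$fibro_subtype_proportions, "fibro_subtype_proportions")
  n_subtypes <- 0L
  if ("EC" %in% names(cfg$major_type_proportions) &&
      cfg$major_type_proportions[["EC"]] > 0) {
    n_subtypes <- n_subtypes + length(cfg$ec_subtype_proportions)
  }
  if ("Fibroblast" %in% names(cfg$major_type_proportions) &&
      cfg$major_type_proportions[["Fibroblast"]] > 0) {
    n_subtypes <- n_subtypes + length(cfg$fibro_subtype_proportions)
  }
  if (cfg$mito_gene_fraction < 0 || cfg$mito_gene_fraction >= 1) {
    stop("mito_gene_fraction must be in [0, 1)")
  }
  n_types <- length(cfg$major_type_proportions)
  n_cc <- if (cfg$cc_cell_fraction > 0) 2L * cfg$n_cc_genes else 0L
  n_mito <- floor(cfg$mito_gene_fraction * cfg$n_genes)
  reserved <- cfg$n_signature_genes_per_subtype * n_subtypes +
    cfg$n_marker_genes_per_type * n_types + n_cc + n_mito
  if (reserved > cfg$n_genes) {
    stop(sprintf(
      "infeasible config: %d genes reserved for signatures/markers/cycle/mito but only %d genes",
      reserved, cfg$n_genes))
  }
  if (cfg$dispersion <= 0) stop("dispersion must be positive")
  if (cfg$signature_log_fold_change < 0) stop("signature_log_fold_change must be >= 0")
  if (cfg$n_samples < 1) stop("n_samples must be >= 1")
  if (length(cfg$age_range) != 2 || cfg$age_range[1] > cfg$age_range[2]) {
    stop("age_range must be an increasing integer pair")
  }
  invisible(cfg)
}

# internal: deterministic gene/cell layout and expected-mean model shared by
# both platform flavors
build_sim_model <- function(cfg) {
  n_mito <- floor(cfg$mito_gene_fraction * cfg$n_genes)
  n_reg <- cfg$n_genes - n_mito
  gene_ids <- c(sprintf("G%05d", seq_len(n_reg)),
                if (n_mito > 0) sprintf("MT-%d", seq_len(n_mito)))
  cell_ids <- sprintf("cell%05d", seq_len(cfg$n_cells))

  types <- names(cfg$major_type_proportions)
  # cell assignments
  major <- sample(types, cfg$n_cells, replace = TRUE,
                  prob = cfg$major_type_proportions)
  subtype <- rep(NA_character_, cfg$n_cells)
  is_ec <- major == "EC"
  if (any(is_ec)) {
    subtype[is_ec] <- sample(names(cfg$ec_subtype_proportions), sum(is_ec),
                             replace = TRUE, prob = cfg$ec_subtype_proportions)
  }
  is_fib <- major == "Fibroblast"
  if (any(is_fib)) {
    subtype[is_fib] <- sample(names(cfg$fibro_subtype_proportions), sum(is_fib),
                              replace = TRUE, prob = cfg$fibro_subtype_proportions)
  }
  sample_id <- sprintf("S%02d", sample.int(cfg$n_samples, cfg$n_cells,
                                           replace = TRUE))
  samples <- sprintf("S%02d", seq_len(cfg$n_samples))
  n_tumor <- round(cfg$tumor_fraction * cfg$n_samples)
  sample_tissue <- stats::setNames(
    c(rep("tumor", n_tumor), rep("normal", cfg$n_samples - n_tumor)), samples)
  sample_age <- stats::setNames(
    sample(seq(cfg$age_range[1], cfg$age_range[2]), cfg$n_samples,
           replace = TRUE), samples)

  # cell-cycle phase
  phase <- rep("none", cfg$n_cells)
  if (cfg$cc_cell_fraction > 0) {
    cyc <- stats::runif(cfg$n_cells) < cfg$cc_cell_fraction
    phase[cyc] <- sample(c("s", "g2m"), sum(cyc), replace = TRUE)
  }

  # gene layout: disjoint blocks among non-mito genes
  cursor <- 0L
  take <- function(k) {
    idx <- cursor + seq_len(k); cursor <<- cursor + k; idx
  }
  marker_idx <- stats::setNames(
    lapply(types, function(t) take(cfg$n_marker_genes_per_type)), types)
  subtypes <- character()
  if (any(is_ec)) subtypes <- c(subtypes, names(cfg$ec_subtype_proportions))
  if (any(is_fib)) subtypes <- c(subtypes, names(cfg$fibro_subtype_proportions))
  sig_idx <- stats::setNames(
    lapply(subtypes, function(s) take(cfg$n_signature_genes_per_subtype)),
    subtypes)
  cc_idx <- list(s = integer(), g2m = integer())
  if (cfg$cc_cell_fraction > 0) {
    cc_idx$s <- take(cfg$n_cc_genes)
    cc_idx$g2m <- take(cfg$n_cc_genes)
  }

  base <- stats::rlnorm(cfg$n_genes, cfg$baseline_meanlog, cfg$baseline_sdlog)
  if (cfg$sequencing_depth_sd > 0) {
    cv <- cfg$sequencing_depth_sd / cfg$sequencing_depth_mean
    sdlog <- sqrt(log(1 + cv^2))
    depth <- stats::rlnorm(cfg$n_cells,
                           log(cfg$sequencing_depth_mean) - sdlog^2 / 2, sdlog)
  } else {
    depth <- rep(cfg$sequencing_depth_mean, cfg$n_cells)
  }
  batch <- if (cfg$sample_effect_sd > 0) {
    matrix(stats::rlnorm(cfg$n_genes * cfg$n_samples,
                         -cfg$sample_effect_sd^2 / 2, cfg$sample_effect_sd),
           cfg$n_genes, cfg$n_samples, dimnames = list(NULL, samples))
  } else {
    matrix(1, cfg$n_genes, cfg$n_samples, dimnames = list(NULL, samples))
  }

  # mean matrix: baseline x depth x batch x planted fold changes
  mu <- outer(base, depth)
  mu <- mu * batch[, sample_id, drop = FALSE]
  mfc <- 2^cfg$marker_log_fold_change
  for (t in types) {
    cells_t <- which(major == t)
    if (length(cells_t)) mu[marker_idx[[t]], cells_t] <-
        mu[marker_idx[[t]], cells_t] * mfc
  }
  sfc <- 2^cfg$signature_log_fold_change
  for (s in subtypes) {
    cells_s <- which(!is.na(subtype) & subtype == s)
    if (length(cells_s)) mu[sig_idx[[s]], cells_s] <-
        mu[sig_idx[[s]], cells_s] * sfc
  }
  cfc <- 2^cfg$cc_log_fold_change
  for (ph in c("s", "g2m")) {
    cells_p <- which(phase == ph)
    if (length(cells_p) && length(cc_idx[[ph]])) {
      mu[cc_idx[[ph]], cells_p] <- mu[cc_idx[[ph]], cells_p] * cfc
    }
  }

  gene_sig <- rep(NA_character_, cfg$n_genes)
  for (s in subtypes) gene_sig[sig_idx[[s]]] <- s
  gene_cc <- rep("none", cfg$n_genes)
  gene_cc[cc_idx$s] <- "s"; gene_cc[cc_idx$g2m] <- "g2m"
  mito_flag <- startsWith(gene_ids, "MT-")

  list(
    gene_ids = gene_ids, cell_ids = cell_ids, mu = mu,
    cells = data.frame(
      cell_id = cell_ids, major_type = major, subtype = subtype,
      sample_id = sample_id, tissue = unname(sample_tissue[sample_id]),
      age = unname(sample_age[sample_id]), phase = phase,
      stringsAsFactors = FALSE),
    genes = data.frame(
      gene_id = gene_ids, signature_of = gene_sig, mito = mito_flag,
      cell_cycle = gene_cc, stringsAsFactors = FALSE),
    signatures = stats::setNames(
      lapply(sig_idx, function(ix) gene_ids[ix]), names(sig_idx)),
    markers = stats::setNames(
      lapply(marker_idx, function(ix) gene_ids[ix]), names(marker_idx)),
    cc_genes = list(s = gene_ids[cc_idx$s], g2m = gene_ids[cc_idx$g2m]))
}

#' Simulate a UMI-platform tumor-microenvironment count dataset
#'
#' Draws negative-binomial counts with mean = per-gene baseline x per-cell
#' depth factor x per-(sample, gene) batch effect x planted fold changes
#' (major-type markers, stromal subtype signatures, optional cell-cycle
#' program), and returns the counts together with full ground truth and the
#' planted gene sets.
#'
#' @param config a [sim_config()] with `platform = "umi"`.
#' @return A list with elements `counts` ([count_matrix()]), `cells`
#'   (per-cell ground truth data.frame), `genes` (per-gene flags),
#'   `signatures` (list: subtype -> planted signature genes), `markers`
#'   (list: major type -> planted marker genes), `cc_genes` (planted S and
#'   G2M gene lists), `mu` (the expected-count matrix) and `config`.
#' @export
simulate_tme_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$platform != "umi") stop("config platform must be 'umi'")
  validate_sim_config(config)
  withr::with_seed(config$seed, {
    model <- build_sim_model(config)
    counts <- matrix(
      stats::rnbinom(length(model$mu), mu = model$mu,
                     size = 1 / config$dispersion),
      nrow = config$n_genes,
      dimnames = list(model$gene_ids, model$cell_ids))
  })
  list(counts = count_matrix(Matrix::Matrix(counts, sparse = TRUE),
                             model$gene_ids, model$cell_ids),
       cells = model$cells, genes = model$genes,
       signatures = model$signatures, markers = model$markers,
       cc_genes = model$cc_genes, mu = model$mu, config = config)
}

#' Simulate a full-length-platform (TPM) dataset
#'
#' Same generative model as [simulate_tme_counts()], then each cell's
#' counts are rescaled to transcripts-per-million, so every column sums to
#' 1e6. Gene lengths are taken as equal (length normalization is assumed to
#' have happened upstream of TPM).
#'
#' @param config a [sim_config()] with `platform = "full_length"`.
#' @return As [simulate_tme_counts()], but with element `tpm` (an
#'   [expression_matrix()] tagged `raw_tpm`) in place of `counts`.
#' @export
simulate_full_length <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$platform != "full_length") {
    stop("config platform must be 'full_length'")
  }
  cfg_umi <- config
  cfg_umi$platform <- "umi"
  class(cfg_umi) <- "sim_config"
  sim <- simulate_tme_counts(cfg_umi)
  counts <- as.matrix(sim$counts$values)
  totals <- colSums(counts)
  if (any(totals == 0)) {
    stop("simulated cell(s) with zero total counts; increase depth or gene means")
  }
  tpm <- sweep(counts, 2, totals, "/") * 1e6
  sim$counts <- NULL
  sim$tpm <- expression_matrix(tpm, "raw_tpm", gene_ids = rownames(tpm),
                               cell_ids = colnames(tpm))
  sim$config <- config
  sim
}

#' Write a simulated dataset to disk as analysis-ready fixtures
#'
#' Writes a 10x-style MTX triplet (`matrix.mtx`, `features.tsv`,
#' `barcodes.tsv`), a per-cell metadata CSV (`metadata.csv`) and a GMT of
#' the planted subtype signatures (`signatures.gmt`). Round-trips
#' losslessly through [read_10x_mtx()], [read_metadata()] and [read_gmt()].
#'
#' @param sim result of [simulate_tme_counts()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_fixture <- function(sim, out_dir) {
  if (is.null(sim$counts)) stop("write_fixture expects a UMI (count) dataset")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_mtx_integer(sim$counts$values, file.path(out_dir, "matrix.mtx"))
  writeLines(paste(sim$counts$gene_ids, sim$counts$gene_ids, sep = "\t"),
             file.path(out_dir, "features.tsv"))
  writeLines(sim$counts$cell_ids, file.path(out_dir, "barcodes.tsv"))
  meta <- sim$cells
  meta$cancer_type <- "synthetic"
  meta$platform <- sim$config$platform
  utils::write.csv(meta, file.path(out_dir, "metadata.csv"), row.names = FALSE)
  if (length(sim$signatures)) {
    write_gmt(sim$signatures, file.path(out_dir, "signatures.gmt"),
              description = "planted")
  }
  invisible(out_dir)
}
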