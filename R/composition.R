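#' Composition table of cell-type counts and fractions by group
#'
#' Counts cells per (group, type) and computes within-group fractions. For
#' stromal subtype tables the denominator convention matters: pass `types`
#' to restrict to a set of subtypes (for example the five common
#' fibroblast/myofibroblast subtypes) so fractions are computed among those
#' only, excluding unknown and tissue-specific calls.
#'
#' @param cells data.frame of cell records.
#' @param group_keys character vector of grouping column names (e.g.
#'   `c("dataset", "tissue")`).
#' @param type_field column holding the cell type or subtype.
#' @param types optional character vector restricting (and ordering) the
#'   types entering the denominator; cells with other types are dropped.
#' @return data.frame with the group columns, `group` (keys joined by
#'   `"|"`), `cell_type`, `count`, `fraction`; within each group the
#'   fractions sum to 1. Empty groups are dropped with a warning.
#' @export
composition_table <- function(cells, group_keys, type_field, types = NULL) {
  missing_cols <- setdiff(c(group_keys, type_field), names(cells))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!is.null(types)) {
    n0 <- nrow(cells)
    cells <- cells[cells[[type_field]] %in% types, , drop = FALSE]
    verbose_message(sprintf("composition_table: %d of %d cells within restricted types",
                            nrow(cells), n0))
  }
  if (!nrow(cells)) {
    warning("no cells after type restriction; empty table")
    return(data.frame(group = character(), cell_type = character(),
                      count = integer(), fraction = numeric()))
  }
  grp <- do.call(paste, c(cells[group_keys], sep = "|"))
  type <- as.character(cells[[type_field]])
  type_levels <- if (is.null(types)) sort(unique(type)) else types
  tab <- table(factor(grp), factor(type, levels = type_levels))
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out) <- c("group", "cell_type", "count")
  key_map <- unique(data.frame(group = grp, cells[group_keys],
                               stringsAsFactors = FALSE))
  out <- merge(key_map, out, by = "group", sort = TRUE)
  totals <- stats::ave(out$count, out$group, FUN = sum)
  empty <- unique(out$group[totals == 0])
  if (length(empty)) {
    warning("empty group(s) dropped: ", paste(empty, collapse = ", "))
    out <- out[totals > 0, , drop = FALSE]
    totals <- totals[totals > 0]
  }
  out$fraction <- out$count / totals
  rownames(out) <- NULL
  out
}

#' Per-type fraction differences between two groups
#'
#' @param table data.frame from [composition_table()].
#' @param group_a,group_b values of the `group` column to compare.
#' @return data.frame with `cell_type`, `fraction_a`, `fraction_b`,
#'   `delta` (a minus b); types absent from a group count as fraction 0.
#' @export
compare_groups <- function(table, group_a, group_b) {
  for (g in c(group_a, group_b)) {
    if (!g %in% table$group) stop("group not in table: ", g)
  }
  types <- unique(table$cell_type)
  frac_of <- function(g) {
    sub <- table[table$group == g, ]
    stats::setNames(sub$fraction, sub$cell_type)[types]
  }
  fa <- frac_of(group_a); fb <- frac_of(group_b)
  fa[is.na(fa)] <- 0; fb[is.na(fb)] <- 0
  data.frame(cell_type = types, fraction_a = as.numeric(fa),
             fraction_b = as.numeric(fb),
             delta = as.numeric(fa - fb), stringsAsFactors = FALSE)
}

#' Stratify cells into young/old age classes
#'
#' young: age < cutoff; old: age >= cutoff; unknown: age missing (such
#' cells are excluded from age-stratified comparisons).
#'
#' @param metadata data.frame with an `age` column (years, may be `NA`).
#' @param cutoff age cutoff in years (default 60).
#' @return The input with an added `age_class` column in
#'   `{"young", "old", "unknown"}`.
#' @export
stratify_age <- function(metadata, cutoff = 60) {
  if (!"age" %in% names(metadata)) stop("metadata must have an age column")
  age <- metadata$age
  metadata$age_class <- ifelse(is.na(age), "unknown",
                               ifelse(age < cutoff, "young", "old"))
  metadata
}

#' Check per-type count columns against declared dataset totals
#'
#' Sums each dataset column of a cell-type count table and compares it with
#' the declared total for that column. Mismatches are reported, not raised:
#' published summary tables occasionally disagree internally and the report
#' makes that visible.
#'
#' @param counts data.frame with a `cell_type` column and one numeric
#'   column per dataset/tissue.
#' @param declared_totals named numeric vector: column name -> declared
#'   total cell count.
#' @return data.frame with `column`, `computed`, `declared`, `match`.
#' @export
consistency_check <- function(counts, declared_totals) {
  cols <- intersect(names(declared_totals), names(counts))
  if (!length(cols)) {
    return(data.frame(column = character(), computed = numeric(),
                      declared = numeric(), match = logical()))
  }
  computed <- vapply(cols, function(cn) sum(counts[[cn]]), numeric(1))
  declared <- declared_totals[cols]
  data.frame(column = cols, computed = as.numeric(computed),
             declared = as.numeric(declared),
             match = as.numeric(computed) == as.numeric(declared),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Transcribed pan-cancer reference composition tables
#'
#' Loads the package's transcribed copies of the published pan-cancer
#' survey summary tables: the dataset summary (cohort sizes and declared
#' tumor/normal cell totals after QC) and the per-cell-type count tables
#' for tumor and adjacent normal tissues. They are transcribed verbatim,
#' including a known internal inconsistency in the gastric row of the
#' summary table (it duplicates the CRC totals and does not match the
#' gastric columns of the count tables); [consistency_check()] surfaces
#' this rather than correcting it.
#'
#' @return A list with data.frames `summary`, `tumor_counts`,
#'   `normal_counts`.
#' @export
pancancer_tables <- function() {
  path <- function(f) {
    p <- system.file("extdata", f, package = "tmestroma")
    if (!nzchar(p)) stop("fixture not found: ", f)
    p
  }
  list(
    summary = utils::read.csv(path("pancancer_dataset_summary.csv"),
                              stringsAsFactors = FALSE),
    tumor_counts = utils::read.csv(path("pancancer_tumor_counts.csv"),
                                   stringsAsFactors = FALSE, check.names = FALSE),
    normal_counts = utils::read.csv(path("pancancer_normal_counts.csv"),
                                    stringsAsFactors = FALSE, check.names = FALSE))
}
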