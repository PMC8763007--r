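#' Read a 10x Genomics MTX triplet directory
#'
#' Reads `matrix.mtx` plus `features.tsv` (or `genes.tsv`) and
#' `barcodes.tsv` from a directory and returns a genes x cells count matrix
#' regardless of the on-disk orientation. The MatrixMarket header is
#' validated against the identifier files and against the actual number of
#' stored entries, so silently truncated files are rejected.
#'
#' @param dir_path directory containing the triplet.
#' @return A [count_matrix()].
#' @export
read_10x_mtx <- function(dir_path) {
  if (!dir.exists(dir_path)) stop("directory not found: ", dir_path)
  mtx_path <- file.path(dir_path, "matrix.mtx")
  feat_path <- file.path(dir_path, "features.tsv")
  if (!file.exists(feat_path)) feat_path <- file.path(dir_path, "genes.tsv")
  bc_path <- file.path(dir_path, "barcodes.tsv")
  for (p in c(mtx_path, feat_path, bc_path)) {
    if (!file.exists(p)) stop("missing file: ", p)
  }
  feats <- utils::read.delim(feat_path, header = FALSE,
                             stringsAsFactors = FALSE)
  genes <- as.character(feats[[1]])
  barcodes <- as.character(readLines(bc_path))
  barcodes <- barcodes[nzchar(barcodes)]

  lines <- readLines(mtx_path)
  if (!length(lines) || !grepl("^%%MatrixMarket", lines[1])) {
    stop("not a MatrixMarket file: ", mtx_path)
  }
  if (!grepl("coordinate", lines[1])) stop("only coordinate MTX is supported")
  body <- lines[!startsWith(lines, "%")]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) stop("MTX file has no size line")
  hdr <- scan(text = body[1], what = numeric(), quiet = TRUE)
  if (length(hdr) != 3) stop("malformed MTX size line")
  nr <- hdr[1]; nc <- hdr[2]; nnz <- hdr[3]
  entries <- body[-1]
  if (length(entries) != nnz) {
    stop(sprintf("MTX header declares %d entries but file has %d",
                 nnz, length(entries)))
  }
  if (nnz > 0) {
    dat <- utils::read.table(text = entries, colClasses = "numeric")
    if (ncol(dat) != 3) stop("malformed MTX entry lines")
    if (any(abs(dat[[3]] - round(dat[[3]])) > 1e-8)) {
      stop("non-integer entries in count MTX")
    }
    m <- Matrix::sparseMatrix(i = dat[[1]], j = dat[[2]], x = dat[[3]],
                              dims = c(nr, nc))
  } else {
    m <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                              dims = c(nr, nc))
  }
  if (nr == length(genes) && nc == length(barcodes)) {
    # genes x cells on disk
  } else if (nr == length(barcodes) && nc == length(genes)) {
    m <- Matrix::t(m)
  } else {
    stop(sprintf(
      "MTX dimensions (%d x %d) match neither %d features x %d barcodes nor its transpose",
      nr, nc, length(genes), length(barcodes)))
  }
  count_matrix(m, genes, barcodes)
}

#' Read gene sets from a GMT file
#'
#' Each line is tab-separated: set name, description, then gene symbols.
#' Gene order is preserved; duplicate genes within a set are dropped
#' (first occurrence kept); duplicate set names are an error.
#'
#' @param path path to a GMT file.
#' @return Named list mapping set name to a character vector of genes.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      stop("GMT line with fewer than 3 fields: ", substr(ln, 1, 60))
    }
    nm <- parts[1]
    if (nm %in% names(sets)) stop("duplicate gene set name: ", nm)
    genes <- parts[-(1:2)]
    genes <- genes[nzchar(genes)]
    sets[[nm]] <- genes[!duplicated(genes)]
  }
  if (any(lengths(sets) == 0)) stop("empty gene set in GMT")
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description description field written for every set.
#' @export
write_gmt <- function(sets, path, description = "na") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read per-cell metadata from CSV
#'
#' Requires columns `cell_id`, `sample_id` and `tissue`; `cancer_type`,
#' `age` and `platform` are used when present and any other columns are
#' preserved untouched. `tissue` is normalized to lower case and must be
#' "tumor" or "normal"; blank ages become `NA`.
#'
#' @param path path to the CSV file.
#' @return A data.frame of cell records.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("cell_id", "sample_id", "tissue")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing required metadata column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$cell_id)) stop("duplicate cell ids in metadata")
  df$tissue <- tolower(trimws(df$tissue))
  bad <- setdiff(unique(df$tissue), c("tumor", "normal"))
  if (length(bad)) stop("tissue values must be tumor/normal; found: ",
                        paste(bad, collapse = ", "))
  if ("age" %in% names(df)) {
    df$age <- suppressWarnings(as.numeric(df$age))
    if (any(!is.na(df$age) & df$age < 0)) stop("negative age in metadata")
  }
  if ("platform" %in% names(df)) {
    df$platform <- tolower(trimws(df$platform))
    badp <- setdiff(unique(df$platform), c("umi", "full_length"))
    if (length(badp)) stop("platform must be umi/full_length; found: ",
                           paste(badp, collapse = ", "))
  }
  df
}

#' Write a composition table to CSV
#'
#' @param table a data.frame as returned by [composition_table()].
#' @param path output path.
#' @export
write_composition <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

# internal: MatrixMarket coordinate-integer writer for count matrices
write_mtx_integer <- function(values, path) {
  m <- methods::as(methods::as(values, "generalMatrix"), "TsparseMatrix")
  header <- "%%MatrixMarket matrix coordinate integer general"
  size <- sprintf("%d %d %d", nrow(m), ncol(m), length(m@x))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(header, size), con)
  if (length(m@x)) {
    writeLines(paste(m@i + 1L, m@j + 1L, as.integer(round(m@x))), con)
  }
  invisible(path)
}

verbose_message <- function(...) {
  if (isTRUE(getOption("tmestroma.verbose", FALSE))) message(...)
  invisible(NULL)
}
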