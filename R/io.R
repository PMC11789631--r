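#' Read a 10x-style feature-barcode matrix
#'
#' Reads the standard CellRanger triplet (`matrix.mtx`, `barcodes.tsv`,
#' `features.tsv`, each optionally gzipped) from a directory into a sparse
#' genes-by-cells count matrix.
#'
#' @param directory Path containing the three files.
#' @return A `CountMatrix`: list with `counts` (a `dgCMatrix`, genes in rows,
#'   cells in columns), `feature_ids`, `feature_symbols` and `barcodes`.
#' @export
read_feature_barcode_matrix <- function(directory) {
  find_one <- function(base) {
    for (f in c(file.path(directory, base), file.path(directory, paste0(base, ".gz"))))
      if (file.exists(f)) return(f)
    stop("missing file in ", directory, ": ", base, "[.gz]", call. = FALSE)
  }
  mtx <- find_one("matrix.mtx")
  bfile <- find_one("barcodes.tsv")
  ffile <- find_one("features.tsv")

  counts <- methods::as(Matrix::readMM(.maybe_gz(mtx)), "CsparseMatrix")
  barcodes <- .read_tsv_col(bfile, 1L)
  feat <- utils::read.delim(.maybe_gz(ffile), header = FALSE,
                            stringsAsFactors = FALSE)
  feature_ids <- as.character(feat[[1L]])
  feature_symbols <- if (ncol(feat) >= 2L) as.character(feat[[2L]]) else feature_ids

  if (nrow(counts) != length(feature_ids))
    stop("matrix declares ", nrow(counts), " genes but features.tsv has ",
         length(feature_ids), call. = FALSE)
  if (ncol(counts) != length(barcodes))
    stop("matrix declares ", ncol(counts), " cells but barcodes.tsv has ",
         length(barcodes), call. = FALSE)
  if (anyDuplicated(barcodes))
    stop("duplicated cell barcodes in barcodes.tsv", call. = FALSE)
  if (any(counts@x < 0) || any(counts@x != round(counts@x)))
    stop("counts must be non-negative integers", call. = FALSE)

  count_matrix(counts, feature_ids, barcodes, feature_symbols)
}

.maybe_gz <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path) else path
}

.read_tsv_col <- function(path, col) {
  x <- utils::read.delim(.maybe_gz(path), header = FALSE,
                         stringsAsFactors = FALSE)
  as.character(x[[col]])
}

#' Construct a CountMatrix
#'
#' @param counts Sparse or dense non-negative integer matrix, genes x cells.
#' @param feature_ids,barcodes Identifier vectors matching the dimensions.
#' @param feature_symbols Optional gene symbols (default: the ids).
#' @return A `CountMatrix` object.
#' @export
count_matrix <- function(counts, feature_ids, barcodes,
                         feature_symbols = feature_ids) {
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "dMatrix")
  stopifnot(nrow(counts) == length(feature_ids),
            ncol(counts) == length(barcodes),
            length(feature_symbols) == length(feature_ids))
  if (anyDuplicated(barcodes)) stop("barcodes must be unique", call. = FALSE)
  rownames(counts) <- feature_ids
  colnames(counts) <- barcodes
  structure(list(counts = counts,
                 feature_ids = as.character(feature_ids),
                 feature_symbols = as.character(feature_symbols),
                 barcodes = as.character(barcodes)),
            class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat("CountMatrix:", length(x$feature_ids), "genes x",
      length(x$barcodes), "cells;",
      length(x$counts@x), "nonzero entries\n")
  invisible(x)
}

#' Write a feature-barcode matrix triplet
#'
#' Mirror of [read_feature_barcode_matrix()]; writes `matrix.mtx`,
#' `barcodes.tsv` and `features.tsv` (gzipped when `gzip = TRUE`) so the
#' directory round-trips through the reader.
#'
#' @param m A `CountMatrix`.
#' @param directory Output directory (created if needed).
#' @param gzip Compress the three files.
#' @return The directory path, invisibly.
#' @export
write_feature_barcode_matrix <- function(m, directory, gzip = TRUE) {
  stopifnot(inherits(m, "CountMatrix"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory))
    stop("cannot create directory: ", directory, call. = FALSE)

  mtx_plain <- file.path(directory, "matrix.mtx")
  Matrix::writeMM(m$counts, mtx_plain)
  if (gzip) {
    .gzip_file(mtx_plain)
    file.remove(mtx_plain)
  }
  .write_lines_maybe_gz(m$barcodes, file.path(directory, "barcodes.tsv"), gzip)
  feat <- paste(m$feature_ids, m$feature_symbols, "Gene Expression", sep = "\t")
  .write_lines_maybe_gz(feat, file.path(directory, "features.tsv"), gzip)
  invisible(directory)
}

.gzip_file <- function(path) {
  con <- gzfile(paste0(path, ".gz"), "wb")
  on.exit(close(con))
  writeBin(readBin(path, "raw", file.info(path)$size), con)
}

.write_lines_maybe_gz <- function(lines, path, gzip) {
  if (gzip) {
    con <- gzfile(paste0(path, ".gz"), "w")
    on.exit(close(con))
    writeLines(lines, con)
  } else {
    writeLines(lines, path)
  }
}

#' Read per-cell binary phenotype labels
#'
#' Reads a CSV with a barcode column and one or more phenotype columns whose
#' values are 0/1 (e.g. disease, age, sex coded from donor metadata), and
#' aligns the rows to a supplied barcode order.
#'
#' @param csv Path to the label CSV.  The barcode column is the first column
#'   unless a column named `barcode` exists.
#' @param barcodes Barcode order to align to (typically from a
#'   `CountMatrix`).
#' @return A `PhenotypeLabels`: data.frame with rownames = barcodes and one
#'   0/1 integer column per phenotype, rows in the order of `barcodes`.
#' @export
read_binary_labels <- function(csv, barcodes) {
  df <- utils::read.csv(csv, stringsAsFactors = FALSE, check.names = FALSE)
  bc_col <- if ("barcode" %in% names(df)) "barcode" else names(df)[1L]
  pheno_cols <- setdiff(names(df), bc_col)
  if (length(pheno_cols) == 0L)
    stop("label CSV has no phenotype columns", call. = FALSE)
  phenotype_labels(df[pheno_cols], df[[bc_col]], align_to = barcodes)
}

#' Construct PhenotypeLabels
#'
#' @param values data.frame or matrix of 0/1 values, one column per
#'   phenotype.
#' @param barcodes Cell barcodes for the rows of `values`.
#' @param align_to Optional barcode order to reorder to; every barcode in
#'   `align_to` must be present.
#' @return A `PhenotypeLabels` data.frame (rownames = barcodes).
#' @export
phenotype_labels <- function(values, barcodes, align_to = NULL) {
  values <- as.data.frame(values, stringsAsFactors = FALSE)
  if (any(!nzchar(names(values))))
    stop("phenotype names must be non-empty", call. = FALSE)
  stopifnot(nrow(values) == length(barcodes))
  for (cn in names(values)) {
    v <- values[[cn]]
    bad <- which(!(v %in% c(0, 1)))
    if (length(bad))
      stop("non-binary label value '", v[bad[1L]], "' in column '", cn,
           "', row ", bad[1L], call. = FALSE)
    values[[cn]] <- as.integer(v)
  }
  rownames(values) <- as.character(barcodes)
  if (!is.null(align_to)) {
    align_to <- as.character(align_to)
    missing <- setdiff(align_to, rownames(values))
    if (length(missing))
      stop("barcodes absent from label table: ",
           paste(utils::head(missing, 5L), collapse = ", "),
           if (length(missing) > 5L) " ..." else "", call. = FALSE)
    values <- values[align_to, , drop = FALSE]
  }
  class(values) <- c("PhenotypeLabels", "data.frame")
  values
}

#' Write phenotype labels to CSV
#' @param labels A `PhenotypeLabels`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  df <- data.frame(barcode = rownames(labels), labels,
                   check.names = FALSE, row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Latent / score CSV plumbing: cells in rows, first column `barcode`.

#' Write a latent matrix (cells x dims) to CSV
#' @param latent A `LatentMatrix`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_latent_csv <- function(latent, path) {
  df <- data.frame(barcode = rownames(latent$values), latent$values,
                   check.names = FALSE, row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a latent matrix CSV written by [write_latent_csv()]
#' @param path CSV path.
#' @return A `LatentMatrix`.
#' @export
read_latent_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  latent_matrix(m)
}

#' Write a score matrix to CSV
#' @param scores A `ScoreMatrix`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_scores_csv <- function(scores, path) {
  df <- data.frame(barcode = rownames(scores$scores), scores$scores,
                   check.names = FALSE, row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a score matrix CSV written by [write_scores_csv()]
#' @param path CSV path.
#' @return A `ScoreMatrix`.
#' @export
read_scores_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  score_matrix(m)
}
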