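# Readers and writers for the 10x-style Matrix Market triplet and
# delimited protein/label tables, plus the standard preprocessing steps:
# CLR normalization of ADT counts, variable-gene selection, and the
# train/test split.

.first_existing <- function(dir, candidates) {
  for (f in candidates) {
    p <- file.path(dir, f)
    if (file.exists(p)) return(p)
  }
  NULL
}

.read_id_column <- function(path) {
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  as.character(tab[[1]])
}

#' Read a 10x-style Matrix Market count directory
#'
#' Expects a directory containing `matrix.mtx`, a barcode list
#' (`barcodes.tsv`) and a feature list (`features.tsv` or `genes.tsv`),
#' each optionally gzipped.  The on-disk matrix may be stored either
#' genes x cells (the 10x convention) or cells x genes; orientation is
#' resolved against the barcode/feature counts and the result is always
#' cells x genes.
#'
#' @param path directory containing the triplet.
#' @return A [count_matrix()].
#' @export
read_10x_mtx <- function(path) {
  if (!dir.exists(path)) .stopf("no such directory: %s", path)
  mtx <- .first_existing(path, c("matrix.mtx", "matrix.mtx.gz"))
  bc <- .first_existing(path, c("barcodes.tsv", "barcodes.tsv.gz"))
  ft <- .first_existing(path, c("features.tsv", "features.tsv.gz",
                                "genes.tsv", "genes.tsv.gz"))
  if (is.null(mtx)) .stopf("matrix.mtx not found in %s", path)
  if (is.null(bc)) .stopf("barcodes.tsv not found in %s", path)
  if (is.null(ft)) .stopf("features.tsv/genes.tsv not found in %s", path)

  m <- as.matrix(Matrix::readMM(mtx))
  barcodes <- .read_id_column(bc)
  features <- .read_id_column(ft)

  if (nrow(m) == length(features) && ncol(m) == length(barcodes)) {
    m <- t(m)                       # genes x cells on disk -> transpose
  } else if (!(nrow(m) == length(barcodes) && ncol(m) == length(features))) {
    .stopf(paste0("matrix is %d x %d but there are %d barcodes and ",
                  "%d features; cannot resolve orientation"),
           nrow(m), ncol(m), length(barcodes), length(features))
  } else if (nrow(m) == ncol(m) && length(barcodes) == length(features)) {
    # square and ambiguous: keep as cells x genes (documented convention)
    NULL
  }
  if (any(m < 0) || any(m != floor(m)))
    .stopf("expression matrix contains negative or non-integer values")
  count_matrix(m, cell_ids = barcodes, gene_ids = features)
}

#' Write a count matrix as a Matrix Market triplet
#'
#' Writes `matrix.mtx` (genes x cells, the 10x convention),
#' `barcodes.tsv` and `features.tsv` into `path`.
#'
#' @param counts a [count_matrix()].
#' @param path output directory (created if missing).
#' @export
write_10x_mtx <- function(counts, path) {
  stopifnot(inherits(counts, "count_matrix"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  m <- Matrix::Matrix(t(counts$values), sparse = TRUE)
  Matrix::writeMM(m, file.path(path, "matrix.mtx"))
  writeLines(counts$cell_ids, file.path(path, "barcodes.tsv"))
  writeLines(counts$gene_ids, file.path(path, "features.tsv"))
  invisible(path)
}

#' Read a delimited cells x features table
#'
#' A header row plus a cell-identifier first column; used for protein
#' (ADT) tables and per-cell label tables.
#'
#' @param path file path (TSV or CSV inferred from the extension).
#' @param scale for protein tables, `"raw"` or `"clr"`.
#' @return A [protein_table()].
#' @export
read_protein_table <- function(path, scale = c("raw", "clr")) {
  scale <- match.arg(scale)
  sep <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
  tab <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
  ids <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) .stopf("non-numeric protein values in %s", path)
  protein_table(m, cell_ids = ids, protein_ids = colnames(tab)[-1],
                scale = scale)
}

#' Write a cells x features table
#'
#' @param x a [protein_table()] or a numeric matrix with rownames.
#' @param path output path; TSV unless the extension is `.csv`.
#' @export
write_protein_table <- function(x, path) {
  if (inherits(x, "protein_table")) x <- x$values
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- data.frame(cell = rownames(x), x, check.names = FALSE)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Centered log-ratio normalization of ADT counts
#'
#' The CITE-seq convention for antibody-derived-tag counts: per cell,
#' `clr_p = log1p(x_p) - mean_q log1p(x_q)`, so each cell's transformed
#' values have zero mean across proteins.  The `margin = "proteins"`
#' variant centers each protein across cells instead.
#'
#' @param table a raw-scale [protein_table()].
#' @param margin `"cells"` (compositional, default) or `"proteins"`.
#' @return A CLR-scale [protein_table()].
#' @export
clr_normalize <- function(table, margin = c("cells", "proteins")) {
  stopifnot(inherits(table, "protein_table"))
  margin <- match.arg(margin)
  if (table$scale != "raw")
    .stopf("clr_normalize() expects a raw-scale protein table")
  lx <- log1p(table$values)
  v <- if (margin == "cells") lx - rowMeans(lx)
       else sweep(lx, 2, colMeans(lx))
  protein_table(v, cell_ids = table$cell_ids,
                protein_ids = table$protein_ids, scale = "clr")
}

#' Select the most variable genes
#'
#' Keeps the `n_top` genes with the largest variance of `log1p(count)`
#' across cells, preserving the original gene order.  Ties break by gene
#' identifier so the selection is deterministic.
#'
#' @param counts a [count_matrix()].
#' @param n_top number of genes to keep (1..n_genes).
#' @return A [count_matrix()] restricted to the selected genes.
#' @export
select_variable_genes <- function(counts, n_top) {
  stopifnot(inherits(counts, "count_matrix"))
  if (!is.numeric(n_top) || n_top <= 0)
    .stopf("n_top must be a positive count")
  n_top <- as.integer(n_top)
  if (n_top > ncol(counts$values))
    .stopf("n_top (%d) exceeds number of genes (%d)",
           n_top, ncol(counts$values))
  v <- apply(log1p(counts$values), 2, var)
  ord <- order(-v, counts$gene_ids)
  keep <- sort(ord[seq_len(n_top)])
  subset_cells(counts, genes = keep)
}

#' Split cells into disjoint train and test sets
#'
#' Uniform random (unstratified) partition with `round(train_fraction *
#' N)` training cells, seeded for reproducibility.
#'
#' @param cell_ids character vector of cell identifiers (N >= 2).
#' @param train_fraction fraction of cells assigned to training,
#'   in (0, 1); default 0.9.
#' @param seed integer seed.
#' @return A list with character vectors `train` and `test`.
#' @export
split_train_test <- function(cell_ids, train_fraction = 0.9, seed = 1L) {
  n <- length(cell_ids)
  if (n < 2) .stopf("need at least 2 cells to split (got %d)", n)
  if (!is.numeric(train_fraction) || train_fraction <= 0 ||
      train_fraction >= 1)
    .stopf("train_fraction must lie strictly between 0 and 1")
  set.seed(seed)
  n_train <- round(train_fraction * n)
  n_train <- min(max(n_train, 1L), n - 1L)
  idx <- sample.int(n, n_train)
  list(train = cell_ids[sort(idx)], test = cell_ids[sort(setdiff(seq_len(n), idx))])
}

#' Read a per-cell label table
#'
#' Two delimited columns with a header: cell identifier and label.
#'
#' @param path file path.
#' @return Named character vector (names are cell identifiers).
#' @export
read_labels <- function(path) {
  sep <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
  tab <- read.delim(path, sep = sep, header = TRUE,
                    stringsAsFactors = FALSE)
  setNames(as.character(tab[[2]]), as.character(tab[[1]]))
}

#' @rdname read_labels
#' @param labels named character vector (names = cell identifiers).
#' @export
write_labels <- function(labels, path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  write.table(data.frame(cell = names(labels), label = unname(labels)),
              path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
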