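#' Single-cell count matrix
#'
#' A light container for a cells x genes matrix of non-negative integer
#' expression counts with cell and gene identifiers.  The cells-by-genes
#' orientation is the package-wide convention; readers normalize on-disk
#' orientation on import.
#'
#' @param values numeric matrix, cells in rows, genes in columns;
#'   all entries must be non-negative integers.
#' @param cell_ids character vector of unique cell identifiers
#'   (defaults to rownames of `values`).
#' @param gene_ids character vector of gene identifiers (defaults to
#'   colnames of `values`).
#' @return An object of class `count_matrix` with fields `values`
#'   (integer storage), `cell_ids` and `gene_ids`.
#' @examples
#' cm <- count_matrix(matrix(0:5, nrow = 2,
#'                           dimnames = list(c("c1", "c2"), NULL)))
#' dim(cm)
#' @export
count_matrix <- function(values, cell_ids = rownames(values),
                         gene_ids = colnames(values)) {
  values <- as.matrix(values)
  if (!is.numeric(values)) .stopf("count values must be numeric")
  if (any(!is.finite(values)) || any(values < 0) || any(values != floor(values)))
    .stopf("count matrix must contain finite non-negative integers")
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(nrow(values)))
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(ncol(values)))
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (length(cell_ids) != nrow(values))
    .stopf("cell_ids length (%d) != number of rows (%d)",
           length(cell_ids), nrow(values))
  if (length(gene_ids) != ncol(values))
    .stopf("gene_ids length (%d) != number of columns (%d)",
           length(gene_ids), ncol(values))
  if (anyDuplicated(cell_ids))
    .stopf("duplicate cell identifiers are not allowed")
  storage.mode(values) <- "integer"
  dimnames(values) <- list(cell_ids, gene_ids)
  structure(list(values = values, cell_ids = cell_ids, gene_ids = gene_ids),
            class = "count_matrix")
}

#' @export
dim.count_matrix <- function(x) dim(x$values)

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d cells x %d genes; total count %.0f\n",
              nrow(x$values), ncol(x$values), sum(as.numeric(x$values))))
  invisible(x)
}

#' Subset a count matrix by cells and/or genes
#'
#' @param x a [count_matrix()].
#' @param cells,genes index vectors (integer, logical or character) into
#'   cells and genes; `NULL` keeps everything.
#' @return A `count_matrix`.
#' @export
subset_cells <- function(x, cells = NULL, genes = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  v <- x$values
  if (!is.null(cells)) v <- v[cells, , drop = FALSE]
  if (!is.null(genes)) v <- v[, genes, drop = FALSE]
  count_matrix(v)
}

#' Surface-protein (ADT) table
#'
#' A cells x proteins matrix of antibody-derived-tag measurements, either
#' raw counts or CLR-normalized values (see [clr_normalize()]).  Rows may
#' cover only a labeled subset of the cells in a companion count matrix.
#'
#' @param values numeric matrix, cells in rows, proteins in columns.
#' @param cell_ids,protein_ids identifiers (default: dimnames).
#' @param scale `"raw"` (non-negative counts) or `"clr"`.
#' @return An object of class `protein_table`.
#' @export
protein_table <- function(values, cell_ids = rownames(values),
                          protein_ids = colnames(values),
                          scale = c("raw", "clr")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (!is.numeric(values) || any(!is.finite(values)))
    .stopf("protein values must be finite numeric")
  if (scale == "raw" && any(values < 0))
    .stopf("raw-scale protein counts must be non-negative")
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(nrow(values)))
  if (is.null(protein_ids)) protein_ids <- paste0("protein", seq_len(ncol(values)))
  cell_ids <- as.character(cell_ids)
  protein_ids <- as.character(protein_ids)
  stopifnot(length(cell_ids) == nrow(values),
            length(protein_ids) == ncol(values))
  if (anyDuplicated(cell_ids)) .stopf("duplicate cell identifiers")
  dimnames(values) <- list(cell_ids, protein_ids)
  structure(list(values = values, cell_ids = cell_ids,
                 protein_ids = protein_ids, scale = scale),
            class = "protein_table")
}

#' @export
dim.protein_table <- function(x) dim(x$values)

#' @export
print.protein_table <- function(x, ...) {
  cat(sprintf("<protein_table> %d cells x %d proteins (%s scale)\n",
              nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

#' Marker gene/protein pair list
#'
#' Designated correspondences between genes and the surface proteins they
#' encode, used for unbiased evaluation of denoised expression.
#'
#' @param gene_ids,protein_ids equal-length character vectors.
#' @return A data.frame of class `marker_pairs` with columns `gene` and
#'   `protein`.
#' @export
marker_pairs <- function(gene_ids, protein_ids) {
  if (length(gene_ids) != length(protein_ids))
    .stopf("gene_ids and protein_ids must have equal length")
  structure(data.frame(gene = as.character(gene_ids),
                       protein = as.character(protein_ids),
                       stringsAsFactors = FALSE),
            class = c("marker_pairs", "data.frame"))
}
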