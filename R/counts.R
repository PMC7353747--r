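#' Construct a cell-by-gene count matrix
#'
#' The basic container used throughout the package: raw non-negative integer
#' mRNA counts with cells as rows and genes as columns, plus identifiers and
#' per-cell library sizes (row sums).
#'
#' @param counts Numeric matrix (or `Matrix` sparse matrix) of non-negative
#'   integers, cells x genes.
#' @param gene_ids Character vector of unique gene identifiers, one per column.
#' @param cell_ids Character vector of cell identifiers, one per row.
#' @return An object of class `disc_counts` with elements `counts`
#'   (base dense matrix), `gene_ids`, `cell_ids` and `library_sizes`.
#' @examples
#' cm <- count_matrix(matrix(c(0, 2, 1, 5), 2, 2),
#'                    gene_ids = c("g1", "g2"), cell_ids = c("c1", "c2"))
#' cm$library_sizes
#' @export
count_matrix <- function(counts, gene_ids = NULL, cell_ids = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(gene_ids)) {
    gene_ids <- colnames(counts)
    if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(ncol(counts)))
  }
  if (is.null(cell_ids)) {
    cell_ids <- rownames(counts)
    if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(nrow(counts)))
  }
  if (length(gene_ids) != ncol(counts)) {
    stop("gene_ids length does not match the number of genes (columns)")
  }
  if (length(cell_ids) != nrow(counts)) {
    stop("cell_ids length does not match the number of cells (rows)")
  }
  if (anyDuplicated(gene_ids)) stop("duplicate gene_ids are not allowed")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(abs(counts - round(counts)) > 1e-8)) {
    stop("counts must be integers")
  }
  dimnames(counts) <- list(cell_ids, gene_ids)
  structure(
    list(counts = counts,
         gene_ids = as.character(gene_ids),
         cell_ids = as.character(cell_ids),
         library_sizes = rowSums(counts)),
    class = "disc_counts")
}

#' @export
print.disc_counts <- function(x, ...) {
  cat(sprintf("disc_counts: %d cells x %d genes, median library size %.0f\n",
              nrow(x$counts), ncol(x$counts), stats::median(x$library_sizes)))
  invisible(x)
}

#' @export
dim.disc_counts <- function(x) dim(x$counts)

check_counts <- function(x) {
  if (!inherits(x, "disc_counts")) stop("expected a disc_counts object")
  x
}
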