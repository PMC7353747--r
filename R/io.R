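# Readers and writers for the standard exchange formats: 10x-style
# MatrixMarket triplets, dense CSV/TSV with labels, and the chunked binary
# store (stream.R).  Cells are rows and genes are columns everywhere inside
# the package; MTX triplets follow the 10x convention of genes as rows on
# disk and are transposed on read/write.

#' Read a count matrix
#'
#' @param path For `mtx_triplet`, a directory containing `matrix.mtx` plus
#'   `genes.tsv` (or `features.tsv`) and `barcodes.tsv`, or the path of the
#'   `.mtx` file itself; for `csv`/`tsv` a delimited file with row and
#'   column labels; for `store` a chunk-store directory.
#' @param format One of `"mtx_triplet"`, `"csv"`, `"tsv"`, `"store"`.
#' @param genes_as_rows For `csv`/`tsv`: set `TRUE` when the file stores
#'   genes as rows (it is transposed on read).  Orientation is never
#'   guessed.
#' @param real Accept non-integer values (e.g. an imputed matrix) and return
#'   a plain numeric matrix instead of a [count_matrix()].
#' @return A [count_matrix()] object (or a numeric matrix when
#'   `real = TRUE`).
#' @export
read_matrix <- function(path, format = c("mtx_triplet", "csv", "tsv", "store"),
                        genes_as_rows = FALSE, real = FALSE) {
  as_result <- function(m, genes, cells) {
    if (real) {
      dimnames(m) <- list(cells, genes)
      return(m)
    }
    count_matrix(m, gene_ids = genes, cell_ids = cells)
  }
  format <- match.arg(format)
  if (!file.exists(path)) stop("input not found: ", path)
  if (format == "store") return(store_to_counts(open_chunk_store(path)))
  if (format == "mtx_triplet") {
    dir <- if (dir.exists(path)) path else dirname(path)
    mtx <- if (dir.exists(path)) file.path(path, "matrix.mtx") else path
    if (!file.exists(mtx)) stop("matrix.mtx not found in ", dir)
    gf <- file.path(dir, c("genes.tsv", "features.tsv"))
    gf <- gf[file.exists(gf)][1]
    bf <- file.path(dir, "barcodes.tsv")
    if (is.na(gf) || !file.exists(bf)) {
      stop("gene/feature and barcode files are required next to ", mtx)
    }
    m <- as.matrix(Matrix::readMM(mtx))   # genes x cells on disk
    genes <- utils::read.delim(gf, header = FALSE,
                               stringsAsFactors = FALSE)[[1]]
    cells <- utils::read.delim(bf, header = FALSE,
                               stringsAsFactors = FALSE)[[1]]
    if (length(genes) != nrow(m) || length(cells) != ncol(m)) {
      stop("dimension mismatch between matrix.mtx (", nrow(m), " x ", ncol(m),
           ") and id files (", length(genes), " genes, ", length(cells),
           " barcodes)")
    }
    return(as_result(t(m), genes, cells))
  }
  sep <- if (format == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                          check.names = FALSE)
  m <- as.matrix(df)
  if (length(m) == 0L) stop("empty matrix in ", path)
  if (genes_as_rows) m <- t(m)
  as_result(m, colnames(m), rownames(m))
}

#' Write a count matrix as a 10x-style MTX triplet
#'
#' @param counts A [count_matrix()] object (or a `disc_imputation`, whose
#'   imputed counts are written as a real-valued MatrixMarket file).
#' @param dir Output directory (`matrix.mtx`, `genes.tsv`, `barcodes.tsv`).
#' @return The directory, invisibly.
#' @export
write_mtx <- function(counts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (inherits(counts, "disc_imputation")) {
    m <- counts$imputed_counts
    genes <- counts$gene_ids; cells <- counts$cell_ids
  } else {
    counts <- check_counts(counts)
    m <- counts$counts
    genes <- counts$gene_ids; cells <- counts$cell_ids
  }
  Matrix::writeMM(Matrix::Matrix(t(m), sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  writeLines(genes, file.path(dir, "genes.tsv"))
  writeLines(cells, file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Write a matrix as labelled CSV (cells as rows)
#'
#' @param m Matrix with dimnames, or `disc_counts`/`disc_imputation`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_csv_matrix <- function(m, path) {
  if (inherits(m, "disc_counts")) m <- m$counts
  if (inherits(m, "disc_imputation")) m <- m$imputed_counts
  df <- data.frame(cell_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write imputation results
#'
#' Writes the imputed matrix (CSV and/or MTX triplet), the compressed latent
#' features as TSV (`cell_id` plus W columns) and, when given, the
#' gene-selection report.
#'
#' @param result A `disc_imputation` from [impute()].
#' @param prefix Output path prefix.
#' @param formats Subset of `c("csv", "mtx")`.
#' @param report Optional gene-selection report from [gene_selection()].
#' @return Character vector of files/directories written, invisibly.
#' @export
write_results <- function(result, prefix, formats = "csv", report = NULL) {
  stopifnot(inherits(result, "disc_imputation"))
  out <- character(0)
  if ("csv" %in% formats) {
    f <- paste0(prefix, "_imputed.csv")
    write_csv_matrix(result, f)
    out <- c(out, f)
  }
  if ("mtx" %in% formats) {
    d <- paste0(prefix, "_imputed_mtx")
    write_mtx(result, d)
    out <- c(out, d)
  }
  lat <- data.frame(cell_id = result$cell_ids, result$latent_features,
                    check.names = FALSE)
  names(lat)[-1L] <- paste0("latent_", seq_len(ncol(result$latent_features)))
  lf <- paste0(prefix, "_latent.tsv")
  utils::write.table(lat, lf, sep = "\t", row.names = FALSE, quote = FALSE)
  out <- c(out, lf)
  if (!is.null(report)) {
    rf <- paste0(prefix, "_gene_selection.tsv")
    utils::write.table(report, rf, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    out <- c(out, rf)
  }
  invisible(out)
}

#' Gene-selection filter
#'
#' Removes genes expressed in fewer than `max(ceiling(n_cells / 1000), 10)`
#' cells and genes whose maximum mRNA count is 1 (regardless of prevalence).
#'
#' @param counts A [count_matrix()] object.
#' @return List with `counts` (filtered [count_matrix()]) and `report`, a
#'   data frame with columns `gene_id`, `kept` and `reason`
#'   (`low_prevalence` or `max_count_one` for removed genes).
#' @export
gene_selection <- function(counts) {
  counts <- check_counts(counts)
  n <- nrow(counts$counts)
  thr <- max(ceiling(n / 1000), 10)
  npos <- colSums(counts$counts > 0)
  cmax <- apply(counts$counts, 2L, max)
  low <- npos < thr
  one <- cmax <= 1
  keep <- !low & !one
  if (!any(keep)) stop("gene selection removed all genes")
  reason <- rep(NA_character_, length(keep))
  reason[one & !low] <- "max_count_one"
  reason[low] <- "low_prevalence"
  report <- data.frame(gene_id = counts$gene_ids, kept = keep,
                       reason = reason, stringsAsFactors = FALSE)
  filtered <- count_matrix(counts$counts[, keep, drop = FALSE],
                           gene_ids = counts$gene_ids[keep],
                           cell_ids = counts$cell_ids)
  list(counts = filtered, report = report)
}
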