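# Chunked on-disk store and the two-level-queue batch streamer.  Cells are
# written in fixed-size row chunks so that training batches can be drawn in
# globally random order while only a bounded number of cells is ever resident
# in memory, independent of dataset size.

#' Build a chunked cell store
#'
#' Writes cells in contiguous fixed-size chunks (the last chunk may be
#' short).  With `path = NULL` an in-memory store with the same interface is
#' returned; with a directory path each chunk becomes one binary file plus a
#' JSON metadata record (gene ids, cell ids, library sizes, chunk layout).
#'
#' @param counts A [count_matrix()] object.
#' @param path Directory to write to, or `NULL` for an in-memory store.
#' @param chunk_size Cells per chunk (default 32).
#' @return A `disc_chunk_store`.
#' @export
build_chunk_store <- function(counts, path = NULL, chunk_size = 32L) {
  counts <- check_counts(counts)
  n <- nrow(counts$counts)
  chunk_size <- as.integer(chunk_size)
  stopifnot(chunk_size >= 1L, n >= 1L)
  n_chunks <- ceiling(n / chunk_size)
  sizes <- rep(chunk_size, n_chunks)
  sizes[n_chunks] <- n - chunk_size * (n_chunks - 1L)
  starts <- cumsum(c(1L, sizes[-n_chunks]))
  store <- structure(list(
    backend = if (is.null(path)) "memory" else "dir",
    path = path,
    n_cells = n, n_genes = ncol(counts$counts),
    gene_ids = counts$gene_ids, cell_ids = counts$cell_ids,
    library_sizes = counts$library_sizes,
    chunk_size = chunk_size, n_chunks = as.integer(n_chunks),
    chunk_sizes = as.integer(sizes), chunk_starts = as.integer(starts)
  ), class = "disc_chunk_store")
  if (is.null(path)) {
    store$chunks <- lapply(seq_len(n_chunks), function(i) {
      idx <- starts[i]:(starts[i] + sizes[i] - 1L)
      counts$counts[idx, , drop = FALSE]
    })
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_len(n_chunks)) {
      idx <- starts[i]:(starts[i] + sizes[i] - 1L)
      con <- file(file.path(path, sprintf("chunk_%06d.bin", i)), "wb")
      writeBin(as.numeric(counts$counts[idx, , drop = FALSE]), con, size = 8L)
      close(con)
    }
    meta <- list(n_cells = n, n_genes = ncol(counts$counts),
                 gene_ids = counts$gene_ids, cell_ids = counts$cell_ids,
                 library_sizes = counts$library_sizes,
                 chunk_size = chunk_size, n_chunks = n_chunks,
                 chunk_sizes = as.integer(sizes))
    jsonlite::write_json(meta, file.path(path, "meta.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  store
}

#' Open an existing on-disk chunk store
#'
#' @param path Directory written by [build_chunk_store()].
#' @return A `disc_chunk_store`.
#' @export
open_chunk_store <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  sizes <- as.integer(meta$chunk_sizes)
  starts <- cumsum(c(1L, sizes[-length(sizes)]))
  structure(list(
    backend = "dir", path = path,
    n_cells = as.integer(meta$n_cells), n_genes = as.integer(meta$n_genes),
    gene_ids = meta$gene_ids, cell_ids = meta$cell_ids,
    library_sizes = as.numeric(meta$library_sizes),
    chunk_size = as.integer(meta$chunk_size),
    n_chunks = as.integer(meta$n_chunks),
    chunk_sizes = sizes, chunk_starts = as.integer(starts)
  ), class = "disc_chunk_store")
}

#' Read one chunk of cells
#'
#' @param store A `disc_chunk_store`.
#' @param i Chunk index (1-based); chunk `i` holds cells
#'   `[(i-1)*chunk_size + 1, ...]` in storage order.
#' @return Numeric matrix, cells x genes.
#' @export
read_chunk <- function(store, i) {
  stopifnot(inherits(store, "disc_chunk_store"), i >= 1L, i <= store$n_chunks)
  nc <- store$chunk_sizes[i]
  if (store$backend == "memory") return(store$chunks[[i]])
  con <- file(file.path(store$path, sprintf("chunk_%06d.bin", i)), "rb")
  on.exit(close(con))
  matrix(readBin(con, "numeric", n = nc * store$n_genes, size = 8L),
         nrow = nc, ncol = store$n_genes)
}

#' Reconstruct the full matrix from a store
#'
#' @param store A `disc_chunk_store`.
#' @return A [count_matrix()] object.
#' @export
store_to_counts <- function(store) {
  m <- do.call(rbind, lapply(seq_len(store$n_chunks),
                             function(i) read_chunk(store, i)))
  count_matrix(m, gene_ids = store$gene_ids, cell_ids = store$cell_ids)
}

#' Globally random constant-memory batch iterator
#'
#' Implements a two-level queue scheme: random chunks are loaded into
#' fixed-capacity sub-queues and shuffled; sub-queues transfer cells in
#' random interleaving into a FIFO main queue from which fixed-size batches
#' are drawn.  One full pass over the chunk permutation emits every stored
#' cell exactly once before the next pass begins, and the number of resident
#' cells is bounded by
#' `n_loaders * sub_queue_chunks * chunk_size + batch_size + chunk_size`
#' regardless of dataset size.
#'
#' @param store A `disc_chunk_store`.
#' @param batch_size Cells per batch (default 128).
#' @param sub_queue_chunks Chunks loaded per sub-queue refill (default 64).
#' @param n_loaders Number of parallel sub-queues (default 2).
#' @param seed Optional seed; with a fixed seed the batch sequence is
#'   reproducible.
#' @return An environment with functions `next_batch()` (returns
#'   `list(counts, idx, ls)` for `batch_size` cells), `resident_cells()` and
#'   `peak_resident()`.
#' @export
batch_stream <- function(store, batch_size = 128L, sub_queue_chunks = 64L,
                         n_loaders = 2L, seed = NULL) {
  stopifnot(inherits(store, "disc_chunk_store"), store$n_cells >= 1L)
  if (!is.null(seed)) set.seed(seed)
  st <- new.env(parent = emptyenv())
  st$perm <- sample.int(store$n_chunks)
  st$cpos <- 1L
  st$subq <- replicate(n_loaders, NULL, simplify = FALSE)
  st$main_mat <- vector("list", 0L)   # FIFO of row blocks
  st$main_idx <- vector("list", 0L)
  st$main_n <- 0L
  st$peak <- 0L

  subq_n <- function(q) if (is.null(q)) 0L else nrow(q$mat) - q$pos + 1L
  resident <- function() {
    sum(vapply(st$subq, subq_n, 0L)) + st$main_n
  }
  refill_subq <- function(k) {
    if (st$cpos > store$n_chunks) return(FALSE)
    take <- st$perm[st$cpos:min(store$n_chunks, st$cpos + sub_queue_chunks - 1L)]
    st$cpos <- st$cpos + length(take)
    mats <- lapply(take, function(i) read_chunk(store, i))
    idx <- unlist(lapply(take, function(i) {
      store$chunk_starts[i]:(store$chunk_starts[i] + store$chunk_sizes[i] - 1L)
    }))
    mat <- do.call(rbind, mats)
    ord <- sample.int(nrow(mat))
    st$subq[[k]] <- list(mat = mat[ord, , drop = FALSE], idx = idx[ord],
                         pos = 1L)
    TRUE
  }
  transfer <- function() {
    # move one chunk-sized block from a random non-empty sub-queue to main
    live <- which(vapply(st$subq, subq_n, 0L) > 0L)
    if (length(live) == 0L) {
      for (k in seq_len(n_loaders)) refill_subq(k)
      live <- which(vapply(st$subq, subq_n, 0L) > 0L)
      if (length(live) == 0L) {
        # epoch exhausted and drained: start a new pass
        st$perm <- sample.int(store$n_chunks)
        st$cpos <- 1L
        for (k in seq_len(n_loaders)) refill_subq(k)
        live <- which(vapply(st$subq, subq_n, 0L) > 0L)
      }
    }
    k <- if (length(live) == 1L) live else sample(live, 1L)
    q <- st$subq[[k]]
    take <- min(store$chunk_size, nrow(q$mat) - q$pos + 1L)
    rows <- q$pos:(q$pos + take - 1L)
    st$main_mat[[length(st$main_mat) + 1L]] <- q$mat[rows, , drop = FALSE]
    st$main_idx[[length(st$main_idx) + 1L]] <- q$idx[rows]
    st$main_n <- st$main_n + take
    q$pos <- q$pos + take
    if (q$pos > nrow(q$mat)) {
      if (!refill_subq(k)) st$subq[k] <- list(NULL)
    } else {
      st$subq[[k]] <- q
    }
    st$peak <- max(st$peak, resident())
  }
  next_batch <- function() {
    while (st$main_n < batch_size) transfer()
    mat <- do.call(rbind, st$main_mat)
    idx <- unlist(st$main_idx)
    out_rows <- seq_len(batch_size)
    batch <- list(counts = mat[out_rows, , drop = FALSE],
                  idx = idx[out_rows],
                  ls = store$library_sizes[idx[out_rows]])
    if (nrow(mat) > batch_size) {
      st$main_mat <- list(mat[-out_rows, , drop = FALSE])
      st$main_idx <- list(idx[-out_rows])
      st$main_n <- nrow(mat) - batch_size
    } else {
      st$main_mat <- vector("list", 0L)
      st$main_idx <- vector("list", 0L)
      st$main_n <- 0L
    }
    batch
  }
  st$next_batch <- next_batch
  st$resident_cells <- resident
  st$peak_resident <- function() st$peak
  st
}
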