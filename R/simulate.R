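# Synthetic ground-truth data: multi-cell-type negative-binomial counts with
# planted gene-gene correlation blocks and per-cell library-size variation,
# plus the transcript-level down-sampling protocol used to benchmark
# imputation against a known reference.

#' Simulation configuration
#'
#' Defaults describe a desk-scale benchmark: 2,000 cells by 300 genes, four
#' cell types with proportions 0.4/0.3/0.2/0.1, negative-binomial dispersion
#' 0.2 (variance mu + 0.2 mu^2), log-normal library sizes centred at 2,000
#' transcripts (sdlog 0.3), and two 15-gene correlated blocks driven by
#' per-cell latent factors.
#'
#' @param n_cells,n_genes Matrix dimensions.
#' @param n_cell_types Number of cell types.
#' @param type_proportions Mixing proportions (sum to 1).
#' @param n_markers_per_type Genes upregulated per type.
#' @param marker_fold Fold change of marker genes in their type.
#' @param dispersion NB dispersion (0 gives Poisson).
#' @param lib_meanlog,lib_sdlog Log-normal library-size parameters.
#' @param corr_blocks List of correlation blocks, each
#'   `list(genes = <indices>, loading = <latent-factor loading>)`.
#' @param seed Integer seed.
#' @return A `disc_sim_config` list.
#' @export
sim_config <- function(n_cells = 2000L, n_genes = 300L, n_cell_types = 4L,
                       type_proportions = c(0.4, 0.3, 0.2, 0.1),
                       n_markers_per_type = 20L, marker_fold = 5,
                       dispersion = 0.2,
                       lib_meanlog = log(2000), lib_sdlog = 0.3,
                       corr_blocks = list(
                         list(genes = 1:15, loading = 0.8),
                         list(genes = 16:30, loading = 0.8)),
                       seed = 1L) {
  if (length(type_proportions) != n_cell_types ||
      abs(sum(type_proportions) - 1) > 1e-8 || any(type_proportions <= 0)) {
    stop("type_proportions must be positive and sum to 1")
  }
  stopifnot(dispersion >= 0, lib_sdlog >= 0, marker_fold > 0)
  structure(as.list(environment()), class = "disc_sim_config")
}

#' Simulate a ground-truth count matrix
#'
#' Per cell: a type is drawn from the mixing proportions, a library size
#' from the log-normal, and one latent factor per correlation block from
#' N(0, 1).  The cell's expected gene expression is the type profile times
#' `exp(loading * factor - loading^2 / 2)` on block genes (unit mean),
#' renormalized to the library size; counts are negative binomial around
#' that mean.  Marker genes make the types separable; block genes acquire
#' positive within-block correlation against an uncorrelated background.
#'
#' @param cfg A [sim_config()].
#' @return List with `counts` (a [count_matrix()]), `labels` (cell-type
#'   vector), `type` per-type mean profiles, and `true_gene_corr`, the
#'   Pearson correlation of the per-cell generative means.
#' @export
simulate_counts <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "disc_sim_config"))
  with_seed(cfg$seed, {
    M <- cfg$n_genes; n <- cfg$n_cells; K <- cfg$n_cell_types
    base <- stats::rlnorm(M, meanlog = 0, sdlog = 1)
    profiles <- matrix(rep(base, K), K, M, byrow = TRUE)
    for (k in seq_len(K)) {
      mk <- sample.int(M, cfg$n_markers_per_type)
      profiles[k, mk] <- profiles[k, mk] * cfg$marker_fold
    }
    labels <- sample.int(K, n, replace = TRUE, prob = cfg$type_proportions)
    libs <- stats::rlnorm(n, cfg$lib_meanlog, cfg$lib_sdlog)
    mu <- profiles[labels, , drop = FALSE]
    for (b in cfg$corr_blocks) {
      f <- stats::rnorm(n)
      lam <- b$loading
      mu[, b$genes] <- mu[, b$genes] * exp(lam * f - lam^2 / 2)
    }
    mu <- mu / rowSums(mu) * libs
    counts <- if (cfg$dispersion > 0) {
      matrix(stats::rnbinom(n * M, size = 1 / cfg$dispersion, mu = mu), n, M)
    } else {
      matrix(stats::rpois(n * M, lambda = mu), n, M)
    }
    cm <- count_matrix(counts,
                       gene_ids = sprintf("gene%03d", seq_len(M)),
                       cell_ids = sprintf("cell%04d", seq_len(n)))
    list(counts = cm, labels = paste0("type", labels),
         type_profiles = profiles,
         # degenerate genes (constant mean across cells) yield NA columns
         true_gene_corr = suppressWarnings(stats::cor(mu)))
  })
}

#' Transcript-level down-sampling
#'
#' For each cell, exactly `floor(fraction * ls_c)` transcripts are drawn
#' uniformly without replacement from the cell's transcript multiset — a
#' multivariate hypergeometric draw over genes — so the observed library
#' size is deterministic and `observed <= reference` elementwise.
#'
#' @param reference A [count_matrix()] object.
#' @param fraction Sampled fraction in (0, 1].
#' @param seed Optional seed.
#' @return List with `reference`, `observed` (both [count_matrix()]) and
#'   `fraction`.
#' @export
downsample_reads <- function(reference, fraction, seed = NULL) {
  reference <- check_counts(reference)
  if (!(fraction > 0 && fraction <= 1)) stop("fraction must be in (0, 1]")
  run <- function() {
    C <- reference$counts
    out <- C
    if (fraction < 1) {
      for (c in seq_len(nrow(C))) {
        row <- C[c, ]
        remaining <- sum(row)
        left <- floor(fraction * remaining)
        for (m in seq_along(row)) {
          if (left <= 0L) { out[c, m:length(row)] <- 0; break }
          remaining <- remaining - row[m]
          x <- stats::rhyper(1L, row[m], remaining, left)
          out[c, m] <- x
          left <- left - x
        }
      }
    }
    list(reference = reference,
         observed = count_matrix(out, gene_ids = reference$gene_ids,
                                 cell_ids = reference$cell_ids),
         fraction = fraction)
  }
  if (!is.null(seed)) with_seed(seed, run()) else run()
}

#' Resample a low-dropout reference expression table
#'
#' Builds a synthetic stand-in for an orthogonal smFISH-style measurement:
#' cells are resampled with replacement on a gene subset and a small
#' multiplicative log-normal noise is applied, producing a reference table
#' for exercising the distribution-comparison metrics (Gini RMSE, FF
#' distance, CMD) without real FISH data.
#'
#' @param counts A [count_matrix()] object.
#' @param gene_subset Gene identifiers to retain.
#' @param n_fish_cells Number of resampled cells.
#' @param noise_sdlog Log-normal noise sdlog (0 disables noise).
#' @param seed Optional seed.
#' @return Numeric matrix, `n_fish_cells` x `length(gene_subset)`.
#' @export
make_fish_like_reference <- function(counts, gene_subset, n_fish_cells,
                                     noise_sdlog = 0.05, seed = NULL) {
  counts <- check_counts(counts)
  if (length(gene_subset) == 0L) stop("empty gene subset")
  j <- match(gene_subset, counts$gene_ids)
  if (anyNA(j)) stop("unknown gene(s): ",
                     paste(gene_subset[is.na(j)], collapse = ", "))
  run <- function() {
    rows <- sample.int(nrow(counts$counts), n_fish_cells, replace = TRUE)
    m <- counts$counts[rows, j, drop = FALSE]
    if (noise_sdlog > 0) {
      m <- m * matrix(stats::rlnorm(length(m), 0, noise_sdlog),
                      nrow(m), ncol(m))
    }
    colnames(m) <- gene_subset
    rownames(m) <- sprintf("fish%04d", seq_len(n_fish_cells))
    m
  }
  if (!is.null(seed)) with_seed(seed, run()) else run()
}
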