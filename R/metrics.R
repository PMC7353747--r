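# Formula-defined evaluation metrics for imputation quality and downstream
# analysis: expression-distribution comparisons (Gini, FF distance, CMD),
# recovery error (MAE, structure correlations), clustering agreement
# (ACC/ARI/Jaccard), Wilcoxon DEG ranking with overlap and null-calibration
# metrics, and pseudotime order accuracy.

#' Gini coefficient of an expression vector
#'
#' Relative mean absolute difference: `G = sum_ij |x_i - x_j| / (2 n^2 mu)`,
#' computed via the sorted-values identity.  Invariant to positive
#' rescaling; 0 for a constant positive vector, approaching 1 for maximal
#' concentration.
#'
#' @param values Non-negative numeric vector with at least one positive
#'   entry.
#' @return Gini coefficient in \[0, 1\].
#' @export
gini <- function(values) {
  if (any(values < 0) || anyNA(values)) stop("values must be non-negative")
  mu <- mean(values)
  if (mu == 0) stop("all-zero input has no Gini coefficient")
  n <- length(values)
  s <- sort(values)
  sum((2 * seq_len(n) - n - 1) * s) / (n^2 * mu)
}

#' RMSE between per-gene Gini coefficients of two expression tables
#'
#' @param reference_table,test_table Cells x genes matrices with gene
#'   column names (cell counts may differ).
#' @param genes Genes to compare (default: intersection of column names).
#' @return `sqrt(mean((gini_ref - gini_test)^2))` over the genes.
#' @export
gini_rmse <- function(reference_table, test_table, genes = NULL) {
  if (is.null(genes)) {
    genes <- intersect(colnames(reference_table), colnames(test_table))
  }
  if (length(genes) == 0L) stop("no overlapping genes")
  gr <- vapply(genes, function(g) gini(reference_table[, g]), 0)
  gt <- vapply(genes, function(g) gini(test_table[, g]), 0)
  sqrt(mean((gr - gt)^2))
}

#' Efficient-factor normalization of an scRNA-seq gene against a reference
#'
#' Rescales the scRNA-seq values of one gene by the ratio of the reference
#' (FISH) mean to the scRNA-seq mean, so both have equal means before their
#' distributions are compared.
#'
#' @param scrna_gene scRNA-seq expression vector (mean must be positive).
#' @param fish_gene Reference expression vector for the same gene.
#' @return Rescaled `scrna_gene`.
#' @export
efficient_factor_normalize <- function(scrna_gene, fish_gene) {
  ms <- mean(scrna_gene)
  if (ms <= 0) stop("scRNA-seq gene mean must be positive")
  scrna_gene * (mean(fish_gene) / ms)
}

#' Fasano-Franceschini two-sample distance
#'
#' A two-dimensional Kolmogorov-Smirnov-type statistic: centred on each data
#' point in turn, the empirical probabilities of the four closed/open
#' quadrants (`<=,<=`, `<=,>`, `>,<=`, `>,>`; a point lies in its own
#' `<=,<=` quadrant) are compared between the samples, and the distance is
#' the average, over the two samples, of the maximal quadrant-probability
#' discrepancy.
#'
#' @param sample_a,sample_b Two-column matrices of 2-D points (>= 2 rows).
#' @return Non-negative distance (0 for identical samples).
#' @export
ff_distance <- function(sample_a, sample_b) {
  sample_a <- as.matrix(sample_a); sample_b <- as.matrix(sample_b)
  stopifnot(ncol(sample_a) == 2L, ncol(sample_b) == 2L,
            nrow(sample_a) >= 2L, nrow(sample_b) >= 2L)
  quad_fracs <- function(pts, cx, cy) {
    lx <- pts[, 1L] <= cx; ly <- pts[, 2L] <= cy
    c(mean(lx & ly), mean(lx & !ly), mean(!lx & ly), mean(!lx & !ly))
  }
  max_disc <- function(centers) {
    d <- 0
    for (i in seq_len(nrow(centers))) {
      fa <- quad_fracs(sample_a, centers[i, 1L], centers[i, 2L])
      fb <- quad_fracs(sample_b, centers[i, 1L], centers[i, 2L])
      d <- max(d, max(abs(fa - fb)))
    }
    d
  }
  (max_disc(sample_a) + max_disc(sample_b)) / 2
}

#' Correlation matrix distance
#'
#' `d(R1, R2) = 1 - tr(R1 R2) / (||R1||_F ||R2||_F)`, 0 when the two
#' correlation structures are identical up to scale, 1 when maximally
#' different.
#'
#' @param R1,R2 Symmetric correlation matrices of the same dimension.
#' @return Distance in \[0, 1\].
#' @export
cmd <- function(R1, R2) {
  stopifnot(all(dim(R1) == dim(R2)))
  if (max(abs(R1 - t(R1))) > 1e-8 || max(abs(R2 - t(R2))) > 1e-8) {
    stop("correlation matrices must be symmetric")
  }
  n1 <- sqrt(sum(R1 * R1)); n2 <- sqrt(sum(R2 * R2))
  if (n1 == 0 || n2 == 0) stop("zero-norm matrix")
  1 - sum(R1 * R2) / (n1 * n2)
}

#' Per-cell mean absolute error against a reference
#'
#' For each cell, the test counts are rescaled to the reference library size
#' (`sf_c = ls_ref / ls_test`) and compared on the genes with positive
#' reference counts:
#' `MAE_c = sum_{i in D_c} |C_test * sf_c - C_ref| / |D_c|`.
#'
#' @param reference A [count_matrix()] object.
#' @param test A [count_matrix()], `disc_imputation` or numeric matrix of
#'   matching shape (library sizes are its row sums).
#' @return Numeric vector of per-cell MAE values.
#' @export
mae <- function(reference, test) {
  reference <- check_counts(reference)
  tm <- if (inherits(test, "disc_counts")) test$counts
        else if (inherits(test, "disc_imputation")) test$imputed_counts
        else as.matrix(test)
  stopifnot(all(dim(tm) == dim(reference$counts)))
  ls_t <- rowSums(tm)
  if (any(ls_t <= 0)) stop("zero test library size for cell(s): ",
                           paste(which(ls_t <= 0), collapse = ", "))
  sf <- reference$library_sizes / ls_t
  vapply(seq_len(nrow(tm)), function(c) {
    d <- reference$counts[c, ] > 0
    mean(abs(tm[c, d] * sf[c] - reference$counts[c, d]))
  }, 0)
}

#' Gene-gene or cell-cell correlation with the reference
#'
#' Pearson correlation of matched reference/test expression vectors per
#' gene (or per cell).  Genes are included when positive in at least 10% of
#' cells of the reference; cells when at least 10% of their reference genes
#' are positive.
#'
#' @param reference,test Matrices of matching shape (cells x genes),
#'   typically log-normalized expression.
#' @param axis `"gene"` or `"cell"`.
#' @param min_frac Inclusion threshold (default 0.1).
#' @return Named numeric vector of per-entity correlations.
#' @export
structure_correlations <- function(reference, test, axis = c("gene", "cell"),
                                   min_frac = 0.1) {
  axis <- match.arg(axis)
  reference <- as.matrix(reference); test <- as.matrix(test)
  stopifnot(all(dim(reference) == dim(test)))
  if (axis == "gene") {
    keep <- colMeans(reference > 0) >= min_frac
    if (!any(keep)) stop("no genes pass the prevalence filter")
    r <- vapply(which(keep), function(j) {
      stats::cor(reference[, j], test[, j])
    }, 0)
    names(r) <- colnames(reference)[keep]
  } else {
    keep <- rowMeans(reference > 0) >= min_frac
    if (!any(keep)) stop("no cells pass the prevalence filter")
    r <- vapply(which(keep), function(i) {
      stats::cor(reference[i, ], test[i, ])
    }, 0)
    names(r) <- rownames(reference)[keep]
  }
  r
}

#' Cell-type annotation accuracy
#'
#' Fraction of cells whose predicted class equals the label (classes must
#' already be mapped onto the label vocabulary).
#'
#' @param labels,predicted Equal-length vectors.
#' @return Accuracy in \[0, 1\].
#' @export
acc <- function(labels, predicted) {
  if (length(labels) != length(predicted)) stop("length mismatch")
  mean(labels == predicted)
}

#' Adjusted Rand index
#'
#' Pair-counting agreement between two partitions, corrected for chance via
#' the hypergeometric expectation over the contingency table.
#'
#' @param labels,clusters Equal-length vectors (any label vocabulary).
#' @return ARI (1 for identical partitions, ~0 at random).
#' @export
ari <- function(labels, clusters) {
  if (length(labels) != length(clusters)) stop("length mismatch")
  tab <- table(labels, clusters)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n2 <- ch2(length(labels))
  expected <- sum_a * sum_b / n2
  denom <- (sum_a + sum_b) / 2 - expected
  # degenerate partitions (e.g. both trivial): agreement is exact or absent
  if (denom == 0) return(as.numeric(sum_ij == expected))
  (sum_ij - expected) / denom
}

#' Jaccard index for one cell type
#'
#' `|c ∩ d| / (|c| + |d| - |c ∩ d|)` where `c` is the set of cells labeled
#' `k` and `d` the set classified as `k`.
#'
#' @param labels,clusters Equal-length vectors.
#' @param k A value of the label vocabulary.
#' @return Jaccard index in \[0, 1\].
#' @export
jaccard <- function(labels, clusters, k) {
  if (!k %in% labels) stop("label ", k, " absent from labels")
  c_set <- which(labels == k)
  d_set <- which(clusters == k)
  inter <- length(intersect(c_set, d_set))
  if (length(c_set) + length(d_set) == 0L) return(0)
  inter / (length(c_set) + length(d_set) - inter)
}

## ---- differential expression ----------------------------------------------

#' Log-normalize counts for differential expression
#'
#' `ln(scale_factor * C / ls + 1)` per cell, the conventional single-cell
#' log-normalization (scale factor 10,000).
#'
#' @param counts A [count_matrix()] or numeric matrix (cells x genes).
#' @param scale_factor Target library size (default 1e4).
#' @return Normalized matrix.
#' @export
log_normalize <- function(counts, scale_factor = 1e4) {
  m <- if (inherits(counts, "disc_counts")) counts$counts else as.matrix(counts)
  ls <- rowSums(m)
  if (any(ls <= 0)) stop("zero library size")
  log1p(scale_factor * m / ls)
}

#' Rank differentially expressed genes by Wilcoxon rank-sum test
#'
#' For every gene expressed in at least `min_pct` of either group, a
#' two-sided Wilcoxon rank-sum test on log-normalized expression and the
#' natural-log fold change of mean expression.  P-values are BH-adjusted
#' and the table is ranked by adjusted p-value, ties broken by absolute log
#' fold change.
#'
#' @param counts A [count_matrix()] or numeric count matrix (cells x genes).
#' @param group_a_cells,group_b_cells Row indices (or cell-id vectors) of
#'   the two groups.
#' @param min_pct Minimum expressed fraction in either group (default 0.1).
#' @param logfc_threshold Minimum absolute log fold change to test
#'   (default 0, i.e. rank all genes).
#' @return Data frame with columns `gene`, `p_val`, `p_val_adj`,
#'   `avg_logfc`, `pct_a`, `pct_b`, ordered by rank.
#' @export
deg_wilcoxon <- function(counts, group_a_cells, group_b_cells,
                         min_pct = 0.1, logfc_threshold = 0) {
  m <- if (inherits(counts, "disc_counts")) counts$counts else as.matrix(counts)
  resolve <- function(g) {
    if (is.character(g)) match(g, rownames(m)) else as.integer(g)
  }
  ia <- resolve(group_a_cells); ib <- resolve(group_b_cells)
  if (length(ia) == 0L || length(ib) == 0L || anyNA(ia) || anyNA(ib)) {
    stop("both groups must be non-empty sets of known cells")
  }
  ln <- log_normalize(m)
  genes <- colnames(m) %||% paste0("gene", seq_len(ncol(m)))
  pct_a <- colMeans(m[ia, , drop = FALSE] > 0)
  pct_b <- colMeans(m[ib, , drop = FALSE] > 0)
  lfc <- log((colMeans(expm1(ln[ia, , drop = FALSE])) + 1) /
               (colMeans(expm1(ln[ib, , drop = FALSE])) + 1))
  test <- pmax(pct_a, pct_b) >= min_pct & abs(lfc) >= logfc_threshold
  if (!any(test)) stop("no gene passes the filters")
  p <- rep(NA_real_, ncol(m))
  for (j in which(test)) {
    p[j] <- suppressWarnings(
      stats::wilcox.test(ln[ia, j], ln[ib, j], exact = FALSE)$p.value)
  }
  p[is.nan(p)] <- 1   # zero-variance genes carry no evidence
  padj <- rep(NA_real_, ncol(m))
  padj[test] <- stats::p.adjust(p[test], method = "BH")
  out <- data.frame(gene = genes[test], p_val = p[test],
                    p_val_adj = padj[test], avg_logfc = lfc[test],
                    pct_a = pct_a[test], pct_b = pct_b[test],
                    stringsAsFactors = FALSE)
  out[order(out$p_val_adj, -abs(out$avg_logfc)), , drop = FALSE]
}

#' Mean top-k overlap of ranked single-cell DEGs with a gold-standard set
#'
#' For `i = 1..k`, the proportion of the top `10*i` ranked genes found in
#' the gold-standard set; the metric is the mean of the `k` proportions
#' (`k = 100` for all-gene comparisons, 10 for per-fold-change intervals).
#'
#' @param sc_ranked_genes Character vector of genes, best first.
#' @param bulk_deg_set Character vector of gold-standard DEGs.
#' @param k Number of prefixes.
#' @return Mean overlap proportion in \[0, 1\].
#' @export
deg_overlap_metric <- function(sc_ranked_genes, bulk_deg_set, k) {
  stopifnot(k >= 1)
  if (length(sc_ranked_genes) < 10 * k) {
    stop("ranked list shorter than 10 * k genes")
  }
  props <- vapply(seq_len(k), function(i) {
    top <- sc_ranked_genes[seq_len(10 * i)]
    length(intersect(top, bulk_deg_set)) / (10 * i)
  }, 0)
  mean(props)
}

#' False-DEG counts on a homogeneous population
#'
#' Randomly splits one homogeneous cell population into two groups at each
#' of the ten size conditions (10 vs 10 through 500 vs 500) and counts the
#' genes passing `p < p_cut` and `|logfc| > lfc_cut` — all of which are
#' false discoveries.
#'
#' @param counts A [count_matrix()] of one homogeneous population.
#' @param sizes List of `c(n_a, n_b)` pairs; the default enumerates the ten
#'   standard conditions.
#' @param seed Optional seed for the random splits.
#' @param p_cut,lfc_cut DEG thresholds (defaults 0.01 and 0.25).
#' @return Data frame with columns `n_a`, `n_b`, `n_false_deg`.
#' @export
null_deg_count <- function(counts,
                           sizes = list(c(10, 10), c(10, 50), c(10, 100),
                                        c(10, 500), c(50, 50), c(50, 100),
                                        c(50, 500), c(100, 100), c(100, 500),
                                        c(500, 500)),
                           seed = NULL, p_cut = 0.01, lfc_cut = 0.25) {
  counts <- check_counts(counts)
  n <- nrow(counts$counts)
  need <- max(vapply(sizes, sum, 0))
  if (n < need) stop("population too small: need ", need, " cells, have ", n)
  run <- function() {
    do.call(rbind, lapply(sizes, function(sz) {
      pick <- sample.int(n, sz[1] + sz[2])
      tab <- deg_wilcoxon(counts, pick[seq_len(sz[1])],
                          pick[sz[1] + seq_len(sz[2])],
                          min_pct = 0.1, logfc_threshold = 0)
      data.frame(n_a = sz[1], n_b = sz[2],
                 n_false_deg = sum(tab$p_val < p_cut &
                                     abs(tab$avg_logfc) > lfc_cut))
    }))
  }
  if (!is.null(seed)) with_seed(seed, run()) else run()
}

#' Pseudotime pairwise order accuracy
#'
#' Over all cell pairs with different differentiation levels that co-occur
#' in at least one lineage, the fraction where the more differentiated cell
#' has the strictly higher pseudotime.  Callers may maximize over candidate
#' root orientations by re-invoking with re-rooted pseudotimes.
#'
#' @param pseudotimes Numeric vector, one per cell.
#' @param differentiation_levels Integer differentiation level per cell.
#' @param lineage_membership Logical cells x lineages matrix (a pair is
#'   eligible when some lineage contains both cells).
#' @return Fraction of correctly ordered eligible pairs.
#' @export
pseudotime_order_accuracy <- function(pseudotimes, differentiation_levels,
                                      lineage_membership) {
  n <- length(pseudotimes)
  lm <- as.matrix(lineage_membership)
  stopifnot(length(differentiation_levels) == n, nrow(lm) == n)
  share <- (lm %*% t(lm)) > 0
  dl <- outer(differentiation_levels, differentiation_levels, "-")
  dp <- outer(pseudotimes, pseudotimes, "-")
  eligible <- share & dl != 0 & upper.tri(share)
  if (!any(eligible)) stop("no eligible cell pairs")
  correct <- (dl > 0 & dp > 0) | (dl < 0 & dp < 0)
  sum(correct & eligible) / sum(eligible)
}

## ---- summary report --------------------------------------------------------

#' Imputation evaluation report
#'
#' Computes the core recovery metrics of the down-sampling benchmark for
#' both the observed and the imputed matrix against the reference: mean
#' per-cell MAE, mean gene-gene and cell-cell correlation (10% prevalence
#' filters, on log-normalized expression), and the correlation matrix
#' distance between gene-gene correlation matrices.
#'
#' @param reference,observed A [count_matrix()] object each.
#' @param imputed A `disc_imputation` or matrix.
#' @param labels Optional cell-type labels, reported as provenance.
#' @return Data frame with columns `metric`, `observed`, `imputed`.
#' @export
evaluate_imputation <- function(reference, observed, imputed, labels = NULL) {
  reference <- check_counts(reference)
  im <- if (inherits(imputed, "disc_imputation")) imputed$imputed_counts
        else as.matrix(imputed)
  ln_ref <- log_normalize(reference)
  ln_obs <- log_normalize(observed)
  ln_imp <- log_normalize(im)
  keep <- colMeans(reference$counts > 0) >= 0.1
  cor_ref <- stats::cor(ln_ref[, keep, drop = FALSE])
  row <- function(metric, obs, imp) {
    data.frame(metric = metric, observed = obs, imputed = imp,
               stringsAsFactors = FALSE)
  }
  rbind(
    row("mae_mean", mean(mae(reference, observed)),
        mean(mae(reference, im))),
    row("gene_correlation_mean",
        mean(structure_correlations(ln_ref, ln_obs, "gene")),
        mean(structure_correlations(ln_ref, ln_imp, "gene"))),
    row("cell_correlation_mean",
        mean(structure_correlations(ln_ref, ln_obs, "cell")),
        mean(structure_correlations(ln_ref, ln_imp, "cell"))),
    row("cmd_gene_correlation",
        cmd(cor_ref, stats::cor(ln_obs[, keep, drop = FALSE])),
        cmd(cor_ref, stats::cor(ln_imp[, keep, drop = FALSE])))
  )
}
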