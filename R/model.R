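# Forward model: normalization, outlier masking, recurrent
# encode/predict/decode with positive-count filtering, soft attention,
# compressor and denormalization.  All operations accept plain matrices and
# are expressed in the tape ops (tape.R) so the training loop can reuse them
# with gradient tracking; called with plain arrays they are ordinary
# functions.

#' Library-size normalization with log transform
#'
#' Each cell's counts are scaled to a common library size `scale_factor` and
#' log-transformed: `ln(scale_factor * C / ls + 1)`.  A scale factor of 1e6
#' is used for outlier detection; the median library size is used when
#' preparing model input.
#'
#' @param counts A [count_matrix()] object.
#' @param scale_factor Positive scale factor.
#' @return Numeric matrix, cells x genes.
#' @export
normalize_counts <- function(counts, scale_factor) {
  counts <- check_counts(counts)
  stopifnot(scale_factor > 0)
  ls <- counts$library_sizes
  if (any(ls <= 0)) {
    stop("zero library size for cell(s): ",
         paste(counts$cell_ids[ls <= 0], collapse = ", "))
  }
  log1p(scale_factor * counts$counts / ls)
}

#' Detect outlier counts
#'
#' Z-scores are computed per gene over all cells on counts normalized to a
#' library size of one million (log scale); entries with Z > 3 are flagged.
#' Flagged entries are never imputed (they pass through unchanged) and are
#' treated as unlabeled during training.  Genes with zero variance yield no
#' outliers.
#'
#' @param counts A [count_matrix()] object with at least 2 cells.
#' @return Logical cells x genes matrix, `TRUE` at outlier entries.
#' @export
detect_outliers <- function(counts) {
  counts <- check_counts(counts)
  if (nrow(counts$counts) < 2L) stop("outlier detection requires >= 2 cells")
  ln <- normalize_counts(counts, 1e6)
  mu <- colMeans(ln)
  sd <- apply(ln, 2L, stats::sd)
  z <- sweep(ln, 2L, mu, "-")
  ok <- sd > 0
  z[, ok] <- sweep(z[, ok, drop = FALSE], 2L, sd[ok], "/")
  z[, !ok] <- 0
  mask <- z > 3
  mask[counts$counts == 0] <- FALSE
  mask
}

#' Prepare the first-step model input
#'
#' Counts are normalized with the median library size as scale factor, then
#' each gene is divided by its normalized maximum over non-outlier cells so
#' that inputs lie in \[0, 1\]; outlier entries are clipped to 1.
#'
#' @param counts A [count_matrix()] object.
#' @param mask Logical outlier mask from [detect_outliers()].
#' @return A `disc_norm` object: `x0` (cells x genes in \[0,1\]),
#'   `gene_norm_max` (per-gene normalized maxima excluding outliers) and
#'   `scale_factor` (the median library size).
#' @export
prepare_input <- function(counts, mask = NULL) {
  counts <- check_counts(counts)
  if (is.null(mask)) mask <- detect_outliers(counts)
  sf <- stats::median(counts$library_sizes)
  cn <- normalize_counts(counts, sf)
  keep <- cn
  keep[mask] <- -Inf
  gmax <- apply(keep, 2L, max)
  bad <- !is.finite(gmax) | gmax <= 0
  if (any(bad)) {
    stop("gene(s) with no positive non-outlier count (apply gene_selection ",
         "first): ", paste(counts$gene_ids[bad], collapse = ", "))
  }
  x0 <- pmin(sweep(cn, 2L, gmax, "/"), 1)
  structure(list(x0 = x0, gene_norm_max = gmax, scale_factor = sf,
                 gene_ids = counts$gene_ids),
            class = "disc_norm")
}

#' Reverse normalized model output to the count scale
#'
#' Exact algebraic inverse of [prepare_input()] composed with
#' [normalize_counts()]: `count = (exp(y * gene_norm_max) - 1) * ls / sf`.
#'
#' @param y Matrix of model outputs in \[0, 1\], cells x genes (node or
#'   numeric).
#' @param norm A `disc_norm` object (carries `gene_norm_max`, `scale_factor`).
#' @param ls Per-cell library sizes, length `nrow(y)`.
#' @return Counts on the original scale (same class as `y`).
#' @export
denormalize <- function(y, norm, ls) {
  yv <- vof(y)
  if (any(yv < 0)) stop("denormalize: negative normalized values")
  n <- nrow(yv)
  gm <- matrix(rep(norm$gene_norm_max, each = n), n, length(norm$gene_norm_max))
  lsm <- matrix(ls / norm$scale_factor, n, ncol(yv))
  td_mul(td_sub(td_exp(td_mul(y, gm)), 1), lsm)
}

## ---- parameters ------------------------------------------------------------

# Evaluate expr with a temporarily seeded RNG, restoring the caller's state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Initialize model parameters
#'
#' Weights are drawn from a variance-scaling normal (sd = 1/sqrt(fan-in));
#' biases and the per-gene gains `phi` start at zero, so every
#' `sigmoid(2 * (phi + 1) * pre)` output layer has near-unit gain at
#' initialization.
#'
#' @param n_genes Number of genes M (after gene selection).
#' @param S Latent dimension (default 512).
#' @param T_steps Number of recurrence steps (default 3).
#' @param H1,H2 Per-gene channel hidden widths (defaults 16 and 8).
#' @param W Compressed feature dimension (default 50).
#' @param seed Integer seed for reproducible initialization.
#' @param gene_ids Optional gene identifiers recorded for compatibility
#'   checks.
#' @param mean_x0 Optional per-gene mean of the normalized input over all
#'   cells.  When supplied, the decoder bias and both prediction-head biases
#'   are set so every output starts at its gene's mean (instead of 0.5),
#'   which anchors the overall imputation level from the first batch and
#'   lets training concentrate on cell-specific structure.
#' @return A `disc_params` object: list of tensors plus a `dims` list.
#' @export
disc_params <- function(n_genes, S = 512L, T_steps = 3L, H1 = 16L, H2 = 8L,
                        W = 50L, seed = 1L, gene_ids = NULL, mean_x0 = NULL) {
  M <- as.integer(n_genes)
  stopifnot(M >= 1L, S >= 1L, T_steps >= 1L, H1 >= 1L, H2 >= 1L, W >= 1L)
  vs <- function(fan_in, ...) {
    array(stats::rnorm(prod(c(...)), sd = sqrt(1 / fan_in)), dim = c(...))
  }
  tensors <- with_seed(seed, list(
    w_E  = vs(M, S, M),
    b_D  = numeric(M),
    phi  = numeric(M),
    W1   = vs(S, H1 * M, S),
    b1   = numeric(H1 * M),
    W2   = vs(H1, M, H2, H1),
    b2   = matrix(0, M, H2),
    Wpsi = vs(H2, M, 1, H2),
    Wp1  = vs(H2, M, 1, H2),
    bp1  = matrix(0, M, 1),
    Wp2  = vs(H2, M, 1, H2),
    bp2  = matrix(0, M, 1),
    Wa   = vs(H1, M, 1, H1),
    Wz   = vs(S * T_steps, W, S * T_steps),
    bz1  = numeric(W),
    bz2  = numeric(S * T_steps)
  ))
  if (!is.null(mean_x0)) {
    stopifnot(length(mean_x0) == M)
    # y = sigmoid(2 (phi + 1) pre) with phi = 0: pre = logit(p) / 2 gives p
    b0 <- stats::qlogis(pmin(pmax(mean_x0, 0.01), 0.9)) / 2
    tensors$b_D <- b0
    tensors$bp1 <- matrix(b0, M, 1)
    tensors$bp2 <- matrix(b0, M, 1)
  }
  structure(list(
    tensors = tensors,
    dims = list(M = M, S = as.integer(S), T = as.integer(T_steps),
                H1 = as.integer(H1), H2 = as.integer(H2), W = as.integer(W)),
    gene_ids = gene_ids
  ), class = "disc_params")
}

#' @export
print.disc_params <- function(x, ...) {
  d <- x$dims
  cat(sprintf(
    "disc_params: M=%d genes, S=%d latent, T=%d steps, H1=%d, H2=%d, W=%d\n",
    d$M, d$S, d$T, d$H1, d$H2, d$W))
  invisible(x)
}

param_tensors <- function(params) {
  if (inherits(params, "disc_params")) params$tensors else params
}

## ---- forward components ----------------------------------------------------

#' Encoder: expression profile to latent representation
#'
#' `z = tanh(w_E x)` applied row-wise to a cells x genes input.
#'
#' @param x Input matrix in \[0, 1\], cells x genes.
#' @param params A [disc_params()] object.
#' @return Latent matrix, cells x S, entries in (-1, 1).
#' @export
encoder_forward <- function(x, params) {
  P <- param_tensors(params)
  if (ncol(vof(x)) != ncol(vof(P$w_E))) stop("encoder: gene dimension mismatch")
  td_tanh(td_matmul(x, P$w_E, tb = TRUE))
}

#' Decoder: latent representation to reconstructed profile
#'
#' `y_hat = sigmoid(2 (phi + 1) * (w_E' z + b_D))`, reusing the transposed
#' encoder weights (tied weights).
#'
#' @param z Latent matrix, cells x S.
#' @param params A [disc_params()] object.
#' @return Reconstructed profile, cells x genes, entries in (0, 1).
#' @export
decoder_forward <- function(z, params) {
  P <- param_tensors(params)
  M <- ncol(vof(P$w_E))
  pre <- td_bias_row(td_matmul(z, P$w_E), P$b_D)
  td_sigmoid(td_mul(td_gene_scale(pre, P$phi, seq_len(M)), 2))
}

#' Per-gene prediction channels
#'
#' Each gene has a private three-layer channel reading the shared latent
#' representation: two hidden layers scaled by `(phi_m + 1)`, then two scalar
#' output heads mixed by a gate `psi = sigmoid(SELU(w_psi h2))`.  The SELU
#' before the gate biases selection toward the first head, which models the
#' major expression distribution of the gene.
#'
#' @param z Latent matrix, cells x S.
#' @param params A [disc_params()] object.
#' @return List with `y` (cells x genes prediction in (0,1)), `h1`, `h2`
#'   (hidden activations in unit-major layout, cells x (H*M)) and `psi`
#'   (cells x genes gate in (0,1)).
#' @export
predictor_forward <- function(z, params) {
  P <- param_tensors(params)
  d <- params$dims
  M <- d$M; H1 <- d$H1; H2 <- d$H2
  gene1 <- rep(seq_len(M), H1)
  gene2 <- rep(seq_len(M), H2)
  h1 <- td_gene_scale(td_bias_row(td_matmul(z, P$W1, tb = TRUE), P$b1),
                      P$phi, gene1)
  h2 <- td_gene_scale(td_gene_linear(td_tanh(h1), P$W2, P$b2, H1, H2, M),
                      P$phi, gene2)
  th2 <- td_tanh(h2)
  psi <- td_sigmoid(td_selu(td_gene_linear(th2, P$Wpsi, NULL, H2, 1L, M)))
  p1 <- td_gene_linear(th2, P$Wp1, P$bp1, H2, 1L, M)
  p2 <- td_gene_linear(th2, P$Wp2, P$bp2, H2, 1L, M)
  mix <- td_add(td_mul(psi, p1), td_mul(td_sub(1, psi), p2))
  y <- td_sigmoid(td_mul(td_gene_scale(mix, P$phi, seq_len(M)), 2))
  list(y = y, h1 = h1, h2 = h2, psi = psi)
}

#' Positive-count filter for the next recurrence input
#'
#' Observed positive counts are kept; zero-count positions take the current
#' prediction: `x_next = x0` where `x0 > 0`, else `y_t`.
#'
#' @param x0 First-step input matrix (or `disc_norm` object).
#' @param y_t Current prediction matrix, same shape.
#' @return Next-step input matrix.
#' @export
filter_next_input <- function(x0, y_t) {
  if (inherits(x0, "disc_norm")) x0 <- x0$x0
  pos <- vof(x0) > 0
  td_add(td_mul(y_t, !pos), x0 * pos)
}

#' Soft-attention combination over recurrence steps
#'
#' Per (cell, gene), a softmax over steps of `w_a SELU(h1^t)` yields weights
#' `a^t` summing to 1; the imputer output `y` and reconstructor output
#' `y_hat` are the attention-weighted averages of the per-step predictions
#' and decodings, sharing the same weights.
#'
#' @param h1_steps List (length T) of first-hidden-layer activations.
#' @param y_steps List of per-step predictions.
#' @param yhat_steps List of per-step decodings.
#' @param params A [disc_params()] object.
#' @return List with `y`, `y_hat` (cells x genes) and `a` (list of per-step
#'   weight matrices).
#' @export
attention_combine <- function(h1_steps, y_steps, yhat_steps, params) {
  if (length(h1_steps) < 1L) stop("attention requires at least one step")
  P <- param_tensors(params)
  d <- params$dims
  logits <- lapply(h1_steps, function(h) {
    td_gene_linear(td_selu(h), P$Wa, NULL, d$H1, 1L, d$M)
  })
  a <- td_softmax_steps(logits)
  wsum <- function(steps) {
    out <- td_mul(a[[1L]], steps[[1L]])
    for (k in seq_along(steps)[-1L]) {
      out <- td_add(out, td_mul(a[[k]], steps[[k]]))
    }
    out
  }
  list(y = wsum(y_steps),
       y_hat = if (!is.null(yhat_steps)) wsum(yhat_steps), a = a)
}

#' Run the full T-step recurrence
#'
#' Step 1 consumes `x0`; each later step consumes the positive-count-filtered
#' previous prediction.  Returns all per-step tensors plus the
#' attention-combined outputs.
#'
#' @param x0 First-step input (matrix or `disc_norm`).
#' @param params A [disc_params()] object.
#' @param zero_scale Optional list (length T) of matrices multiplied into the
#'   zero-count positions of each recurrent input (used for the training-time
#'   dropout on noisy inputs); `NULL` for none.
#' @param decode Compute the per-step decodings and combined reconstruction
#'   (`TRUE` by default; the noisy training pass skips them since no loss
#'   reads them).
#' @return List with per-step lists `z`, `y`, `yhat`, `h1`, `h2`, `psi`,
#'   inputs `x_steps` (length T + 1, the trailing entry is the filtered final
#'   prediction), attention weights `a`, and combined `y_comb`, `yhat_comb`.
#' @export
run_recurrence <- function(x0, params, zero_scale = NULL, decode = TRUE) {
  if (inherits(x0, "disc_norm")) x0 <- x0$x0
  d <- params$dims
  pos <- vof(x0) > 0
  x0pos <- x0 * pos   # equal to x0 when x0 is zero off-support
  out <- list(z = list(), y = list(), yhat = if (decode) list(), h1 = list(),
              h2 = list(), psi = list(), x_steps = list())
  x <- x0
  for (t in seq_len(d$T)) {
    z <- encoder_forward(x, params)
    pr <- predictor_forward(z, params)
    out$z[[t]] <- z; out$y[[t]] <- pr$y
    if (decode) out$yhat[[t]] <- decoder_forward(z, params)
    out$h1[[t]] <- pr$h1; out$h2[[t]] <- pr$h2; out$psi[[t]] <- pr$psi
    zmask <- !pos
    if (!is.null(zero_scale)) zmask <- zmask * zero_scale[[t]]
    x <- td_add(td_mul(pr$y, zmask), x0pos)
    out$x_steps[[t]] <- x
  }
  out$x_steps <- c(list(x0), out$x_steps)
  comb <- attention_combine(out$h1, out$y, out$yhat, params)
  out$a <- comb$a
  out$y_comb <- comb$y
  out$yhat_comb <- comb$y_hat
  out
}

#' Compress per-step latent representations
#'
#' A tied-weight autoencoder maps the concatenated latents (S*T) to `W`
#' dimensions: `cp = tanh(w_z z + b_z1)`, decoded back as
#' `z_tilde = tanh(w_z' cp + b_z2)`.  When attention weights are supplied,
#' each decompressed per-step latent is decoded to a profile and combined
#' with the shared attention weights into `y_tilde`.
#'
#' @param z_steps List of per-step latent matrices (or a single
#'   concatenated cells x (S*T) matrix).
#' @param params A [disc_params()] object.
#' @param attention Optional list of per-step attention weight matrices.
#' @return List with `cp` (cells x W), `z_tilde` (cells x (S*T)) and
#'   `y_tilde` (cells x genes, `NULL` without attention).
#' @export
compress <- function(z_steps, params, attention = NULL) {
  P <- param_tensors(params)
  d <- params$dims
  z_all <- if (is.list(z_steps)) td_cbind(z_steps) else z_steps
  if (ncol(vof(z_all)) != d$S * d$T) stop("compress: latent dimension mismatch")
  cp <- td_tanh(td_bias_row(td_matmul(z_all, P$Wz, tb = TRUE), P$bz1))
  z_tilde <- td_tanh(td_bias_row(td_matmul(cp, P$Wz), P$bz2))
  y_tilde <- NULL
  if (!is.null(attention)) {
    for (t in seq_len(d$T)) {
      zt <- td_cols(z_tilde, ((t - 1L) * d$S + 1L):(t * d$S))
      dec <- decoder_forward(zt, params)
      term <- td_mul(attention[[t]], dec)
      y_tilde <- if (is.null(y_tilde)) term else td_add(y_tilde, term)
    }
  }
  list(cp = cp, z_tilde = z_tilde, y_tilde = y_tilde)
}

## ---- imputation ------------------------------------------------------------

#' Impute a count matrix with a trained model
#'
#' Runs the recurrence with soft attention, denormalizes the combined
#' prediction back to the count scale, and passes outlier entries through
#' unchanged.  In `conservative` mode all observed positive counts are also
#' kept as-is, so only zeros are imputed; in `denoised` mode (default) the
#' model output replaces everything except outliers.
#'
#' @param counts A [count_matrix()] object on the model's gene set.
#' @param model A `disc_model` from [fit()] (or a list with `params`,
#'   `gene_norm_max`, `scale_factor`).
#' @param mode `"denoised"` or `"conservative"`.
#' @param batch_cells Number of cells processed per forward block.
#' @return A `disc_imputation` object: `imputed_counts`, `latent_features`
#'   (cells x W), `reconstruction` (cells x genes in (0,1)), `mode`, plus
#'   identifiers.
#' @export
impute <- function(counts, model, mode = c("denoised", "conservative"),
                   batch_cells = 1024L) {
  counts <- check_counts(counts)
  mode <- match.arg(mode)
  params <- model$params
  if (!is.null(params$gene_ids) &&
      !identical(params$gene_ids, counts$gene_ids)) {
    stop("gene set of counts does not match the gene set the model was ",
         "trained on")
  }
  if (params$dims$M != ncol(counts$counts)) {
    stop("gene dimension mismatch between model and counts")
  }
  norm <- structure(list(gene_norm_max = model$gene_norm_max,
                         scale_factor = model$scale_factor),
                    class = "disc_norm")
  mask <- detect_outliers(counts)
  cn <- normalize_counts(counts, model$scale_factor)
  x0_all <- pmin(sweep(cn, 2L, model$gene_norm_max, "/"), 1)
  x0_all[mask] <- 0   # outliers are unlabeled: model never sees them
  n <- nrow(x0_all)
  imputed <- matrix(0, n, params$dims$M,
                    dimnames = dimnames(counts$counts))
  recon <- imputed
  latent <- matrix(0, n, params$dims$W,
                   dimnames = list(counts$cell_ids, NULL))
  for (start in seq(1L, n, by = batch_cells)) {
    idx <- start:min(n, start + batch_cells - 1L)
    fw <- run_recurrence(x0_all[idx, , drop = FALSE], params)
    imputed[idx, ] <- denormalize(fw$y_comb, norm,
                                  counts$library_sizes[idx])
    recon[idx, ] <- fw$yhat_comb
    latent[idx, ] <- compress(fw$z, params)$cp
  }
  imputed[mask] <- counts$counts[mask]
  if (mode == "conservative") {
    keep <- counts$counts > 0
    imputed[keep] <- counts$counts[keep]
  }
  structure(list(imputed_counts = imputed, latent_features = latent,
                 reconstruction = recon, mode = mode,
                 gene_ids = counts$gene_ids, cell_ids = counts$cell_ids),
            class = "disc_imputation")
}

#' @export
print.disc_imputation <- function(x, ...) {
  cat(sprintf("disc_imputation (%s): %d cells x %d genes, %d latent features\n",
              x$mode, nrow(x$imputed_counts), ncol(x$imputed_counts),
              ncol(x$latent_features)))
  invisible(x)
}
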