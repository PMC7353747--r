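# The five-term semi-supervised training objective.  Positive observed
# counts are the labeled positions; zeros (and masked outliers) are unlabeled
# and receive pseudo-label targets that are held constant within the step
# (gradient-detached), so the semi-supervised scheme cannot collapse onto its
# own targets.  All functions accept plain arrays or tape nodes.

#' Default loss weights
#'
#' Returns the default weighting of the five loss terms and the
#' regularizers.  `beta4` scales with the number of genes and is recomputed
#' whenever M changes.
#'
#' @param n_genes Number of genes M.
#' @param ... Named overrides of any weight.
#' @return Named list: `alpha_R`, `alpha_P1`, `alpha_P2`, `beta1`..`beta9`.
#' @export
loss_weights <- function(n_genes, ...) {
  w <- list(alpha_R = 5, alpha_P1 = 1.5, alpha_P2 = 0.35,
            beta1 = 1, beta2 = 1, beta3 = 1,
            beta4 = 1.65 * n_genes * 1e-5, beta5 = 6.3e-5,
            beta6 = 1e-6, beta7 = 1e-6, beta8 = 1e-5, beta9 = 1e-4)
  ov <- list(...)
  stopifnot(all(names(ov) %in% names(w)))
  w[names(ov)] <- ov
  stopifnot(all(unlist(w) >= 0))
  w
}

#' Noise-to-noise imputation loss
#'
#' L1 distance between the noisy-pass imputer output and an independent
#' noise draw of the same input, restricted to observed positive counts:
#' `L_I = (1/N) * sum(pos * |ny - ny'|)`.
#'
#' @param ny Noisy-pass combined prediction, cells x genes.
#' @param ny_target Independent noise target (second draw times `x0`).
#' @param pos_mask Logical/0-1 matrix, 1 at supervised positive positions.
#' @return Scalar loss.
#' @export
imputation_loss <- function(ny, ny_target, pos_mask) {
  n <- nrow(vof(ny))
  td_mul(td_sum(td_mul(td_abs(td_sub(ny, ny_target)), pos_mask * 1)), 1 / n)
}

#' Reconstruction loss
#'
#' Squared error of the attention-combined decoding against the observed
#' input at positives (weight `alpha_R`) and against the detached imputer
#' output at zeros (weight 1).
#'
#' @param yhat Combined reconstructor output, cells x genes.
#' @param y Combined imputer output (pseudo-label source, detached).
#' @param x0 First-step input.
#' @param pos_mask Supervised-positive mask.
#' @param alpha_R Weight on positive positions (default 5).
#' @return Scalar loss.
#' @export
reconstruction_loss <- function(yhat, y, x0, pos_mask, alpha_R = 5) {
  n <- nrow(vof(yhat))
  pos <- pos_mask * 1
  target <- vof(x0) * pos + td_detach(y) * (1 - pos)
  w <- alpha_R * pos + (1 - pos)
  d <- td_sub(yhat, target)
  td_mul(td_sum(td_mul(td_mul(d, d), w)), 1 / n)
}

#' Prediction loss
#'
#' Per-step squared error of the predictor output against the observed input
#' at positives (weight `alpha_P1`) and against the same step's detached
#' decoding at zeros (weight `alpha_P2`), summed over steps.
#'
#' @param y_steps List of per-step predictions.
#' @param yhat_steps List of per-step decodings (pseudo-label source).
#' @param x0 First-step input.
#' @param pos_mask Supervised-positive mask.
#' @param alpha_P1,alpha_P2 Weights at positive / zero positions.
#' @return Scalar loss.
#' @export
prediction_loss <- function(y_steps, yhat_steps, x0, pos_mask,
                            alpha_P1 = 1.5, alpha_P2 = 0.35) {
  n <- nrow(vof(x0))
  pos <- pos_mask * 1
  w <- alpha_P1 * pos + alpha_P2 * (1 - pos)
  total <- NULL
  for (t in seq_along(y_steps)) {
    target <- vof(x0) * pos + td_detach(yhat_steps[[t]]) * (1 - pos)
    d <- td_sub(y_steps[[t]], target)
    term <- td_sum(td_mul(td_mul(d, d), w))
    total <- if (is.null(total)) term else td_add(total, term)
  }
  td_mul(total, 1 / n)
}

#' Latent representation loss
#'
#' Squared difference of the pre-activation encoder projections of
#' successive recurrence inputs, averaged over cells and steps:
#' `L_LR = 1/(N*T) * sum_t ||x^t w_E' - x^(t-1) w_E'||^2`.  Its batch-wise
#' standard deviation drives the stopping rule.
#'
#' @param x_steps List of successive recurrence inputs (length T + 1,
#'   starting at `x0`; the last entry is the filtered final prediction).
#' @param w_E Encoder weight matrix (S x M).
#' @return Scalar loss.
#' @export
latent_representation_loss <- function(x_steps, w_E) {
  if (length(x_steps) < 2L) stop("latent representation loss needs T >= 1")
  n <- nrow(vof(x_steps[[1L]]))
  T_steps <- length(x_steps) - 1L
  prev <- td_matmul(x_steps[[1L]], w_E, tb = TRUE)
  total <- NULL
  for (t in seq_along(x_steps)[-1L]) {
    cur <- td_matmul(x_steps[[t]], w_E, tb = TRUE)
    d <- td_sub(cur, prev)
    term <- td_sum(td_mul(d, d))
    total <- if (is.null(total)) term else td_add(total, term)
    prev <- cur
  }
  td_mul(total, 1 / (n * T_steps))
}

#' Capacity constraint loss
#'
#' Penalizes the total imputed count mass placed on zero-count positions:
#' per step, the denormalized prediction at zero positions, squared and
#' summed.  Positive positions never contribute.
#'
#' @param y_steps List of per-step predictions.
#' @param zero_mask Logical/0-1 matrix, 1 at unlabeled (zero-count or
#'   outlier) positions.
#' @param norm A `disc_norm` object (gene maxima and scale factor).
#' @param ls Per-cell library sizes.
#' @return Scalar loss.
#' @export
capacity_constraint_loss <- function(y_steps, zero_mask, norm, ls) {
  total <- NULL
  for (t in seq_along(y_steps)) {
    v <- td_mul(denormalize(y_steps[[t]], norm, ls), zero_mask * 1)
    term <- td_sum(td_mul(v, v))
    total <- if (is.null(total)) term else td_add(total, term)
  }
  total
}

#' Structured sparsity regularizer
#'
#' For each output node, the square of the sum of squared incoming weights:
#' `f_re(w) = sum_i (sum_j w_ij^2)^2` over rows i.  Unlike an L1 penalty it
#' restricts the number of genes with strong connections to each node.
#' Applied to the encoder weights and the first per-gene hidden layer.
#'
#' @param w Weight matrix (output nodes x inputs).
#' @return Scalar penalty.
#' @export
structured_regularizer <- function(w) td_fre(w)

#' Total training loss
#'
#' Weighted sum of the five data losses, the structured regularizer on
#' `w_E` and `w_h1`, and ridge penalties on the remaining channel weights,
#' the attention weights and the per-gene gains `phi`.
#'
#' @param components Named list with scalars `L_I`, `L_R`, `L_P`, `L_LR`,
#'   `L_C` (tape nodes or numbers).
#' @param params A [disc_params()] object (tensors may be tape nodes).
#' @param weights A [loss_weights()] list.
#' @return Scalar total loss.
#' @export
total_loss <- function(components, params, weights) {
  P <- param_tensors(params)
  w <- weights
  acc <- function(a, b) if (is.null(a)) b else td_add(a, b)
  tot <- NULL
  tot <- acc(tot, td_mul(components$L_I, w$beta1))
  tot <- acc(tot, td_mul(components$L_R, w$beta2))
  tot <- acc(tot, td_mul(components$L_P, w$beta3))
  tot <- acc(tot, td_mul(components$L_LR, w$beta4))
  tot <- acc(tot, td_mul(components$L_C, w$beta5))
  tot <- acc(tot, td_mul(td_add(td_fre(P$w_E), td_fre(P$W1)), w$beta6))
  rid <- td_add(td_add(td_l2(P$W2), td_l2(P$Wp1)), td_l2(P$Wp2))
  tot <- acc(tot, td_mul(rid, w$beta7))
  tot <- acc(tot, td_mul(td_l2(P$Wa), w$beta8))
  tot <- acc(tot, td_mul(td_l2(P$phi), w$beta9))
  tot
}
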