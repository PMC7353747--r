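# Training loop: noise-to-noise corruption, one clean and one noisy forward
# pass per batch, Adam with global-norm gradient clipping, and the
# latent-loss-variance stopping rule.

#' Noise configuration for the noisy training pass
#'
#' @param mult_low,mult_high Bounds of the uniform multiplicative noise
#'   applied elementwise to the input (defaults 0.9 and 1.1).
#' @param zero_dropout_rate Probability of zeroing a zero-count position of
#'   each noisy recurrent input (default 0.5).
#' @param seed Optional seed for reproducible draws.
#' @return A `disc_noise_config` list.
#' @export
noise_config <- function(mult_low = 0.9, mult_high = 1.1,
                         zero_dropout_rate = 0.5, seed = NULL) {
  stopifnot(mult_low > 0, mult_low <= mult_high,
            zero_dropout_rate >= 0, zero_dropout_rate < 1)
  structure(list(mult_low = mult_low, mult_high = mult_high,
                 zero_dropout_rate = zero_dropout_rate, seed = seed),
            class = "disc_noise_config")
}

#' Draw the noisy input, noise target and per-step dropout masks
#'
#' The noisy first-step input is an independent elementwise uniform
#' multiplicative corruption of `x0`; the target is a second independent
#' draw.  Zero entries stay zero under multiplicative noise.  The returned
#' `zero_scale` masks (one per step) zero out zero-count positions of the
#' noisy recurrent inputs with probability `zero_dropout_rate`.
#'
#' @param x0 First-step input matrix.
#' @param cfg A [noise_config()].
#' @param n_steps Number of recurrence steps T.
#' @return List with `nx0`, `ny_target` and `zero_scale` (list of 0/1
#'   matrices, length `n_steps`).
#' @export
make_noisy_input <- function(x0, cfg = noise_config(), n_steps = 1L) {
  draw <- function() {
    n <- length(x0)
    u1 <- matrix(stats::runif(n, cfg$mult_low, cfg$mult_high),
                 nrow(x0), ncol(x0))
    u2 <- matrix(stats::runif(n, cfg$mult_low, cfg$mult_high),
                 nrow(x0), ncol(x0))
    zs <- lapply(seq_len(n_steps), function(t) {
      matrix(stats::rbinom(n, 1L, 1 - cfg$zero_dropout_rate),
             nrow(x0), ncol(x0))
    })
    list(nx0 = u1 * x0, ny_target = u2 * x0, zero_scale = zs)
  }
  if (!is.null(cfg$seed)) with_seed(cfg$seed, draw()) else draw()
}

## ---- optimizer -------------------------------------------------------------

zeros_like <- function(v) {
  if (is.null(dim(v))) numeric(length(v)) else array(0, dim = dim(v))
}

adam_init <- function(tensors) {
  list(t = 0L,
       m = lapply(tensors, zeros_like),
       v = lapply(tensors, zeros_like))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Clip gradients by global L2 norm
#'
#' @param grads Named list of gradient arrays.
#' @param max_norm Clipping bound (default 5).
#' @return The (possibly rescaled) gradient list.
#' @export
clip_gradients <- function(grads, max_norm = 5) {
  gn <- sqrt(sum(vapply(grads, function(g) sum(g * g), 0)))
  if (is.finite(gn) && gn > max_norm) {
    grads <- lapply(grads, function(g) g * (max_norm / gn))
  }
  grads
}

adam_update <- function(tensors, grads, state, lr = 1e-3,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(tensors)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    step <- lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    out <- tensors[[nm]] - step
    if (is.null(dim(out))) names(out) <- NULL else dimnames(out) <- NULL
    tensors[[nm]] <- out
  }
  list(tensors = tensors, state = state)
}

## ---- stopping rule ---------------------------------------------------------

#' Initialize the stopping-rule state
#'
#' Training stops when the standard deviation of the latent representation
#' loss over the last `window` batches fails to reach a new minimum for
#' `min_rounds` consecutive rounds, evaluated first after `warmup_cells`
#' cells and then every `round_cells` cells.
#'
#' @param window Number of batches in the STD window (default 10,000).
#' @param warmup_cells Cells consumed before the first check (default 5e6).
#' @param round_cells Cells per round between checks (default 5e4).
#' @param min_rounds Consecutive non-improving rounds required to stop
#'   (default 5).
#' @return A `disc_stop_state` list.
#' @export
stop_rule_init <- function(window = 10000L, warmup_cells = 5e6,
                           round_cells = 5e4, min_rounds = 5L) {
  structure(list(window = as.integer(window), warmup_cells = warmup_cells,
                 round_cells = round_cells, min_rounds = as.integer(min_rounds),
                 llr = numeric(0), cells_seen = 0,
                 next_check = warmup_cells,
                 min_std = Inf, min_round = 0L, checks = 0L),
            class = "disc_stop_state")
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Advance the stopping rule by one STD evaluation
#'
#' The first evaluation sets the minimum STD (minimum round = 1); each later
#' evaluation either increments the minimum round (no improvement) or resets
#' it to 1 with a new minimum STD.
#'
#' @param state A `disc_stop_state`.
#' @param new_std Standard deviation of the latent loss over the window.
#' @return Updated state.
#' @export
stop_rule_step <- function(state, new_std) {
  state$checks <- state$checks + 1L
  if (state$checks == 1L || new_std <= state$min_std) {
    state$min_std <- new_std
    state$min_round <- 1L
  } else {
    state$min_round <- state$min_round + 1L
  }
  state
}

#' Record per-batch latent losses and evaluate the rule at checkpoints
#'
#' @param state A `disc_stop_state`.
#' @param llr_values Numeric vector of per-batch latent loss values.
#' @param n_new_cells Number of cells consumed by those batches.
#' @return Updated state.
#' @export
stop_rule_record <- function(state, llr_values, n_new_cells) {
  state$llr <- c(state$llr, llr_values)
  if (length(state$llr) > state$window) {
    state$llr <- state$llr[(length(state$llr) - state$window + 1L):
                             length(state$llr)]
  }
  state$cells_seen <- state$cells_seen + n_new_cells
  while (state$cells_seen >= state$next_check) {
    state <- stop_rule_step(state, pop_sd(state$llr))
    state$next_check <- state$next_check + state$round_cells
    if (should_stop(state)) break
  }
  state
}

#' Has the stopping rule fired?
#'
#' @param state A `disc_stop_state`.
#' @return `TRUE` once the minimum round has reached `min_rounds`.
#' @export
should_stop <- function(state) state$min_round >= state$min_rounds

## ---- single optimization step ---------------------------------------------

# Global normalization statistics shared by every batch.
batch_input <- function(batch, stats) {
  C <- batch$counts
  ls <- batch$ls
  cn <- log1p(stats$scale_factor * C / ls)
  ln6 <- log1p(1e6 * C / ls)
  z <- sweep(ln6, 2L, stats$out_mu, "-")
  ok <- stats$out_sd > 0
  z[, ok] <- sweep(z[, ok, drop = FALSE], 2L, stats$out_sd[ok], "/")
  z[, !ok] <- 0
  outlier <- z > 3 & C > 0
  x0 <- pmin(sweep(cn, 2L, stats$gene_norm_max, "/"), 1)
  x0[outlier] <- 0   # outliers are unlabeled during training
  pos <- x0 > 0
  list(x0 = x0, pos = pos, zero = !pos, ls = ls, outlier = outlier)
}

#' One optimization step on a batch of cells
#'
#' Runs a clean forward pass (reconstruction, prediction, latent and
#' capacity losses) and an independent noisy pass (noise-to-noise imputation
#' loss), backpropagates the weighted total, clips the gradient at global
#' norm `clip` and applies one Adam update.
#'
#' @param batch List with `counts` (cells x genes) and `ls` (library sizes).
#' @param params A [disc_params()] object.
#' @param opt_state Adam state from a previous call, or `NULL`.
#' @param stats Normalization statistics (list with `scale_factor`,
#'   `gene_norm_max`, `out_mu`, `out_sd`) as computed by [fit()].
#' @param weights A [loss_weights()] list.
#' @param noise A [noise_config()].
#' @param lr Learning rate (default 0.001).
#' @param clip Gradient clipping bound (default 5).
#' @return List with updated `params`, `opt_state` and the named `losses` of
#'   the batch.
#' @export
train_step <- function(batch, params, opt_state, stats, weights,
                       noise = noise_config(), lr = 1e-3, clip = 5) {
  stopifnot(nrow(batch$counts) >= 1L)
  bi <- batch_input(batch, stats)
  nz <- make_noisy_input(bi$x0, noise, n_steps = params$dims$T)
  norm <- structure(list(gene_norm_max = stats$gene_norm_max,
                         scale_factor = stats$scale_factor),
                    class = "disc_norm")

  tape <- tape_new()
  pn <- params
  pn$tensors <- lapply(params$tensors, function(v) tp_param(tape, v))

  clean <- run_recurrence(bi$x0, pn)
  noisy <- run_recurrence(nz$nx0, pn, zero_scale = nz$zero_scale,
                          decode = FALSE)

  comps <- list(
    L_I = imputation_loss(noisy$y_comb, nz$ny_target, bi$pos),
    L_R = reconstruction_loss(clean$yhat_comb, clean$y_comb, bi$x0, bi$pos,
                              weights$alpha_R),
    L_P = prediction_loss(clean$y, clean$yhat, bi$x0, bi$pos,
                          weights$alpha_P1, weights$alpha_P2),
    L_LR = latent_representation_loss(clean$x_steps, pn$tensors$w_E),
    L_C = capacity_constraint_loss(clean$y, bi$zero, norm, bi$ls)
  )
  total <- total_loss(comps, pn, weights)
  if (!is.finite(total$value)) {
    stop(sprintf(
      "non-finite training loss (L_I=%.3g L_R=%.3g L_P=%.3g L_LR=%.3g L_C=%.3g)",
      vof(comps$L_I), vof(comps$L_R), vof(comps$L_P), vof(comps$L_LR),
      vof(comps$L_C)))
  }
  tp_backward(total)
  grads <- lapply(pn$tensors, function(nd) nd$grad %||% zeros_like(nd$value))
  grads <- clip_gradients(grads, clip)
  if (is.null(opt_state)) opt_state <- adam_init(params$tensors)
  upd <- adam_update(params$tensors, grads, opt_state, lr = lr)
  params$tensors <- upd$tensors
  losses <- c(vapply(comps, vof, 0), total = vof(total))
  list(params = params, opt_state = upd$state, losses = losses)
}

## ---- global statistics -----------------------------------------------------

# Two streaming passes over a chunk store: per-gene mean/sd of the
# 1e6-scaled log-normalized counts (outlier Z-scores), then the per-gene
# normalized maximum excluding outliers at the model scale factor.
store_stats <- function(store) {
  ls <- store$library_sizes
  if (any(ls <= 0)) stop("zero library size in store")
  sf <- stats::median(ls)
  M <- store$n_genes
  s1 <- numeric(M); s2 <- numeric(M); n <- 0
  pos <- 1L
  for (i in seq_len(store$n_chunks)) {
    C <- read_chunk(store, i)
    rows <- pos:(pos + nrow(C) - 1L); pos <- pos + nrow(C)
    ln6 <- log1p(1e6 * C / ls[rows])
    s1 <- s1 + colSums(ln6)
    s2 <- s2 + colSums(ln6 * ln6)
    n <- n + nrow(C)
  }
  mu <- s1 / n
  var <- pmax((s2 - n * mu * mu) / (n - 1), 0)
  sd <- sqrt(var)
  gmax <- rep(-Inf, M)
  gmax_all <- rep(-Inf, M)
  cnsum <- numeric(M)
  pos <- 1L
  for (i in seq_len(store$n_chunks)) {
    C <- read_chunk(store, i)
    rows <- pos:(pos + nrow(C) - 1L); pos <- pos + nrow(C)
    ln6 <- log1p(1e6 * C / ls[rows])
    z <- sweep(ln6, 2L, mu, "-")
    ok <- sd > 0
    z[, ok] <- sweep(z[, ok, drop = FALSE], 2L, sd[ok], "/")
    z[, !ok] <- 0
    cn <- log1p(sf * C / ls[rows])
    cnsum <- cnsum + colSums(cn)
    allmax <- apply(cn, 2L, max)
    cn[z > 3 & C > 0] <- -Inf
    gmax <- pmax(gmax, apply(cn, 2L, max))
    gmax_all <- pmax(gmax_all, allmax)
  }
  # A very sparse gene can have every positive entry flagged as an outlier
  # (its Z-scores are dominated by the zeros).  Such genes are fully
  # unlabeled during training -- all their positives are masked -- and their
  # normalization max falls back to the overall max so the gene still maps
  # into [0, 1].
  degenerate <- !is.finite(gmax) | gmax <= 0
  gmax[degenerate] <- gmax_all[degenerate]
  bad <- !is.finite(gmax) | gmax <= 0
  if (any(bad)) {
    stop("all-zero gene(s) (apply gene_selection first): ",
         paste(store$gene_ids[bad], collapse = ", "))
  }
  list(scale_factor = sf, gene_norm_max = gmax, out_mu = mu, out_sd = sd,
       mean_x0 = (cnsum / n) / gmax)
}

## ---- full training ---------------------------------------------------------

#' Training configuration
#'
#' All tunable training hyperparameters with their defaults.
#' `schedule_scale` multiplies the warmup, round and window sizes of the
#' stopping rule so the full procedure can be exercised on small data.
#'
#' @param S,T_steps,H1,H2,W Architecture dimensions (see [disc_params()]).
#' @param batch_size Cells per training batch (default 128).
#' @param chunk_size,sub_queue_chunks,n_loaders Streaming parameters (see
#'   [batch_stream()]).
#' @param lr Adam learning rate (default 0.001).
#' @param clip Gradient clipping bound (default 5).
#' @param warmup_cells,round_cells,window,min_rounds Stopping rule (see
#'   [stop_rule_init()]).
#' @param schedule_scale Multiplier applied to `warmup_cells`, `round_cells`
#'   and `window` (default 1).
#' @param max_cells Hard cap on cells consumed (default `Inf`).
#' @param noise A [noise_config()].
#' @param weights Optional [loss_weights()] overrides (list of named values).
#' @param seed Integer seed controlling initialization, streaming and noise.
#' @return A `disc_config` list.
#' @export
disc_config <- function(S = 512L, T_steps = 3L, H1 = 16L, H2 = 8L, W = 50L,
                        batch_size = 128L, chunk_size = 32L,
                        sub_queue_chunks = 64L, n_loaders = 2L,
                        lr = 1e-3, clip = 5,
                        warmup_cells = 5e6, round_cells = 5e4,
                        window = 10000L, min_rounds = 5L,
                        schedule_scale = 1, max_cells = Inf,
                        noise = noise_config(), weights = list(),
                        seed = 1L) {
  structure(as.list(environment()), class = "disc_config")
}

#' Fit the imputation model
#'
#' Streams globally random batches from the input, performs one
#' [train_step()] per batch, and stops when the latent-loss variance rule
#' fires (or `max_cells` is reached).  Gene selection
#' ([gene_selection()]) is assumed to have been applied.  Fully
#' reproducible for a fixed seed in single-threaded execution.
#'
#' @param x A [count_matrix()] object or a `disc_chunk_store`.
#' @param config A [disc_config()].
#' @return A `disc_model`: trained `params`, normalization statistics
#'   (`gene_norm_max`, `scale_factor`, `out_mu`, `out_sd`), the per-batch
#'   loss `trace` (data frame with columns batch, L_I, L_R, L_P, L_LR, L_C,
#'   total), `cells_seen`, `stopped` and the `config`.
#' @export
fit <- function(x, config = disc_config()) {
  store <- if (inherits(x, "disc_chunk_store")) x else {
    build_chunk_store(check_counts(x), path = NULL,
                      chunk_size = config$chunk_size)
  }
  cfg <- config
  with_seed(cfg$seed, {
    stats <- store_stats(store)
    M <- store$n_genes
    w <- do.call(loss_weights, c(list(n_genes = M), cfg$weights))
    params <- disc_params(M, S = cfg$S, T_steps = cfg$T_steps, H1 = cfg$H1,
                          H2 = cfg$H2, W = cfg$W, seed = sample.int(2^30, 1L),
                          gene_ids = store$gene_ids, mean_x0 = stats$mean_x0)
    stream <- batch_stream(store, batch_size = cfg$batch_size,
                           sub_queue_chunks = cfg$sub_queue_chunks,
                           n_loaders = cfg$n_loaders)
    stop_state <- stop_rule_init(
      window = max(10L, round(cfg$window * cfg$schedule_scale)),
      warmup_cells = cfg$warmup_cells * cfg$schedule_scale,
      round_cells = cfg$round_cells * cfg$schedule_scale,
      min_rounds = cfg$min_rounds)
    opt_state <- NULL
    trace <- list()
    cells_seen <- 0
    b <- 0L
    while (!should_stop(stop_state) && cells_seen < cfg$max_cells) {
      batch <- stream$next_batch()
      res <- train_step(batch, params, opt_state, stats, w,
                        noise = cfg$noise, lr = cfg$lr, clip = cfg$clip)
      params <- res$params
      opt_state <- res$opt_state
      b <- b + 1L
      cells_seen <- cells_seen + nrow(batch$counts)
      trace[[b]] <- c(batch = b, res$losses)
      stop_state <- stop_rule_record(stop_state, res$losses[["L_LR"]],
                                     nrow(batch$counts))
    }
    trace <- as.data.frame(do.call(rbind, trace))
    structure(list(params = params,
                   gene_norm_max = stats$gene_norm_max,
                   scale_factor = stats$scale_factor,
                   out_mu = stats$out_mu, out_sd = stats$out_sd,
                   trace = trace, cells_seen = cells_seen,
                   stopped = should_stop(stop_state),
                   config = cfg),
              class = "disc_model")
  })
}

#' @export
print.disc_model <- function(x, ...) {
  cat(sprintf(
    "disc_model: %d genes, trained on %.0f cells (%d batches)%s\n",
    x$params$dims$M, x$cells_seen, nrow(x$trace),
    if (x$stopped) ", stop rule fired" else ""))
  invisible(x)
}
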