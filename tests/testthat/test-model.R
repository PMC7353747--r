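test_that("normalization follows the log library-size formula", {
  C <- matrix(c(0, 10, 5, 85), 1, 4)
  cm <- count_matrix(C)
  out <- normalize_counts(cm, 50)
  expect_equal(out[1, 1], 0)                      # ln(1) = 0
  expect_equal(out[1, 2], log(6), tolerance = 1e-12)  # ln(50*10/100 + 1)
  # monotone in counts within a cell
  expect_true(all(diff(out[1, order(C[1, ])]) >= 0))
  zero <- count_matrix(matrix(c(0L, 5L, 0L, 4L), 2, 2))
  expect_error(normalize_counts(zero, 50), "cell1")
})

test_that("outlier detection flags Z > 3 and tolerates degenerate genes", {
  # constant positive gene: no outliers
  C <- matrix(5L, 10, 2)
  C[, 2] <- c(rep(2L, 9), 3L)
  mask <- detect_outliers(count_matrix(C))
  expect_false(any(mask[, 1]))
  # single large cell among 100: hand-computed Z exceeds 3
  C2 <- matrix(rep(c(3L, 4L), 50), 100, 2)
  C2[, 2] <- 0L
  C2[100, 2] <- 50L
  cm2 <- count_matrix(C2)
  mask2 <- detect_outliers(cm2)
  ln <- log1p(1e6 * C2[, 2] / rowSums(C2))
  z_hand <- (ln[100] - mean(ln)) / sd(ln)
  expect_gt(z_hand, 3)
  expect_true(mask2[100, 2])
  expect_equal(sum(mask2[, 2]), 1L)
  # zeros can never be outliers
  expect_false(any(mask2[C2 == 0]))
})

test_that("input preparation scales each gene to [0, 1]", {
  C <- matrix(c(2L, 4L, 8L, 0L, 5L, 0L), 3, 2)
  cm <- count_matrix(C)
  mask <- matrix(FALSE, 3, 2)
  norm <- prepare_input(cm, mask)
  expect_true(all(norm$x0 >= 0 & norm$x0 <= 1))
  expect_true(all((norm$x0 == 0) == (C == 0)))
  expect_equal(norm$scale_factor, median(rowSums(C)))
  expect_equal(norm$x0[2, 2], 1)   # the gene's single positive maps to 1
  # a gene whose only positive entries are outliers is rejected
  mask2 <- mask; mask2[2, 2] <- TRUE
  expect_error(prepare_input(cm, mask2), "gene2")
})

test_that("denormalize inverts input preparation exactly off outliers", {
  cm <- tiny_counts(6, 5, seed = 2)
  mask <- detect_outliers(cm)
  norm <- prepare_input(cm, mask)
  back <- denormalize(norm$x0, norm, cm$library_sizes)
  expect_lt(max(abs(back[!mask] - cm$counts[!mask])), 1e-9)
  expect_equal(denormalize(matrix(0, 1, 5), norm, 10),
               matrix(0, 1, 5))
  expect_error(denormalize(matrix(-0.1, 1, 5), norm, 10), "negative")
})

test_that("encoder, decoder and predictor match per-element loop oracles", {
  m <- 4
  params <- tiny_params(m, S = 2, T_steps = 2, H1 = 3, H2 = 2)
  P <- params$tensors
  x <- matrix(runif(2 * m), 2, m)
  z <- encoder_forward(x, params)
  # hand loop
  z_hand <- matrix(0, 2, 2)
  for (c in 1:2) for (s in 1:2) z_hand[c, s] <- tanh(sum(P$w_E[s, ] * x[c, ]))
  expect_equal(z, z_hand, tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(all(abs(z) < 1))
  expect_equal(encoder_forward(matrix(0, 1, m), params),
               matrix(0, 1, 2), ignore_attr = TRUE)
  expect_error(encoder_forward(matrix(0, 1, m + 1), params), "mismatch")

  yhat <- decoder_forward(z, params)
  sig <- function(v) 1 / (1 + exp(-v))
  yhat_hand <- matrix(0, 2, m)
  for (c in 1:2) for (g in 1:m) {
    pre <- sum(P$w_E[, g] * z[c, ]) + P$b_D[g]
    yhat_hand[c, g] <- sig(2 * (P$phi[g] + 1) * pre)
  }
  expect_equal(yhat, yhat_hand, tolerance = 1e-12, ignore_attr = TRUE)
  # z = 0, b_D = 0 gives 0.5 everywhere
  expect_equal(decoder_forward(matrix(0, 1, 2), params),
               matrix(0.5, 1, m), ignore_attr = TRUE)

  pr <- predictor_forward(z, params)
  selu <- function(v) 1.0507009873554805 *
    ifelse(v > 0, v, 1.6732632423543772 * (exp(v) - 1))
  for (c in 1:2) for (g in 1:m) {
    h1 <- (P$phi[g] + 1) * (P$W1[(0:2) * m + g, ] %*% z[c, ] + P$b1[(0:2) * m + g])
    h2 <- (P$phi[g] + 1) * (P$W2[g, , ] %*% tanh(h1) + P$b2[g, ])
    psi <- sig(selu(sum(P$Wpsi[g, 1, ] * tanh(h2))))
    o1 <- sum(P$Wp1[g, 1, ] * tanh(h2)) + P$bp1[g, 1]
    o2 <- sum(P$Wp2[g, 1, ] * tanh(h2)) + P$bp2[g, 1]
    y <- sig(2 * (P$phi[g] + 1) * (psi * o1 + (1 - psi) * o2))
    expect_equal(pr$y[c, g], y, tolerance = 1e-10)
    expect_equal(pr$psi[c, g], psi, tolerance = 1e-10)
    expect_equal(pr$h1[c, (0:2) * m + g], as.vector(h1), tolerance = 1e-10)
  }
  # all-zero weights give the symmetric gate and output
  p0 <- params
  for (nm in names(p0$tensors)) p0$tensors[[nm]][] <- 0
  pr0 <- predictor_forward(matrix(0.3, 1, 2), p0)
  expect_equal(pr0$psi, matrix(0.5, 1, m), ignore_attr = TRUE)
  expect_equal(pr0$y, matrix(0.5, 1, m), ignore_attr = TRUE)
})

test_that("the positive-count filter keeps observed values", {
  x0 <- matrix(c(0.5, 0, 0, 0.2), 2, 2)
  y <- matrix(c(0.9, 0.8, 0.7, 0.6), 2, 2)
  expect_equal(filter_next_input(x0, y),
               matrix(c(0.5, 0.8, 0.7, 0.2), 2, 2))
  expect_equal(filter_next_input(x0, x0), x0)           # fixed point
  allpos <- matrix(0.4, 2, 2)
  expect_equal(filter_next_input(allpos, y), allpos)
  expect_equal(filter_next_input(matrix(0, 2, 2), y), y)
})

test_that("attention weights are a softmax over steps", {
  m <- 4
  params <- tiny_params(m, S = 2, T_steps = 3, H1 = 3, H2 = 2)
  h1s <- lapply(1:3, function(t) matrix(rnorm(2 * 3 * m), 2, 3 * m))
  ys <- lapply(1:3, function(t) matrix(runif(2 * m), 2, m))
  comb <- attention_combine(h1s, ys, ys, params)
  asum <- Reduce(`+`, comb$a)
  expect_equal(asum, matrix(1, 2, m), tolerance = 1e-12, ignore_attr = TRUE)
  # brute-force softmax oracle
  P <- params$tensors
  selu <- function(v) 1.0507009873554805 *
    ifelse(v > 0, v, 1.6732632423543772 * (exp(v) - 1))
  for (c in 1:2) for (g in 1:m) {
    logits <- vapply(1:3, function(t) {
      sum(P$Wa[g, 1, ] * selu(h1s[[t]][c, (0:2) * m + g]))
    }, 0)
    aa <- exp(logits) / sum(exp(logits))
    got <- vapply(comb$a, function(x) x[c, g], 0)
    expect_equal(got, aa, tolerance = 1e-10)
    expect_equal(comb$y[c, g],
                 sum(aa * vapply(ys, function(x) x[c, g], 0)),
                 tolerance = 1e-10)
  }
  # single step: weight is identically 1
  c1 <- attention_combine(h1s[1], ys[1], ys[1], params)
  expect_equal(c1$a[[1]], matrix(1, 2, m), ignore_attr = TRUE)
  expect_equal(c1$y, ys[[1]])
  # identical logits: 1/T each
  cid <- attention_combine(list(h1s[[1]], h1s[[1]]), ys[1:2], ys[1:2], params)
  expect_equal(cid$a[[1]], matrix(0.5, 2, m), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(attention_combine(list(), list(), list(), params), "step")
})

test_that("the recurrence composes the components step by step", {
  cm <- tiny_counts(5, 4, seed = 4)
  norm <- prepare_input(cm, matrix(FALSE, 5, 4))
  params <- tiny_params(4, S = 2, T_steps = 3, H1 = 3, H2 = 2)
  fw <- run_recurrence(norm, params)
  # manual unroll
  x <- norm$x0
  for (t in 1:3) {
    z <- encoder_forward(x, params)
    pr <- predictor_forward(z, params)
    expect_equal(fw$z[[t]], z)
    expect_equal(fw$y[[t]], pr$y)
    expect_equal(fw$yhat[[t]], decoder_forward(z, params))
    x <- filter_next_input(norm$x0, pr$y)
    expect_equal(fw$x_steps[[t + 1]], x)
  }
  # positive positions of every recurrent input equal x0 exactly
  pos <- norm$x0 > 0
  for (t in seq_along(fw$x_steps)) {
    expect_identical(fw$x_steps[[t]][pos], norm$x0[pos])
  }
  expect_equal(length(fw$x_steps), 4L)
})

test_that("compressor is a tied-weight autoencoder over stacked latents", {
  m <- 4
  params <- tiny_params(m, S = 2, T_steps = 2, H1 = 3, H2 = 2, W = 2)
  z_steps <- list(matrix(rnorm(6), 3, 2), matrix(rnorm(6), 3, 2))
  out <- compress(z_steps, params)
  P <- params$tensors
  zall <- cbind(z_steps[[1]], z_steps[[2]])
  for (c in 1:3) {
    cp_hand <- tanh(P$Wz %*% zall[c, ] + P$bz1)
    expect_equal(out$cp[c, ], as.vector(cp_hand), tolerance = 1e-12)
    zt_hand <- tanh(t(P$Wz) %*% cp_hand + P$bz2)
    expect_equal(out$z_tilde[c, ], as.vector(zt_hand), tolerance = 1e-12)
  }
  # zero weights: cp = tanh(b_z1)
  p0 <- params; p0$tensors$Wz[] <- 0; p0$tensors$bz1 <- c(0.3, -0.2)
  out0 <- compress(z_steps, p0)
  expect_equal(out0$cp, matrix(rep(tanh(c(0.3, -0.2)), each = 3), 3, 2),
               ignore_attr = TRUE)
  expect_error(compress(list(matrix(0, 3, 3)), params), "mismatch")
})

test_that("imputation passes outliers and conservative positives through", {
  set.seed(9)
  C <- matrix(rpois(40 * 6, 4), 40, 6)
  C[C == 1] <- 2
  C[3, 2] <- 400L   # planted outlier
  cm <- count_matrix(C)
  mask <- detect_outliers(cm)
  expect_true(mask[3, 2])
  cfg <- disc_config(S = 4, T_steps = 2, H1 = 3, H2 = 2, W = 3,
                     batch_size = 20, chunk_size = 8,
                     schedule_scale = 1e-4, max_cells = 400, seed = 5)
  model <- fit(cm, cfg)
  res <- impute(cm, model)
  expect_identical(res$imputed_counts[mask], C[mask])
  expect_true(all(res$imputed_counts >= 0))
  expect_true(all(is.finite(res$imputed_counts)))
  expect_equal(dim(res$latent_features), c(40L, 3L))
  cons <- impute(cm, model, mode = "conservative")
  keep <- C > 0
  expect_identical(cons$imputed_counts[keep], C[keep])
  # gene-set compatibility is enforced
  other <- count_matrix(C[, 1:5],
                        gene_ids = paste0("x", 1:5))
  expect_error(impute(other, model), "gene")
})
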