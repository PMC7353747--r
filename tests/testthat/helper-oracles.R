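# Independent naive reference implementations (explicit loops over cells,
# genes and steps) used to validate the vectorized package code, plus small
# fixture builders.  These deliberately share no code with the package.

oracle_L_I <- function(ny, nyt, pos) {
  s <- 0
  for (c in seq_len(nrow(ny))) for (m in seq_len(ncol(ny))) {
    if (pos[c, m]) s <- s + abs(ny[c, m] - nyt[c, m])
  }
  s / nrow(ny)
}

oracle_L_R <- function(yhat, y, x0, pos, aR) {
  s <- 0
  for (c in seq_len(nrow(yhat))) for (m in seq_len(ncol(yhat))) {
    if (pos[c, m]) {
      s <- s + aR * (yhat[c, m] - x0[c, m])^2
    } else {
      s <- s + (yhat[c, m] - y[c, m])^2
    }
  }
  s / nrow(yhat)
}

oracle_L_P <- function(y_steps, yhat_steps, x0, pos, a1, a2) {
  s <- 0
  for (t in seq_along(y_steps)) {
    for (c in seq_len(nrow(x0))) for (m in seq_len(ncol(x0))) {
      if (pos[c, m]) {
        s <- s + a1 * (y_steps[[t]][c, m] - x0[c, m])^2
      } else {
        s <- s + a2 * (y_steps[[t]][c, m] - yhat_steps[[t]][c, m])^2
      }
    }
  }
  s / nrow(x0)
}

oracle_L_LR <- function(x_steps, wE) {
  s <- 0
  T_steps <- length(x_steps) - 1
  for (t in seq_along(x_steps)[-1]) {
    p1 <- x_steps[[t]] %*% t(wE)
    p0 <- x_steps[[t - 1]] %*% t(wE)
    for (c in seq_len(nrow(p1))) s <- s + sum((p1[c, ] - p0[c, ])^2)
  }
  s / (nrow(x_steps[[1]]) * T_steps)
}

oracle_L_C <- function(y_steps, zero, gmax, sf, ls) {
  s <- 0
  for (t in seq_along(y_steps)) {
    for (c in seq_len(nrow(zero))) for (m in seq_len(ncol(zero))) {
      if (zero[c, m]) {
        v <- (exp(y_steps[[t]][c, m] * gmax[m]) - 1) * ls[c] / sf
        s <- s + v^2
      }
    }
  }
  s
}

oracle_fre <- function(w) {
  s <- 0
  for (i in seq_len(nrow(w))) s <- s + sum(w[i, ]^2)^2
  s
}

oracle_gini <- function(x) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) s <- s + abs(x[i] - x[j])
  s / (2 * n^2 * mean(x))
}

oracle_ari <- function(a, b) {
  n <- length(a)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) s11 <- s11 + 1
    else if (!sa && !sb) s00 <- s00 + 1
    else if (sa) s10 <- s10 + 1
    else s01 <- s01 + 1
  }
  np <- s11 + s00 + s10 + s01
  exp_idx <- (s11 + s10) * (s11 + s01) / np
  max_idx <- ((s11 + s10) + (s11 + s01)) / 2
  if (max_idx == exp_idx) return(as.numeric(s11 == exp_idx))
  (s11 - exp_idx) / (max_idx - exp_idx)
}

oracle_ff <- function(a, b) {
  quad <- function(pts, cx, cy) {
    n <- nrow(pts)
    q <- c(0, 0, 0, 0)
    for (i in seq_len(n)) {
      lx <- pts[i, 1] <= cx; ly <- pts[i, 2] <= cy
      k <- if (lx && ly) 1 else if (lx) 2 else if (ly) 3 else 4
      q[k] <- q[k] + 1
    }
    q / n
  }
  dmax <- function(centers) {
    d <- 0
    for (i in seq_len(nrow(centers))) {
      qa <- quad(a, centers[i, 1], centers[i, 2])
      qb <- quad(b, centers[i, 1], centers[i, 2])
      d <- max(d, max(abs(qa - qb)))
    }
    d
  }
  (dmax(a) + dmax(b)) / 2
}

oracle_mae <- function(ref, test, ls_ref, ls_test) {
  out <- numeric(nrow(ref))
  for (c in seq_len(nrow(ref))) {
    s <- 0; k <- 0
    for (m in seq_len(ncol(ref))) {
      if (ref[c, m] > 0) {
        s <- s + abs(test[c, m] * ls_ref[c] / ls_test[c] - ref[c, m])
        k <- k + 1
      }
    }
    out[c] <- s / k
  }
  out
}

# -- fixtures -----------------------------------------------------------------

tiny_counts <- function(n = 6, m = 5, seed = 1, lambda = 3) {
  set.seed(seed)
  C <- matrix(rpois(n * m, lambda), n, m)
  C[1, ] <- C[1, ] + 1   # guard against an all-zero cell
  if (any(colSums(C) == 0)) C[2, colSums(C) == 0] <- 2
  C[C == 1] <- 2         # keep every gene past the max-count-1 filter
  count_matrix(C)
}

tiny_params <- function(m, S = 3, T_steps = 2, H1 = 3, H2 = 2, W = 2,
                        seed = 7) {
  disc_params(m, S = S, T_steps = T_steps, H1 = H1, H2 = H2, W = W,
              seed = seed)
}

# random per-step tensors for loss oracle checks: 4 cells x 6 genes x 3 steps
random_loss_fixture <- function(seed) {
  set.seed(seed)
  n <- 4; m <- 6; T_steps <- 3
  x0 <- matrix(runif(n * m), n, m)
  x0[matrix(runif(n * m) < 0.4, n, m)] <- 0
  list(
    n = n, m = m, T_steps = T_steps, x0 = x0, pos = x0 > 0,
    ny = matrix(runif(n * m), n, m), nyt = matrix(runif(n * m), n, m),
    yhat = matrix(runif(n * m), n, m), y = matrix(runif(n * m), n, m),
    y_steps = lapply(1:T_steps, function(t) matrix(runif(n * m), n, m)),
    yhat_steps = lapply(1:T_steps, function(t) matrix(runif(n * m), n, m)),
    x_steps = lapply(1:(T_steps + 1), function(t) matrix(runif(n * m), n, m)),
    wE = matrix(rnorm(3 * m, sd = 0.5), 3, m),
    gmax = runif(m, 1, 3), ls = rpois(n, 50) + 10, sf = 40
  )
}
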