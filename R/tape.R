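# Reverse-mode automatic differentiation on a flat tape.
#
# The model's training objective mixes dense matrix algebra with per-gene
# channel operations, so the gradient machinery is written once here and the
# forward model is expressed in these ops.  Every op accepts either a plain
# numeric array (treated as a constant) or a `disc_node`; when no argument is
# a node the op simply returns the numeric result, which lets the same
# forward code serve both inference and training.

selu_lambda <- 1.0507009873554805
selu_alpha <- 1.6732632423543772

#' @noRd
tape_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

new_node <- function(tape, value, parents, backfn) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backfn <- backfn
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  nd$id <- tape$n
  nd$tape <- tape
  tape$nodes[[tape$n]] <- nd
  class(nd) <- "disc_node"
  nd
}

is_node <- function(x) inherits(x, "disc_node")
vof <- function(x) if (is_node(x)) x$value else x

find_tape <- function(...) {
  for (x in list(...)) if (is_node(x)) return(x$tape)
  NULL
}

#' @noRd
tp_param <- function(tape, value) {
  new_node(tape, value, list(), function(g) list())
}

accum_grad <- function(nd, g) {
  if (is.null(nd$grad)) nd$grad <- g else nd$grad <- nd$grad + g
}

# Backward sweep from a scalar node; afterwards every parameter node created
# on the tape carries its gradient in $grad.
#' @noRd
tp_backward <- function(loss) {
  stopifnot(is_node(loss), length(loss$value) == 1L)
  tape <- loss$tape
  loss$grad <- 1
  for (i in seq(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad) || length(nd$parents) == 0L) next
    gs <- nd$backfn(nd$grad)
    for (k in seq_along(nd$parents)) {
      p <- nd$parents[[k]]
      if (is_node(p) && !is.null(gs[[k]])) accum_grad(p, gs[[k]])
    }
  }
  invisible(loss)
}

## ---- primitive ops ---------------------------------------------------------

td_matmul <- function(a, b, ta = FALSE, tb = FALSE) {
  av <- vof(a); bv <- vof(b)
  ae <- if (ta) t(av) else av
  be <- if (tb) t(bv) else bv
  val <- ae %*% be
  tape <- find_tape(a, b)
  if (is.null(tape)) return(val)
  new_node(tape, val, list(a, b), function(g) {
    da <- if (is_node(a)) {
      d <- g %*% t(be)
      if (ta) t(d) else d
    }
    db <- if (is_node(b)) {
      d <- t(ae) %*% g
      if (tb) t(d) else d
    }
    list(da, db)
  })
}

td_add <- function(a, b) {
  av <- vof(a); bv <- vof(b)
  val <- av + bv
  tape <- find_tape(a, b)
  if (is.null(tape)) return(val)
  new_node(tape, val, list(a, b), function(g) {
    list(if (is_node(a)) { if (length(av) == 1L) sum(g) else g },
         if (is_node(b)) { if (length(bv) == 1L) sum(g) else g })
  })
}

td_sub <- function(a, b) {
  av <- vof(a); bv <- vof(b)
  val <- av - bv
  tape <- find_tape(a, b)
  if (is.null(tape)) return(val)
  new_node(tape, val, list(a, b), function(g) {
    list(if (is_node(a)) { if (length(av) == 1L) sum(g) else g },
         if (is_node(b)) { if (length(bv) == 1L) -sum(g) else -g })
  })
}

# Elementwise product; either side may be a scalar or a conforming array.
td_mul <- function(a, b) {
  av <- vof(a); bv <- vof(b)
  val <- av * bv
  tape <- find_tape(a, b)
  if (is.null(tape)) return(val)
  new_node(tape, val, list(a, b), function(g) {
    da <- if (is_node(a)) { d <- g * bv; if (length(av) == 1L) sum(d) else d }
    db <- if (is_node(b)) { d <- g * av; if (length(bv) == 1L) sum(d) else d }
    list(da, db)
  })
}

td_div <- function(a, b) {
  av <- vof(a); bv <- vof(b)
  val <- av / bv
  tape <- find_tape(a, b)
  if (is.null(tape)) return(val)
  new_node(tape, val, list(a, b), function(g) {
    da <- if (is_node(a)) { d <- g / bv; if (length(av) == 1L) sum(d) else d }
    db <- if (is_node(b)) { d <- -g * av / (bv * bv); if (length(bv) == 1L) sum(d) else d }
    list(da, db)
  })
}

td_tanh <- function(a) {
  val <- tanh(vof(a))
  tape <- find_tape(a)
  if (is.null(tape)) return(val)
  new_node(tape, val, list(a), function(g) list(g * (1 - val * val)))
}

td_sigmoid <- function(a) {
  val <- 1 / (1 + exp(-vof(a)))
  tape <- find_tape(a)
  if (is.null(tape)) return(val)
  new_node(tape, val, list(a), function(g) list(g * val * (1 - val)))
}

td_selu <- function(a) {
  av <- vof(a)
  neg <- av <= 0
  val <- av
  val[neg] <- selu_alpha * (exp(av[neg]) - 1)
  val <- selu_lambda * val
  tape <- find_tape(a)
  if (is.null(tape)) return(val)
  new_node(tape, val, list(a), function(g) {
    d <- array(selu_lambda, dim = dim(av) %||% length(av))
    d[neg] <- selu_lambda * selu_alpha * exp(av[neg])
    list(g * d)
  })
}

td_exp <- function(a) {
  val <- exp(vof(a))
  tape <- find_tape(a)
  if (is.null(tape)) return(val)
  new_node(tape, val, list(a), function(g) list(g * val))
}

td_abs <- function(a) {
  av <- vof(a)
  val <- abs(av)
  tape <- find_tape(a)
  if (is.null(tape)) return(val)
  new_node(tape, val, list(a), function(g) list(g * sign(av)))
}

td_sum <- function(a) {
  av <- vof(a)
  val <- sum(av)
  tape <- find_tape(a)
  if (is.null(tape)) return(val)
  new_node(tape, val, list(a), function(g) {
    d <- array(g, dim = if (is.null(dim(av))) length(av) else dim(av))
    if (is.null(dim(av))) d <- as.vector(d)
    list(d)
  })
}

# Sum of squares of all entries (ridge penalty on a tensor).
td_l2 <- function(a) {
  av <- vof(a)
  val <- sum(av * av)
  tape <- find_tape(a)
  if (is.null(tape)) return(val)
  new_node(tape, val, list(a), function(g) list(2 * g * av))
}

# Structured sparsity regularizer: for each output node (row of w), the
# square of the sum of squared incoming weights.
td_fre <- function(a) {
  av <- vof(a)
  rs <- rowSums(av * av)
  val <- sum(rs * rs)
  tape <- find_tape(a)
  if (is.null(tape)) return(val)
  new_node(tape, val, list(a), function(g) list(4 * g * av * rs))
}

# Add a length-ncol bias vector to every row.
td_bias_row <- function(a, b) {
  av <- vof(a); bv <- vof(b)
  val <- sweep(av, 2L, bv, "+")
  tape <- find_tape(a, b)
  if (is.null(tape)) return(val)
  new_node(tape, val, list(a, b), function(g) {
    list(if (is_node(a)) g, if (is_node(b)) colSums(g))
  })
}

# Multiply column j of a by (phi + 1)[gene_of_col[j]], broadcast over rows.
# gene_of_col maps columns of a to gene indices of phi.
td_gene_scale <- function(a, phi, gene_of_col) {
  av <- vof(a); pv <- vof(phi)
  fac <- (pv + 1)[gene_of_col]
  n <- nrow(av)
  facx <- rep(fac, each = n)
  val <- av * facx
  tape <- find_tape(a, phi)
  if (is.null(tape)) return(val)
  M <- length(pv)
  H <- length(gene_of_col) %/% M
  tiled <- identical(gene_of_col, rep(seq_len(M), H))
  new_node(tape, val, list(a, phi), function(g) {
    da <- if (is_node(a)) g * facx
    dp <- if (is_node(phi)) {
      cs <- .colSums(g * av, n, length(gene_of_col))
      if (tiled) .rowSums(cs, M, H) else as.vector(rowsum(cs, gene_of_col))
    }
    list(da, dp)
  })
}

# Batched per-gene dense layer.  `a` is N x (h_in * M) in unit-major layout
# (columns [ (i-1)*M + 1 .. i*M ] hold hidden unit i for all M genes); W is an
# (M, h_out, h_in) array of per-gene weights, b an optional (M, h_out) bias.
# Numerically identical to looping gene-by-gene over M small dense layers.
td_gene_linear <- function(a, W, b, h_in, h_out, M) {
  av <- vof(a); Wv <- vof(W); bv <- if (is.null(b)) NULL else vof(b)
  n <- nrow(av)
  val <- cpp_gene_linear_fwd(av, Wv, if (is.null(bv)) numeric(1) else bv,
                             n, M, h_in, h_out, !is.null(bv))
  tape <- find_tape(a, W, b)
  if (is.null(tape)) return(val)
  new_node(tape, val, list(a, W, b), function(g) {
    bw <- cpp_gene_linear_bwd(g, av, Wv, n, M, h_in, h_out,
                              is_node(a), is_node(W),
                              !is.null(b) && is_node(b))
    dW <- bw$dW
    if (!is.null(dW)) dim(dW) <- dim(Wv)
    list(bw$da, dW, bw$db)
  })
}

td_cbind <- function(lst) {
  vals <- lapply(lst, vof)
  val <- do.call(cbind, vals)
  tape <- do.call(find_tape, lst)
  if (is.null(tape)) return(val)
  widths <- vapply(vals, ncol, 1L)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  new_node(tape, val, lst, function(g) {
    lapply(seq_along(lst), function(k) {
      if (is_node(lst[[k]])) g[, starts[k]:ends[k], drop = FALSE]
    })
  })
}

td_cols <- function(a, idx) {
  av <- vof(a)
  val <- av[, idx, drop = FALSE]
  tape <- find_tape(a)
  if (is.null(tape)) return(val)
  new_node(tape, val, list(a), function(g) {
    d <- matrix(0, nrow(av), ncol(av))
    d[, idx] <- g
    list(d)
  })
}

# Value without gradient: pseudo-label targets are constants within a step.
td_detach <- function(a) vof(a)

# softmax across a list of conforming matrices (the recurrence-step axis),
# shifted by the running elementwise max for stability.
td_softmax_steps <- function(logits) {
  mx <- vof(logits[[1L]])
  for (k in seq_along(logits)[-1L]) mx <- pmax(mx, vof(logits[[k]]))
  ex <- lapply(logits, function(l) td_exp(td_sub(l, mx)))
  tot <- ex[[1L]]
  for (k in seq_along(ex)[-1L]) tot <- td_add(tot, ex[[k]])
  lapply(ex, function(e) td_div(e, tot))
}
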