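# Minimal reverse-mode automatic differentiation over dense matrices.
#
# Every value is a numeric matrix (scalars are 1x1).  Nodes are
# environments; each op appends its node to the active tape, so creation
# order is a topological order and the backward sweep is a single reverse
# pass over the tape.  Parameter leaves live outside any tape and
# accumulate gradients across tapes until `ad_zero_grads()`.
#
# The engine exists to train the sequence tagger; its gradients are
# verified against central finite differences in the test suite.

.ad <- new.env(parent = emptyenv())
.ad$tape <- NULL

ad_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 2048L)
  t$n <- 0L
  t
}

# Run `expr` with a fresh tape; returns list(result, tape).
ad_with_tape <- function(expr) {
  old <- .ad$tape
  .ad$tape <- ad_tape()
  on.exit(.ad$tape <- old)
  res <- force(expr)
  list(result = res, tape = .ad$tape)
}

ad_record <- function(node) {
  t <- .ad$tape
  if (is.null(t)) return(node)   # outside a tape: value-only use
  n <- t$n + 1L
  if (n > length(t$nodes)) t$nodes <- c(t$nodes, vector("list", length(t$nodes)))
  t$nodes[[n]] <- node
  t$n <- n
  node
}

ad_node <- function(v, parents = NULL, pback = NULL) {
  e <- new.env(parent = emptyenv())
  e$v <- v
  e$grad <- NULL
  e$parents <- parents
  e$pback <- pback
  class(e) <- "ad_node"
  ad_record(e)
}

# Parameter or constant leaf.  Leaves are never on a tape.
ad_leaf <- function(v) {
  e <- new.env(parent = emptyenv())
  e$v <- as_mat(v)
  e$grad <- NULL
  e$parents <- NULL
  e$pback <- NULL
  class(e) <- "ad_node"
  e
}

as_mat <- function(v) {
  if (is.matrix(v)) v else matrix(v, ncol = 1L)
}

ad_value <- function(x) x$v

accum_grad <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
}

# Reverse sweep from `loss` (1x1) over `tape`.
ad_backward <- function(loss, tape) {
  stopifnot(length(loss$v) == 1L)
  loss$grad <- matrix(1)
  for (i in seq(tape$n, 1L)) {
    node <- tape$nodes[[i]]
    g <- node$grad
    if (is.null(g)) next
    ps <- node$parents
    if (is.null(ps)) next
    pb <- node$pback
    for (k in seq_along(ps)) accum_grad(ps[[k]], pb[[k]](g))
  }
  invisible(NULL)
}

ad_zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# ---- ops --------------------------------------------------------------

ad_matmul <- function(a, b) {
  ad_node(a$v %*% b$v, list(a, b),
          list(function(g) g %*% t(b$v),
               function(g) t(a$v) %*% g))
}

ad_add <- function(a, b) {
  ad_node(a$v + b$v, list(a, b),
          list(function(g) g, function(g) g))
}

ad_sub <- function(a, b) {
  ad_node(a$v - b$v, list(a, b),
          list(function(g) g, function(g) -g))
}

# a: (n x m), bias: (n x 1) added to every column.
ad_add_bias <- function(a, bias) {
  ad_node(a$v + as.vector(bias$v), list(a, bias),
          list(function(g) g,
               function(g) matrix(rowSums(g), ncol = 1L)))
}

ad_hadamard <- function(a, b) {
  ad_node(a$v * b$v, list(a, b),
          list(function(g) g * b$v,
               function(g) g * a$v))
}

ad_scale <- function(a, s) {   # s: plain numeric scalar
  ad_node(a$v * s, list(a), list(function(g) g * s))
}

ad_sigmoid <- function(a) {
  y <- 1 / (1 + exp(-a$v))
  ad_node(y, list(a), list(function(g) g * y * (1 - y)))
}

ad_tanh <- function(a) {
  y <- tanh(a$v)
  ad_node(y, list(a), list(function(g) g * (1 - y * y)))
}

ad_transpose <- function(a) {
  ad_node(t(a$v), list(a), list(function(g) t(g)))
}

# Softmax over rows within each column.
ad_softmax_col <- function(a) {
  x <- a$v
  mx <- apply(x, 2L, max)
  ex <- exp(sweep(x, 2L, mx))
  y <- sweep(ex, 2L, colSums(ex), "/")
  ad_node(y, list(a), list(function(g) {
    y * sweep(g, 2L, colSums(g * y))
  }))
}

# Column-wise log-sum-exp: (r x c) -> (1 x c).
ad_logsumexp_col <- function(a) {
  x <- a$v
  mx <- apply(x, 2L, max)
  s <- log(colSums(exp(sweep(x, 2L, mx)))) + mx
  y <- matrix(s, nrow = 1L)
  ad_node(y, list(a), list(function(g) {
    sweep(exp(sweep(x, 2L, s)), 2L, as.vector(g), "*")
  }))
}

# log-sum-exp over all entries -> 1x1.
ad_logsumexp <- function(a) {
  x <- a$v
  mx <- max(x)
  s <- log(sum(exp(x - mx))) + mx
  ad_node(matrix(s), list(a), list(function(g) {
    as.vector(g) * exp(x - s)
  }))
}

ad_sum <- function(a) {
  ad_node(matrix(sum(a$v)), list(a), list(function(g) {
    matrix(as.vector(g), nrow = nrow(a$v), ncol = ncol(a$v))
  }))
}

ad_rows <- function(a, idx) {
  ad_node(a$v[idx, , drop = FALSE], list(a), list(function(g) {
    out <- matrix(0, nrow(a$v), ncol(a$v))
    out[idx, ] <- g
    out
  }))
}

ad_col <- function(a, j) {
  ad_node(a$v[, j, drop = FALSE], list(a), list(function(g) {
    out <- matrix(0, nrow(a$v), ncol(a$v))
    out[, j] <- g
    out
  }))
}

# Submatrix a[rows, cols].
ad_submatrix <- function(a, rows, cols) {
  ad_node(a$v[rows, cols, drop = FALSE], list(a), list(function(g) {
    out <- matrix(0, nrow(a$v), ncol(a$v))
    out[rows, cols] <- g
    out
  }))
}

# Embedding lookup: rows of `emb` (V x d) selected by integer idx, with
# scatter-add on the way back (idx may repeat).
ad_lookup <- function(emb, idx) {
  ad_node(emb$v[idx, , drop = FALSE], list(emb), list(function(g) {
    out <- matrix(0, nrow(emb$v), ncol(emb$v))
    acc <- rowsum(g, group = idx)
    out[as.integer(rownames(acc)), ] <- acc
    out
  }))
}

ad_concat_rows <- function(nodes) {
  vs <- lapply(nodes, ad_value)
  nr <- vapply(vs, nrow, 0L)
  offs <- cumsum(c(0L, nr))
  pb <- lapply(seq_along(nodes), function(k) {
    force(k)
    function(g) g[(offs[k] + 1L):offs[k + 1L], , drop = FALSE]
  })
  ad_node(do.call(rbind, vs), nodes, pb)
}

ad_concat_cols <- function(nodes) {
  vs <- lapply(nodes, ad_value)
  nc <- vapply(vs, ncol, 0L)
  offs <- cumsum(c(0L, nc))
  pb <- lapply(seq_along(nodes), function(k) {
    force(k)
    function(g) g[, (offs[k] + 1L):offs[k + 1L], drop = FALSE]
  })
  ad_node(do.call(cbind, vs), nodes, pb)
}

# Zero-padded shift along columns: k = +1 moves content right.
ad_shift_cols <- function(a, k) {
  x <- a$v
  w <- ncol(x)
  shift <- function(m, k) {
    out <- matrix(0, nrow(m), ncol(m))
    if (k >= 0) {
      if (k < w) out[, (k + 1L):w] <- m[, 1L:(w - k), drop = FALSE]
    } else {
      if (-k < w) out[, 1L:(w + k)] <- m[, (1L - k):w, drop = FALSE]
    }
    out
  }
  ad_node(shift(x, k), list(a), list(function(g) shift(g, -k)))
}

# Scale column j of `a` by scalar s[j]; s is a node whose value has
# length ncol(a) (any shape).
ad_scale_cols <- function(a, s) {
  sv <- as.vector(s$v)
  ad_node(sweep(a$v, 2L, sv, "*"), list(a, s),
          list(function(g) sweep(g, 2L, sv, "*"),
               function(g) matrix(colSums(g * a$v),
                                  nrow = nrow(s$v), ncol = ncol(s$v))))
}

ad_flatten <- function(a) {
  ad_node(matrix(as.vector(a$v), ncol = 1L), list(a), list(function(g) {
    matrix(as.vector(g), nrow = nrow(a$v), ncol = ncol(a$v))
  }))
}

ad_reverse_cols <- function(a) {
  idx <- rev(seq_len(ncol(a$v)))
  ad_node(a$v[, idx, drop = FALSE], list(a),
          list(function(g) g[, idx, drop = FALSE]))
}

# Sum of selected entries a[cbind(rows, cols)] -> 1x1 (positions may repeat).
ad_index_sum <- function(a, rows, cols) {
  ij <- cbind(rows, cols)
  ad_node(matrix(sum(a$v[ij])), list(a), list(function(g) {
    out <- matrix(0, nrow(a$v), ncol(a$v))
    gv <- as.vector(g)
    for (r in seq_len(nrow(ij))) {
      out[ij[r, 1L], ij[r, 2L]] <- out[ij[r, 1L], ij[r, 2L]] + gv
    }
    out
  }))
}

# ---- fused ops --------------------------------------------------------
# Fused building blocks keep tape length short; each implements the exact
# composite forward with a hand-derived backward, all verified by finite
# differences in the test suite.

# w %*% x + b (b broadcast across columns).
ad_affine <- function(w, x, b) {
  ad_node(w$v %*% x$v + as.vector(b$v), list(w, x, b),
          list(function(g) g %*% t(x$v),
               function(g) t(w$v) %*% g,
               function(g) matrix(rowSums(g), ncol = 1L)))
}

# One LSTM step.  `zxb` is the precomputed (4h x W) input projection
# including bias; `hc_prev` stacks [h; c] from the previous step.  The
# node's value stacks [h; c] for this step.
ad_lstm_cell <- function(zxb, t_idx, wh, hc_prev, hdim) {
  h_prev <- hc_prev$v[1:hdim, , drop = FALSE]
  c_prev <- hc_prev$v[(hdim + 1L):(2L * hdim), , drop = FALSE]
  z <- zxb$v[, t_idx, drop = FALSE] + wh$v %*% h_prev
  ri <- 1:hdim; rf <- ri + hdim; rg <- rf + hdim; ro <- rg + hdim
  i_g <- 1 / (1 + exp(-z[ri, , drop = FALSE]))
  f_g <- 1 / (1 + exp(-z[rf, , drop = FALSE]))
  g_g <- tanh(z[rg, , drop = FALSE])
  o_g <- 1 / (1 + exp(-z[ro, , drop = FALSE]))
  c_new <- f_g * c_prev + i_g * g_g
  tc <- tanh(c_new)
  h_new <- o_g * tc
  ad_node(rbind(h_new, c_new), list(zxb, wh, hc_prev), {
    back_z <- function(g) {
      gh <- g[1:hdim, , drop = FALSE]
      gc_in <- g[(hdim + 1L):(2L * hdim), , drop = FALSE]
      gc <- gc_in + gh * o_g * (1 - tc * tc)
      rbind(gc * g_g * i_g * (1 - i_g),
            gc * c_prev * f_g * (1 - f_g),
            gc * i_g * (1 - g_g * g_g),
            gh * tc * o_g * (1 - o_g))
    }
    list(function(g) {
      out <- matrix(0, nrow(zxb$v), ncol(zxb$v))
      out[, t_idx] <- back_z(g)
      out
    },
    function(g) back_z(g) %*% t(h_prev),
    function(g) {
      gz <- back_z(g)
      rbind(t(wh$v) %*% gz,
            (g[(hdim + 1L):(2L * hdim), , drop = FALSE] +
               g[1:hdim, , drop = FALSE] * o_g * (1 - tc * tc)) * f_g)
    })
  })
}

# Criss-cross attention over a C x W map at H = 1 (dense attention along
# the width, with residual): out = V softmax(K^T Q) + m, with
# Q = wq m, K = wk m, V = wv m.
ad_ccnet_fused <- function(m, wq, wk, wv) {
  mv <- m$v
  q <- wq$v %*% mv; k <- wk$v %*% mv; v <- wv$v %*% mv
  d <- crossprod(k, q)
  mx <- apply(d, 2L, max)
  ex <- exp(sweep(d, 2L, mx))
  a <- sweep(ex, 2L, colSums(ex), "/")
  ad_node(v %*% a + mv, list(m, wq, wk, wv), {
    shared <- function(g) {
      gv <- g %*% t(a)
      ga <- crossprod(v, g)
      gd <- a * sweep(ga, 2L, colSums(ga * a))
      gq <- k %*% gd
      gk <- q %*% t(gd)
      list(gq = gq, gk = gk, gv = gv)
    }
    list(function(g) {
      s <- shared(g)
      t(wq$v) %*% s$gq + t(wk$v) %*% s$gk + t(wv$v) %*% s$gv + g
    },
    function(g) shared(g)$gq %*% t(mv),
    function(g) shared(g)$gk %*% t(mv),
    function(g) shared(g)$gv %*% t(mv))
  })
}

# Width-preserving 1x3 convolution along columns with bias.
ad_conv3_fused <- function(x, wl, wm, wr, b) {
  xv <- x$v
  w <- ncol(xv)
  pad <- matrix(0, nrow(xv), 1L)
  xl <- cbind(pad, xv[, -w, drop = FALSE])
  xr <- cbind(xv[, -1L, drop = FALSE], pad)
  ad_node(wl$v %*% xl + wm$v %*% xv + wr$v %*% xr + as.vector(b$v),
          list(x, wl, wm, wr, b),
          list(function(g) {
            gl <- t(wl$v) %*% g; gr <- t(wr$v) %*% g
            t(wm$v) %*% g +
              cbind(gl[, -1L, drop = FALSE], pad) +
              cbind(pad, gr[, -w, drop = FALSE])
          },
          function(g) g %*% t(xl),
          function(g) g %*% t(xv),
          function(g) g %*% t(xr),
          function(g) matrix(rowSums(g), ncol = 1L)))
}

# a = sigmoid(q vec(att) + qb): per-set gate from a flattened map.
ad_set_gate <- function(q, att, qb) {
  vec <- matrix(as.vector(att$v), ncol = 1L)
  a <- 1 / (1 + exp(-(q$v %*% vec + qb$v)))
  ad_node(a, list(q, att, qb), {
    gz <- function(g) g * a * (1 - a)
    list(function(g) gz(g) %*% t(vec),
         function(g) matrix(as.vector(t(q$v) %*% gz(g)),
                            nrow = nrow(att$v), ncol = ncol(att$v)),
         function(g) gz(g))
  })
}

# CRF log-partition as a single node; backward is the forward-backward
# algorithm (emission gradients are state marginals, transition gradients
# are pairwise marginals).  `emis` is T x W; `trans` is (T+2) x (T+2)
# with START = T+1, STOP = T+2.
ad_crf_logz <- function(emis, trans, T_) {
  ev <- emis$v; tv <- trans$v
  W <- ncol(ev)
  START <- T_ + 1L; STOP <- T_ + 2L
  tt <- tv[1:T_, 1:T_, drop = FALSE]
  lse <- function(x) { m <- max(x); log(sum(exp(x - m))) + m }
  alpha <- matrix(0, T_, W)
  alpha[, 1L] <- tv[START, 1:T_] + ev[, 1L]
  if (W > 1L) {
    for (t in 2:W) {
      m <- tt + alpha[, t - 1L]
      mx <- apply(m, 2L, max)
      alpha[, t] <- log(colSums(exp(sweep(m, 2L, mx)))) + mx + ev[, t]
    }
  }
  logz <- lse(alpha[, W] + tv[1:T_, STOP])
  ad_node(matrix(logz), list(emis, trans), {
    shared <- function() {
      beta <- matrix(0, T_, W)
      beta[, W] <- tv[1:T_, STOP]
      if (W > 1L) {
        for (t in (W - 1L):1L) {
          m <- sweep(tt, 2L, ev[, t + 1L] + beta[, t + 1L], "+")
          mx <- apply(m, 1L, max)
          beta[, t] <- log(rowSums(exp(m - mx))) + mx
        }
      }
      marg <- exp(alpha + beta - logz)
      gtr <- matrix(0, T_ + 2L, T_ + 2L)
      if (W > 1L) {
        for (t in 2:W) {
          xi <- exp(outer(alpha[, t - 1L], ev[, t] + beta[, t], "+") +
                      tt - logz)
          gtr[1:T_, 1:T_] <- gtr[1:T_, 1:T_] + xi
        }
      }
      gtr[START, 1:T_] <- marg[, 1L]
      gtr[1:T_, STOP] <- marg[, W]
      list(marg = marg, gtr = gtr)
    }
    list(function(g) as.vector(g) * shared()$marg,
         function(g) as.vector(g) * shared()$gtr)
  })
}
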