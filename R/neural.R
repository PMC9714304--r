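# Criss-cross attention, attention-weighted Softlexicon, the parallel
# criss-cross attention block (PCAT), and the linear-chain CRF.

rand_mat <- function(nr, nc, scale = 0.1) {
  matrix(stats::runif(nr * nc, -scale, scale), nr, nc)
}

#' Criss-cross attention parameters
#'
#' 1x1-convolution (i.e. channel-mixing) projections: query and key maps
#' reduce `C` channels to `c_prime < C`; the value map preserves `C`.
#'
#' @param C input channel count.
#' @param c_prime reduced query/key channel count, default `max(1, C %/% 8)`.
#' @param seed seed for uniform(-0.1, 0.1) initialisation.
#' @return Object of class `ccnet_params` with matrices `wq`, `wk`
#'   (`c_prime x C`) and `wv` (`C x C`).
#' @export
ccnet_params <- function(C, c_prime = max(1L, C %/% 8L), seed = 1L) {
  if (c_prime >= C && C > 1L) stop("c_prime must be smaller than C")
  with_seed(seed, {
    structure(list(C = C, c_prime = c_prime,
                   wq = rand_mat(c_prime, C),
                   wk = rand_mat(c_prime, C),
                   wv = rand_mat(C, C)),
              class = "ccnet_params")
  })
}

#' Criss-cross attention over a feature map
#'
#' For each spatial position `u` of a `[C, W, H]` feature map, attends
#' over the `H + W - 1` positions in the same row and column as `u` (`u`
#' itself counted once): affinities `d_{i,u} = Q_u . K_i` are softmaxed
#' and used to aggregate the value projections, and the result is added
#' back to the input (residual).  With `H = 1` the criss-cross set is the
#' whole row, so the block degenerates to dense attention along the
#' sequence — which is exactly its role in sequence tagging.
#'
#' @param m numeric array `[C, W, H]`, or a `C x W` matrix (taken as
#'   `H = 1`).
#' @param params a [ccnet_params()].
#' @return Feature map of the same shape as the input.
#' @export
criss_cross_attention <- function(m, params) {
  was_mat <- is.matrix(m)
  if (was_mat) m <- array(m, c(nrow(m), ncol(m), 1L))
  if (length(dim(m)) != 3L) stop("feature map must be [C, W, H]")
  C <- dim(m)[1]; W <- dim(m)[2]; H <- dim(m)[3]
  if (C != params$C) stop("channel mismatch: map has ", C,
                          ", params expect ", params$C)
  # channel-mixing projections applied position-wise
  flat <- matrix(m, nrow = C)                      # C x (W*H), col = (w,h)
  q <- params$wq %*% flat
  k <- params$wk %*% flat
  v <- params$wv %*% flat
  out <- m
  pos <- function(w, h) (h - 1L) * W + w
  for (h in seq_len(H)) {
    for (w in seq_len(W)) {
      u <- pos(w, h)
      # criss-cross candidates: same row (all w' at h), same column
      # (all h' at w), position u only once
      row_idx <- pos(seq_len(W), h)
      col_idx <- pos(w, seq_len(H))
      idx <- c(row_idx, col_idx[col_idx != u])
      d <- as.vector(crossprod(q[, u, drop = FALSE], k[, idx, drop = FALSE]))
      a <- exp(d - max(d)); a <- a / sum(a)
      out[, w, h] <- v[, idx, drop = FALSE] %*% a + m[, w, h]
    }
  }
  if (was_mat) out <- matrix(out, nrow = C)
  out
}

#' Attention-weighted Softlexicon parameters
#'
#' A criss-cross attention block over the stacked `[d_w, 4]` set-vector
#' map plus one affine map `q` from the flattened attention output to 4
#' logits; a sigmoid turns the logits into per-set weights in (0, 1).
#'
#' @param d_w word-embedding dimension.
#' @param c_prime reduced channel count for the attention block.
#' @param seed initialisation seed.
#' @return Object of class `attsoft_params`.
#' @export
attsoft_params <- function(d_w, c_prime = max(1L, d_w %/% 8L), seed = 1L) {
  with_seed(seed, {
    structure(list(d_w = d_w,
                   ccnet = ccnet_params(d_w, c_prime, seed = seed + 1L),
                   q = rand_mat(4L, 4L * d_w),
                   q_bias = rand_mat(4L, 1L)),
              class = "attsoft_params")
  })
}

#' Learned importance weights for the four BMES word sets
#'
#' `a = sigmoid(q(flatten(CCNet(V))))` where `V` is the `[d_w, 4]` map of
#' frequency-weighted set vectors (columns B, M, E, S).  Each weight lies
#' strictly in (0, 1); the weights are not constrained to sum to 1.
#'
#' @param v_sets `d_w x 4` matrix of set vectors.
#' @param params an [attsoft_params()].
#' @return Numeric weight vector of length 4.
#' @export
attsoft_weights <- function(v_sets, params) {
  if (ncol(v_sets) != 4L) stop("expected exactly four set columns")
  att <- criss_cross_attention(v_sets, params$ccnet)
  logits <- params$q %*% matrix(as.vector(att), ncol = 1L) + params$q_bias
  as.vector(1 / (1 + exp(-logits)))
}

#' Attention-weighted Softlexicon character feature
#'
#' Concatenates the character embedding with the four set vectors, each
#' scaled by its learned importance weight:
#' `[x_c; a1 v(B); a2 v(M); a3 v(E); a4 v(S)]`.  With all weights equal
#' to 1 this reproduces [softlexicon_feature()] exactly.
#'
#' @param x_c character embedding vector.
#' @param word_sets a [match_word_sets()] result.
#' @param emb word [embedding_table()].
#' @param params an [attsoft_params()].
#' @param weights optional fixed weight vector overriding the learned
#'   weights (used for ablation).
#' @return Numeric vector of length `length(x_c) + 4 * emb$dim`.
#' @export
attsoft_feature <- function(x_c, word_sets, emb, params, weights = NULL) {
  v <- set_vector_matrix(word_sets, emb)
  a <- if (is.null(weights)) attsoft_weights(v, params) else weights
  c(x_c, as.vector(sweep(v, 2L, a, "*")))
}

#' PCAT parameters
#'
#' Two branches over a `[C, W, 1]` map: branch 1 is 1x1 conv, criss-cross
#' attention, 1x3 conv; branch 2 is 1x3 conv, criss-cross attention,
#' 1x3 conv.  All convolutions preserve channel count and width
#' (symmetric zero padding) and carry a bias; attention weights of the
#' two branches are not shared.
#'
#' @param C channel count (the BiLSTM output dimension in the full model).
#' @param c_prime reduced channel count inside the attention blocks.
#' @param seed initialisation seed.
#' @return Object of class `pcat_params`.
#' @export
pcat_params <- function(C, c_prime = max(1L, C %/% 8L), seed = 1L) {
  conv1 <- function() list(w = rand_mat(C, C), b = rand_mat(C, 1L))
  conv3 <- function() list(w_left = rand_mat(C, C), w_mid = rand_mat(C, C),
                           w_right = rand_mat(C, C), b = rand_mat(C, 1L))
  with_seed(seed, {
    structure(list(C = C,
                   b1_in = conv1(),
                   b1_cc = ccnet_params(C, c_prime, seed = seed + 1L),
                   b1_out = conv3(),
                   b2_in = conv3(),
                   b2_cc = ccnet_params(C, c_prime, seed = seed + 2L),
                   b2_out = conv3()),
              class = "pcat_params")
  })
}

conv1_apply <- function(x, p) p$w %*% x + as.vector(p$b)

conv3_apply <- function(x, p) {
  w <- ncol(x)
  pad <- matrix(0, nrow(x), 1L)
  xl <- cbind(pad, x[, -w, drop = FALSE])    # left neighbour
  xr <- cbind(x[, -1L, drop = FALSE], pad)   # right neighbour
  p$w_left %*% xl + p$w_mid %*% x + p$w_right %*% xr + as.vector(p$b)
}

#' Parallel criss-cross attention block
#'
#' Applies the two conv / criss-cross attention / conv branches to a
#' `C x W` sequence feature map and sums them.  Width is preserved.
#'
#' @param x `C x W` numeric matrix (sentence features, one column per
#'   character).
#' @param params a [pcat_params()].
#' @return `C x W` numeric matrix.
#' @export
pcat_forward <- function(x, params) {
  if (!is.matrix(x) || ncol(x) < 1L) stop("x must be a C x W matrix, W >= 1")
  if (nrow(x) != params$C) stop("channel mismatch")
  b1 <- conv3_apply(criss_cross_attention(conv1_apply(x, params$b1_in),
                                          params$b1_cc), params$b1_out)
  b2 <- conv3_apply(criss_cross_attention(conv3_apply(x, params$b2_in),
                                          params$b2_cc), params$b2_out)
  b1 + b2
}

# ---- linear-chain CRF -------------------------------------------------

#' Linear-chain CRF parameters
#'
#' Transition scores over the tagset augmented with START and STOP
#' states.  The transition matrix is `(T+2) x (T+2)`; rows index the
#' source tag, columns the target.
#'
#' @param tagset character vector of tag names.
#' @param seed initialisation seed (uniform(-0.1, 0.1) scores).
#' @return Object of class `crf_params` with elements `tagset`, `trans`,
#'   `start` and `stop` (the augmented state indices).
#' @export
crf_params <- function(tagset, seed = 1L) {
  T_ <- length(tagset)
  with_seed(seed, {
    trans <- rand_mat(T_ + 2L, T_ + 2L)
    dimnames(trans) <- list(c(tagset, "<START>", "<STOP>"),
                            c(tagset, "<START>", "<STOP>"))
    structure(list(tagset = tagset, trans = trans,
                   start = T_ + 1L, stop = T_ + 2L),
              class = "crf_params")
  })
}

#' CRF log-partition function
#'
#' `log sum over all tag paths of exp(score)` for a `W x T` emission
#' matrix, where a path score is the sum of its emission scores plus
#' transition scores including START -> first tag and last tag -> STOP.
#' Computed by the forward recursion in log space.
#'
#' @param emissions `W x T` numeric matrix of per-position tag scores.
#' @param params a [crf_params()].
#' @return Scalar log-partition value.
#' @export
crf_log_partition <- function(emissions, params) {
  W <- nrow(emissions); T_ <- length(params$tagset)
  if (ncol(emissions) != T_) stop("emission width must equal tagset size")
  trans <- params$trans
  alpha <- trans[params$start, 1:T_] + emissions[1L, ]
  if (W > 1L) {
    for (t in 2:W) {
      m <- trans[1:T_, 1:T_] + alpha              # recycles down columns
      mx <- apply(m, 2L, max)
      alpha <- log(colSums(exp(sweep(m, 2L, mx)))) + mx + emissions[t, ]
    }
  }
  fin <- alpha + trans[1:T_, params$stop]
  mx <- max(fin)
  log(sum(exp(fin - mx))) + mx
}

#' Score of one tag path under a CRF
#'
#' @param emissions `W x T` emission matrix.
#' @param path integer vector of tag indices, length `W`.
#' @param params a [crf_params()].
#' @return Scalar path score.
#' @export
crf_path_score <- function(emissions, path, params) {
  W <- nrow(emissions)
  trans <- params$trans
  sum(emissions[cbind(seq_len(W), path)]) +
    sum(trans[cbind(c(params$start, path), c(path, params$stop))])
}

#' Viterbi decoding for a linear-chain CRF
#'
#' Returns the highest-scoring tag path.  Ties break deterministically
#' toward the lowest tag index.  An optional mask of forbidden
#' transitions (same shape as `params$trans`, `TRUE` = forbidden) is
#' applied as a large negative penalty, which is how the tagger enforces
#' BMES well-formedness at decode time.
#'
#' @param emissions `W x T` emission matrix.
#' @param params a [crf_params()].
#' @param forbidden optional logical matrix of forbidden transitions.
#' @return List with `path` (integer tag indices) and `score`.
#' @export
crf_viterbi <- function(emissions, params, forbidden = NULL) {
  W <- nrow(emissions); T_ <- length(params$tagset)
  trans <- params$trans
  if (!is.null(forbidden)) trans <- trans - 1e9 * forbidden
  delta <- trans[params$start, 1:T_] + emissions[1L, ]
  back <- matrix(0L, W, T_)
  if (W > 1L) {
    for (t in 2:W) {
      m <- trans[1:T_, 1:T_] + delta
      back[t, ] <- apply(m, 2L, which.max)
      delta <- m[cbind(back[t, ], 1:T_)] + emissions[t, ]
    }
  }
  fin <- delta + trans[1:T_, params$stop]
  path <- integer(W)
  path[W] <- which.max(fin)
  if (W > 1L) for (t in W:2) path[t - 1L] <- back[t, path[t]]
  list(path = path, score = max(fin))
}

# Forbidden-transition mask for a BMES-O tagset: inside an entity only
# M/E of the same category may follow B/M; entities must be closed before
# O, B, S or STOP; M/E may not begin an entity.
bmes_forbidden_mask <- function(tagset) {
  T_ <- length(tagset)
  states <- c(tagset, "<START>", "<STOP>")
  n <- T_ + 2L
  forb <- matrix(FALSE, n, n, dimnames = list(states, states))
  pos <- function(s) ifelse(s %in% c("O", "<START>", "<STOP>"), s,
                            substr(s, 1L, 1L))
  cat_of <- function(s) ifelse(s %in% c("O", "<START>", "<STOP>"), "",
                               substring(s, 3L))
  for (a in states) {
    for (b in states) {
      pa <- pos(a); pb <- pos(b)
      bad <- FALSE
      if (pa %in% c("B", "M")) {
        # entity open: must continue with M/E of the same category
        bad <- !(pb %in% c("M", "E") && cat_of(b) == cat_of(a))
      } else {
        # no entity open: M and E may not start
        if (pb %in% c("M", "E")) bad <- TRUE
      }
      if (a == "<STOP>" || b == "<START>") bad <- TRUE
      if (a == "<START>" && b == "<STOP>") bad <- TRUE
      forb[a, b] <- bad
    }
  }
  forb
}
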