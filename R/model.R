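# The full tagger: attention-weighted Softlexicon character features,
# BiLSTM encoder, parallel criss-cross attention block, linear-chain CRF.
# Trained by SGD through the package's reverse-mode autodiff engine.

#' Model configuration
#'
#' Defaults follow the reference configuration for this architecture:
#' character and word embeddings of dimension 50, LSTM hidden size 300
#' per direction, dropout 0.5.
#'
#' @param d_char character embedding dimension.
#' @param d_word word embedding dimension.
#' @param lstm_hidden hidden units per LSTM direction.
#' @param dropout dropout rate applied to the fused character features
#'   during training.
#' @param c_prime_frac reduced attention channel count as a fraction
#'   denominator: `c_prime = max(1, C %/% c_prime_frac)`.
#' @return A list of class `model_config`.
#' @export
model_config <- function(d_char = 50L, d_word = 50L, lstm_hidden = 300L,
                         dropout = 0.5, c_prime_frac = 8L) {
  stopifnot(d_char > 0, d_word > 0, lstm_hidden > 0,
            dropout >= 0, dropout < 1)
  structure(list(d_char = as.integer(d_char), d_word = as.integer(d_word),
                 lstm_hidden = as.integer(lstm_hidden), dropout = dropout,
                 c_prime_frac = as.integer(c_prime_frac)),
            class = "model_config")
}

#' Training configuration
#'
#' Defaults follow the reference training regime: batch size 16, SGD with
#' initial learning rate 0.0015 and decay 0.05 (epoch `e` runs at
#' `lr / (1 + decay * (e - 1))`).  Gradients are clipped to a global L2
#' norm of 5 for stability.
#'
#' @param batch_size sentences per SGD step.
#' @param lr initial learning rate.
#' @param lr_decay learning-rate decay coefficient.
#' @param epochs maximum number of epochs.
#' @param seed RNG seed controlling initialisation, shuffling and dropout.
#' @param grad_clip global gradient-norm clip.
#' @param stop_f1 optional early-stopping target: training stops once the
#'   monitored entity F1 (dev set if supplied, else training set) reaches
#'   this value (percent scale).
#' @return A list of class `train_config`.
#' @export
train_config <- function(batch_size = 16L, lr = 0.0015, lr_decay = 0.05,
                         epochs = 30L, seed = 1L, grad_clip = 5.0,
                         stop_f1 = NULL) {
  stopifnot(batch_size >= 1, lr > 0, lr_decay >= 0, epochs >= 1)
  structure(list(batch_size = as.integer(batch_size), lr = lr,
                 lr_decay = lr_decay, epochs = as.integer(epochs),
                 seed = as.integer(seed), grad_clip = grad_clip,
                 stop_f1 = stop_f1),
            class = "train_config")
}

full_tagset <- function(categories) {
  c("O", as.vector(t(outer(c("B", "M", "E", "S"), sort(categories),
                           paste, sep = "-"))))
}

# Precompute the static (lexicon-derived) part of a sentence's features:
# character indices plus, per character, the four word sets as word-vocab
# indices and their normalised frequency weights 4 z(w) / Z.
encode_sentence <- function(chars, lex, char_vocab, word_vocab) {
  W <- length(chars)
  unk_c <- match("<UNK>", char_vocab)
  char_idx <- match(chars, char_vocab)
  char_idx[is.na(char_idx)] <- unk_c
  sets <- vector("list", W)
  unk_w <- match("<UNK>", word_vocab)
  for (i in seq_len(W)) {
    ws <- match_word_sets(chars, lex, i)
    z <- word_sets_total(ws)
    # fuse the four sets into one lookup: idx concatenates the sets'
    # word indices; wblk (4 x K) holds 4 z(w)/Z in the row of each set
    idx <- integer(); rows <- integer(); wts <- numeric()
    for (r in 1:4) {
      df <- ws[[c("b", "m", "e", "s")[r]]]
      ii <- match(df$word, word_vocab)
      ii[is.na(ii)] <- unk_w
      idx <- c(idx, ii)
      rows <- c(rows, rep(r, length(ii)))
      wts <- c(wts, 4 * df$z / z)
    }
    wblk <- matrix(0, 4L, length(idx))
    wblk[cbind(rows, seq_along(idx))] <- wts
    sets[[i]] <- list(idx = idx, wblk = wblk)
  }
  list(chars = chars, char_idx = char_idx, sets = sets, n = W)
}

ad_lstm_dir <- function(x, wx, wh, b, hdim) {
  W <- ncol(ad_value(x))
  zxb <- ad_affine(wx, x, b)
  hc <- ad_leaf(matrix(0, 2L * hdim, 1L))
  hs <- vector("list", W)
  for (t in seq_len(W)) {
    hc <- ad_lstm_cell(zxb, t, wh, hc, hdim)
    hs[[t]] <- ad_rows(hc, 1:hdim)
  }
  ad_concat_cols(hs)
}

# Fused character-feature map (D x W) with attention-weighted set vectors.
ad_sentence_features <- function(enc, P, cfg, drop_mask = NULL) {
  d_c <- cfg$d_char
  xc_all <- ad_transpose(ad_lookup(P$e_char, enc$char_idx))
  cols <- vector("list", enc$n)
  for (i in seq_len(enc$n)) {
    st <- enc$sets[[i]]
    vmat <- ad_transpose(ad_matmul(ad_leaf(st$wblk),
                                   ad_lookup(P$e_word, st$idx)))
    att <- ad_ccnet_fused(vmat, P$att_wq, P$att_wk, P$att_wv)
    a <- ad_set_gate(P$att_q, att, P$att_qb)
    weighted <- ad_scale_cols(vmat, a)
    cols[[i]] <- ad_concat_rows(list(ad_col(xc_all, i), ad_flatten(weighted)))
  }
  x <- ad_concat_cols(cols)
  if (!is.null(drop_mask)) x <- ad_hadamard(x, ad_leaf(drop_mask))
  x
}

# Emission scores (T x W) for one sentence.
ad_emissions <- function(enc, P, cfg, drop_mask = NULL) {
  x <- ad_sentence_features(enc, P, cfg, drop_mask)
  h <- cfg$lstm_hidden
  hf <- ad_lstm_dir(x, P$lstm_f_wx, P$lstm_f_wh, P$lstm_f_b, h)
  hb <- ad_reverse_cols(ad_lstm_dir(ad_reverse_cols(x), P$lstm_b_wx,
                                    P$lstm_b_wh, P$lstm_b_b, h))
  out <- ad_concat_rows(list(hf, hb))
  b1 <- ad_conv3_fused(ad_ccnet_fused(ad_affine(P$p1i_w, out, P$p1i_b),
                                      P$p1c_wq, P$p1c_wk, P$p1c_wv),
                       P$p1o_wl, P$p1o_wm, P$p1o_wr, P$p1o_b)
  b2 <- ad_conv3_fused(ad_ccnet_fused(ad_conv3_fused(out, P$p2i_wl, P$p2i_wm,
                                                     P$p2i_wr, P$p2i_b),
                                      P$p2c_wq, P$p2c_wk, P$p2c_wv),
                       P$p2o_wl, P$p2o_wm, P$p2o_wr, P$p2o_b)
  ad_affine(P$emis_w, ad_add(b1, b2), P$emis_b)
}

# CRF negative log-likelihood node from a (T x W) emission node.
ad_crf_nll <- function(emis, trans, path, T_) {
  W <- ncol(ad_value(emis))
  START <- T_ + 1L; STOP <- T_ + 2L
  logz <- ad_crf_logz(emis, trans, T_)
  gold <- ad_add(ad_index_sum(emis, path, seq_len(W)),
                 ad_index_sum(trans, c(START, path), c(path, STOP)))
  ad_sub(logz, gold)
}

init_params <- function(cfg, n_char, n_word, T_, char_init = NULL,
                        word_init = NULL) {
  d_c <- cfg$d_char; d_w <- cfg$d_word; h <- cfg$lstm_hidden
  D <- d_c + 4L * d_w; C2 <- 2L * h
  cp_att <- max(1L, d_w %/% cfg$c_prime_frac)
  cp_enc <- max(1L, C2 %/% cfg$c_prime_frac)
  r <- function(nr, nc) rand_mat(nr, nc)
  P <- list(
    e_char = if (is.null(char_init)) r(n_char, d_c) else char_init,
    e_word = if (is.null(word_init)) r(n_word, d_w) else word_init,
    att_wq = r(cp_att, d_w), att_wk = r(cp_att, d_w), att_wv = r(d_w, d_w),
    att_q = r(4L, 4L * d_w), att_qb = r(4L, 1L),
    lstm_f_wx = r(4L * h, D), lstm_f_wh = r(4L * h, h), lstm_f_b = r(4L * h, 1L),
    lstm_b_wx = r(4L * h, D), lstm_b_wh = r(4L * h, h), lstm_b_b = r(4L * h, 1L),
    p1i_w = r(C2, C2), p1i_b = r(C2, 1L),
    p1c_wq = r(cp_enc, C2), p1c_wk = r(cp_enc, C2), p1c_wv = r(C2, C2),
    p1o_wl = r(C2, C2), p1o_wm = r(C2, C2), p1o_wr = r(C2, C2),
    p1o_b = r(C2, 1L),
    p2i_wl = r(C2, C2), p2i_wm = r(C2, C2), p2i_wr = r(C2, C2),
    p2i_b = r(C2, 1L),
    p2c_wq = r(cp_enc, C2), p2c_wk = r(cp_enc, C2), p2c_wv = r(C2, C2),
    p2o_wl = r(C2, C2), p2o_wm = r(C2, C2), p2o_wr = r(C2, C2),
    p2o_b = r(C2, 1L),
    emis_w = r(T_, C2), emis_b = r(T_, 1L),
    trans = r(T_ + 2L, T_ + 2L)
  )
  # forget-gate bias starts at 1 so early training retains memory
  P$lstm_f_b[(h + 1L):(2L * h), 1L] <- 1
  P$lstm_b_b[(h + 1L):(2L * h), 1L] <- 1
  lapply(P, ad_leaf)
}

embedding_init <- function(emb, tokens, dim) {
  if (is.null(emb)) return(NULL)
  if (emb$dim != dim) {
    stop("pretrained embedding dimension ", emb$dim,
         " does not match configured dimension ", dim)
  }
  embedding_lookup(emb, tokens)
}

#' Fit the lexicon-enhanced neural tagger
#'
#' Trains a character-level BMES-O sequence tagger: characters are
#' embedded and fused with attention-weighted Softlexicon word-set
#' vectors, encoded by a BiLSTM, refined by a parallel criss-cross
#' attention block, and scored by a linear-chain CRF.  Training minimises
#' the CRF negative log-likelihood by mini-batch SGD with a decaying
#' learning rate; all randomness (initialisation, shuffling, dropout) is
#' governed by `train$seed`, so runs are exactly reproducible.
#'
#' @param corpus list of [tagged_sentence()] objects (training data).
#' @param lex a [lexicon()] used for BMES word-set matching.
#' @param model a [model_config()].
#' @param train a [train_config()].
#' @param char_embeddings optional pretrained character
#'   [embedding_table()]; characters absent from it fall back to `<UNK>`.
#' @param word_embeddings optional pretrained word [embedding_table()].
#' @param dev optional list of [tagged_sentence()]: a development set
#'   whose entity F1 is recorded each epoch.
#' @param verbose print a line per epoch.
#' @return An object of class `lexner`: a list with the trained parameter
#'   matrices (`params`), vocabularies, tagset, configs and a per-epoch
#'   `history` data.frame (columns `epoch`, `lr`, `loss`, `dev_f1`).
#' @seealso [predict.lexner()], [entity_prf()]
#' @export
lexner <- function(corpus, lex, model = model_config(),
                   train = train_config(), char_embeddings = NULL,
                   word_embeddings = NULL, dev = NULL, verbose = FALSE) {
  if (!length(corpus)) stop("training corpus is empty")
  cats <- sort(unique(unlist(lapply(corpus, function(s) {
    sub("^[BMES]-", "", s$tags[s$tags != "O"])
  }))))
  tagset <- full_tagset(cats)
  T_ <- length(tagset)
  char_vocab <- c(sort(unique(unlist(lapply(corpus, `[[`, "chars")))),
                  RESERVED_TOKENS)
  word_vocab <- c(lex$words, RESERVED_TOKENS)

  encs <- lapply(corpus, function(s) encode_sentence(s$chars, lex,
                                                     char_vocab, word_vocab))
  paths <- lapply(corpus, function(s) match(s$tags, tagset))
  if (anyNA(unlist(paths))) stop("corpus contains tags outside the tagset")

  set.seed(train$seed)
  P <- init_params(model, length(char_vocab), length(word_vocab), T_,
                   embedding_init(char_embeddings, char_vocab, model$d_char),
                   embedding_init(word_embeddings, word_vocab, model$d_word))
  plist <- P   # named list of ad leaves

  obj <- structure(list(params = NULL, tagset = tagset, categories = cats,
                        char_vocab = char_vocab, word_vocab = word_vocab,
                        model = model, train = train, lexicon = lex,
                        history = NULL),
                   class = "lexner")

  D <- model$d_char + 4L * model$d_word
  n <- length(encs)
  history <- data.frame(epoch = integer(), lr = numeric(), loss = numeric(),
                        dev_f1 = numeric())
  monitor <- if (!is.null(dev)) dev else corpus

  for (epoch in seq_len(train$epochs)) {
    lr_e <- train$lr / (1 + train$lr_decay * (epoch - 1L))
    ord <- sample.int(n)
    total_loss <- 0
    for (b0 in seq(1L, n, by = train$batch_size)) {
      batch <- ord[b0:min(b0 + train$batch_size - 1L, n)]
      ad_zero_grads(plist)
      for (si in batch) {
        enc <- encs[[si]]
        mask <- NULL
        if (model$dropout > 0) {
          keep <- matrix(stats::rbinom(D * enc$n, 1L, 1 - model$dropout),
                         D, enc$n)
          mask <- keep / (1 - model$dropout)
        }
        run <- ad_with_tape({
          emis <- ad_emissions(enc, plist, model, mask)
          ad_scale(ad_crf_nll(emis, plist$trans, paths[[si]], T_),
                   1 / length(batch))
        })
        ad_backward(run$result, run$tape)
        total_loss <- total_loss + ad_value(run$result)[1] * length(batch)
      }
      gnorm <- sqrt(sum(vapply(plist, function(p) {
        if (is.null(p$grad)) 0 else sum(p$grad^2)
      }, numeric(1))))
      scale <- if (gnorm > train$grad_clip) train$grad_clip / gnorm else 1
      for (p in plist) {
        if (!is.null(p$grad)) p$v <- p$v - lr_e * scale * p$grad
      }
    }
    mean_loss <- total_loss / n
    obj$params <- lapply(plist, ad_value)
    dev_f1 <- {
      pred <- predict_internal(obj, monitor, encs_cache =
                                 if (is.null(dev)) encs else NULL)
      entity_prf(monitor, pred)$f1
    }
    history <- rbind(history, data.frame(epoch = epoch, lr = lr_e,
                                         loss = mean_loss, dev_f1 = dev_f1))
    if (verbose) {
      message(sprintf("epoch %3d  lr %.5f  loss %9.4f  F1 %6.2f",
                      epoch, lr_e, mean_loss, dev_f1))
    }
    if (!is.null(train$stop_f1) && dev_f1 >= train$stop_f1) break
  }
  obj$params <- lapply(plist, ad_value)
  obj$history <- history
  obj
}

predict_internal <- function(object, sentences, encs_cache = NULL) {
  if (!length(sentences)) return(list())
  P <- lapply(object$params, ad_leaf)
  T_ <- length(object$tagset)
  crf <- structure(list(tagset = object$tagset,
                        trans = object$params$trans,
                        start = T_ + 1L, stop = T_ + 2L),
                   class = "crf_params")
  forb <- bmes_forbidden_mask(object$tagset)
  out <- vector("list", length(sentences))
  for (k in seq_along(sentences)) {
    s <- sentences[[k]]
    chars <- if (inherits(s, "tagged_sentence")) s$chars else {
      if (length(s) == 1L && nchar(s) > 1L) split_chars(s) else enc2utf8(s)
    }
    enc <- if (!is.null(encs_cache)) encs_cache[[k]] else {
      encode_sentence(chars, object$lexicon, object$char_vocab,
                      object$word_vocab)
    }
    emis <- ad_value(ad_emissions(enc, P, object$model))   # T x W
    vit <- crf_viterbi(t(emis), crf, forbidden = forb)
    out[[k]] <- tagged_sentence(chars, object$tagset[vit$path])
  }
  out
}

#' Predict tags for new sentences
#'
#' Runs the trained tagger and decodes with Viterbi under a
#' forbidden-transition mask, so every output tag sequence is well-formed
#' BMES-O.
#'
#' @param object a fitted [lexner()] model.
#' @param sentences list of strings, character vectors or
#'   [tagged_sentence()] objects.
#' @param ... unused.
#' @return List of [tagged_sentence()] with predicted tags.
#' @export
predict.lexner <- function(object, sentences, ...) {
  predict_internal(object, sentences)
}

#' @export
print.lexner <- function(x, ...) {
  cat("Lexicon-enhanced BiLSTM-CRF tagger\n")
  cat("  tagset:      ", length(x$tagset), "tags (",
      length(x$categories), "entity categories )\n")
  cat("  vocab:       ", length(x$char_vocab), "characters,",
      length(x$word_vocab), "lexicon words\n")
  cat("  dims:         d_char", x$model$d_char, "| d_word", x$model$d_word,
      "| LSTM hidden", x$model$lstm_hidden, "\n")
  if (!is.null(x$history) && nrow(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  trained:      %d epochs, final loss %.4f, entity F1 %.2f\n",
                last$epoch, last$loss, last$dev_f1))
  }
  invisible(x)
}

#' @export
summary.lexner <- function(object, ...) {
  print(object)
  npar <- sum(vapply(object$params, length, 0L))
  cat("  parameters:  ", format(npar, big.mark = ","), "\n")
  if (!is.null(object$history)) {
    cat("\nTraining history:\n")
    print(object$history, row.names = FALSE, digits = 4)
  }
  invisible(object)
}

#' @export
coef.lexner <- function(object, ...) object$params

#' @export
plot.lexner <- function(x, ...) {
  h <- x$history
  if (is.null(h) || !nrow(h)) stop("no training history to plot")
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  plot(h$epoch, h$loss, type = "b", xlab = "epoch", ylab = "mean CRF NLL",
       main = "Training loss", ...)
  plot(h$epoch, h$dev_f1, type = "b", xlab = "epoch", ylab = "entity F1 (%)",
       main = "Monitored entity F1", ...)
  invisible(x)
}

#' @export
logLik.lexner <- function(object, ...) {
  h <- object$history
  if (is.null(h) || !nrow(h)) return(NA_real_)
  val <- -h$loss[nrow(h)]
  structure(val, class = "logLik", df = sum(vapply(object$params, length, 0L)))
}
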