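# Shared fixtures and independent oracle implementations.  Oracles are
# deliberately naive (enumeration, dense linear algebra) and never share
# code with the package internals they check.

# The worked-example sentence and lexicon: "plant disease" with the words
# plant / disease / plant-disease / disease(single char).
example_sentence <- function() "\u690d\u7269\u75c5\u5bb3"
example_lexicon <- function(freqs = c(2, 3, 1, 4)) {
  lexicon(c("\u690d\u7269", "\u75c5\u5bb3",
            "\u690d\u7269\u75c5\u5bb3", "\u75c5"), freqs)
}

# Pseudo-character alphabet for generated fixtures (private-use area).
pua <- function(i) vapply(0xE000 + i - 1L, intToUtf8, "")

random_tagged_corpus <- function(n_sent, cats = c("DIS", "PEST"),
                                 max_len = 8L) {
  lapply(seq_len(n_sent), function(i) {
    n <- sample(1:max_len, 1L)
    chars <- pua(sample(1:40, n, replace = TRUE))
    spans <- random_spans(n, cats)
    tagged_sentence(chars, spans_to_tags(spans, n))
  })
}

# Random non-overlapping span set on [0, n).
random_spans <- function(n, cats = c("A", "B")) {
  starts <- integer(); ends <- integer(); cc <- character()
  i <- 0L
  while (i < n) {
    if (stats::runif(1) < 0.4) {
      len <- sample(1:min(3L, n - i), 1L)
      starts <- c(starts, i); ends <- c(ends, i + len)
      cc <- c(cc, sample(cats, 1L))
      i <- i + len
    } else {
      i <- i + 1L
    }
  }
  data.frame(start = starts, end = ends, category = cc,
             stringsAsFactors = FALSE)
}

# Brute-force reference decoder for BMES-O tag sequences: leftmost-greedy
# matching of S-X and B-X (M-X)* E-X runs via an encoded-string regex.
oracle_tags_to_spans <- function(tags) {
  starts <- integer(); ends <- integer(); cats <- character()
  i <- 1L
  n <- length(tags)
  while (i <= n) {
    m <- regmatches(tags[[i]], regexec("^S-(.+)$", tags[[i]]))[[1]]
    if (length(m)) {
      starts <- c(starts, i - 1L); ends <- c(ends, i); cats <- c(cats, m[2])
      i <- i + 1L
      next
    }
    m <- regmatches(tags[[i]], regexec("^B-(.+)$", tags[[i]]))[[1]]
    if (length(m)) {
      cc <- m[2]
      j <- i + 1L
      while (j <= n && tags[[j]] == paste0("M-", cc)) j <- j + 1L
      if (j <= n && tags[[j]] == paste0("E-", cc)) {
        starts <- c(starts, i - 1L); ends <- c(ends, j); cats <- c(cats, cc)
        i <- j + 1L
        next
      }
    }
    i <- i + 1L
  }
  data.frame(start = starts, end = ends, category = cats,
             stringsAsFactors = FALSE)
}

# Dense softmax attention along the sequence: the H = 1 reference for
# criss-cross attention.
oracle_dense_attention <- function(m, params) {
  q <- params$wq %*% m
  k <- params$wk %*% m
  v <- params$wv %*% m
  d <- t(k) %*% q
  a <- apply(d, 2L, function(col) {
    e <- exp(col - max(col)); e / sum(e)
  })
  v %*% a + m
}

# Exhaustive CRF quantities for small W, T.
oracle_crf_enumerate <- function(emissions, params) {
  W <- nrow(emissions); T_ <- length(params$tagset)
  grid <- as.matrix(expand.grid(rep(list(seq_len(T_)), W)))
  scores <- apply(grid, 1L, function(pp) crf_path_score(emissions, pp, params))
  mx <- max(scores)
  list(log_partition = mx + log(sum(exp(scores - mx))),
       best_score = mx,
       best_path = grid[which.max(scores), ])
}

# The memorization fixture: a small world the tagger can memorise on CPU.
memorization_fixture <- function(seed = 11L) {
  spec <- synth_spec(n_common_words = 40L, n_domain_words = 24L,
                     n_sentences = 200L, mean_words = 4,
                     alphabet_size = 120L, seed = seed)
  world <- generate_world(spec)
  corpora <- generate_corpora(world, spec)
  list(spec = spec, world = world, corpora = corpora)
}

memorization_model_config <- function() {
  model_config(d_char = 16L, d_word = 16L, lstm_hidden = 32L, dropout = 0)
}

memorization_train_config <- function(seed = 5L, epochs = 30L,
                                      stop_f1 = 95) {
  train_config(batch_size = 8L, lr = 0.3, lr_decay = 0.05, epochs = epochs,
               seed = seed, grad_clip = 5, stop_f1 = stop_f1)
}
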