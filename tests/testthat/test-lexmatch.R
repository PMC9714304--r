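test_that("worked example: sets for the interior character", {
  ws <- match_word_sets(example_sentence(), example_lexicon(), 2)
  expect_identical(ws$b$word, "<NONE>")
  expect_identical(ws$m$word, "\u690d\u7269\u75c5\u5bb3")
  expect_identical(ws$e$word, "\u690d\u7269")
  expect_identical(ws$s$word, "<NONE>")
  # exactly two lexicon words contain this character
  matched <- setdiff(c(ws$b$word, ws$m$word, ws$e$word, ws$s$word), "<NONE>")
  expect_length(matched, 2L)
})

test_that("set membership follows the positional definitions", {
  lex <- example_lexicon()
  # last character: ends two words, no begins/singles
  ws <- match_word_sets(example_sentence(), lex, 4)
  expect_identical(ws$b$word, "<NONE>")
  expect_identical(ws$m$word, "<NONE>")
  expect_setequal(ws$e$word, c("\u75c5\u5bb3",
                               "\u690d\u7269\u75c5\u5bb3"))
  expect_identical(ws$s$word, "<NONE>")
  # a character in no lexicon word: all four sets are the placeholder
  ws0 <- match_word_sets("xyz", lex, 2)
  for (nm in c("b", "m", "e", "s")) {
    expect_identical(ws0[[nm]]$word, "<NONE>")
    expect_identical(ws0[[nm]]$z, 1)
  }
  expect_error(match_word_sets("ab", lex, 3), "out of range")
})

test_that("trie matching equals brute-force substring scan", {
  set.seed(13)
  for (rep in 1:25) {
    n_words <- sample(3:12, 1)
    words <- unique(replicate(n_words, paste(pua(sample(1:8, sample(1:4, 1),
                                                        replace = TRUE)),
                                             collapse = "")))
    lex <- lexicon(words, sample(1:9, length(words), replace = TRUE))
    sent <- paste(pua(sample(1:8, sample(3:10, 1), replace = TRUE)),
                  collapse = "")
    for (i in seq_len(nchar(sent))) {
      expect_identical(match_word_sets(sent, lex, i),
                       lexner:::match_word_sets_bruteforce(sent, lex, i))
    }
  }
})

test_that("a word of length l appears in exactly l sets across the sentence", {
  set.seed(17)
  for (rep in 1:15) {
    words <- unique(replicate(8, paste(pua(sample(1:6, sample(2:4, 1),
                                                  replace = TRUE)),
                                       collapse = "")))
    lex <- lexicon(words, rep(1, length(words)))
    sent <- paste(pua(sample(1:6, 9, replace = TRUE)), collapse = "")
    chars <- strsplit(sent, "")[[1]]
    all_sets <- lapply(seq_along(chars), function(i)
      match_word_sets(sent, lex, i))
    for (w in words) {
      # occurrences of w in the sentence (overlapping)
      occ <- 0L
      L <- nchar(w)
      for (j in seq_len(nchar(sent) - L + 1L)) {
        if (substr(sent, j, j + L - 1L) == w) occ <- occ + 1L
      }
      if (L < 2L) next
      n_b <- sum(vapply(all_sets, function(ws) w %in% ws$b$word, TRUE))
      n_m <- sum(vapply(all_sets, function(ws) w %in% ws$m$word, TRUE))
      n_e <- sum(vapply(all_sets, function(ws) w %in% ws$e$word, TRUE))
      if (occ == 0L) {
        expect_identical(n_b + n_m + n_e, 0L)
      } else {
        # sets are deduplicated, so multiple occurrences still yield
        # membership at each covered position
        expect_gte(n_b, 1L); expect_gte(n_e, 1L)
        if (occ == 1L) {
          expect_identical(n_b, 1L)
          expect_identical(n_e, 1L)
          expect_identical(n_m, L - 2L)
        }
      }
    }
  }
})

test_that("weighted set vectors follow the frequency formula", {
  d <- 3L
  emb <- embedding_table(matrix(c(1, 0, 0), 1, d,
                                dimnames = list("w1", NULL)), seed = 2)
  emb$mat["<NONE>", ] <- 0
  # b = {(w1, 3)}, other sets {NONE}: Z = 6, v_b = 4*3/6 * e(w1) = 2 e(w1)
  b <- data.frame(word = "w1", z = 3, stringsAsFactors = FALSE)
  none <- data.frame(word = "<NONE>", z = 1, stringsAsFactors = FALSE)
  z_total <- 3 + 1 + 1 + 1
  expect_equal(weighted_set_vector(b, z_total, emb), c(2, 0, 0))
  expect_equal(weighted_set_vector(none, z_total, emb), c(0, 0, 0))
})

test_that("total set-weight mass is exactly 4 and scale-invariant", {
  set.seed(19)
  for (rep in 1:20) {
    lex <- example_lexicon(sample(1:50, 4, replace = TRUE))
    i <- sample(1:4, 1)
    ws <- match_word_sets(example_sentence(), lex, i)
    z <- word_sets_total(ws)
    mass <- sum(vapply(ws[c("b", "m", "e", "s")],
                       function(df) sum(4 * df$z / z), numeric(1)))
    expect_equal(mass, 4)
  }
  # multiplying every z(w) (and hence Z) by a constant leaves v unchanged
  set.seed(23)
  mat <- matrix(rnorm(3 * 6), 3, 6, dimnames = list(c("w1", "w2", "w3"), NULL))
  emb <- embedding_table(mat, seed = 3)
  set_df <- data.frame(word = c("w1", "w3"), z = c(2, 5),
                       stringsAsFactors = FALSE)
  z_total <- 11
  v1 <- weighted_set_vector(set_df, z_total, emb)
  set_df$z <- set_df$z * 7
  v2 <- weighted_set_vector(set_df, z_total * 7, emb)
  expect_equal(v1, v2)
})

test_that("softlexicon feature is the concatenation with correct dims", {
  set.seed(29)
  lex <- example_lexicon()
  words <- c(lex$words, "<NONE>", "<UNK>", "<PAD>")
  emb <- embedding_table(matrix(rnorm(length(words) * 50), length(words), 50,
                                dimnames = list(words, NULL)))
  x_c <- rnorm(50)
  ws <- match_word_sets(example_sentence(), lex, 2)
  fused <- softlexicon_feature(x_c, ws, emb)
  expect_length(fused, 50 + 4 * 50)
  # brute-force reference concatenation
  z <- word_sets_total(ws)
  ref <- c(x_c, unlist(lapply(ws[c("b", "m", "e", "s")], function(df) {
    v <- rep(0, 50)
    for (r in seq_len(nrow(df))) {
      v <- v + 4 * df$z[r] / z * emb$mat[df$word[r], ]
    }
    v
  }), use.names = FALSE))
  expect_equal(fused, ref)
})
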