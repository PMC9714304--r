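test_that("criss-cross attention at H = 1 equals dense attention", {
  set.seed(3)
  for (rep in 1:10) {
    C <- sample(3:8, 1); W <- sample(2:9, 1)
    params <- ccnet_params(C, max(1L, C %/% 2L), seed = rep)
    m <- matrix(rnorm(C * W), C, W)
    got <- criss_cross_attention(m, params)
    expect_lt(max(abs(got - oracle_dense_attention(m, params))), 1e-5)
    expect_identical(dim(got), dim(m))
  }
})

test_that("zero value projection makes the attention a residual identity", {
  params <- ccnet_params(6, 2, seed = 1)
  params$wv[] <- 0
  m <- matrix(rnorm(6 * 7), 6, 7)
  expect_identical(criss_cross_attention(m, params), m)
  arr <- array(rnorm(6 * 4 * 3), c(6, 4, 3))
  expect_identical(criss_cross_attention(arr, params), arr)
})

test_that("criss-cross attention preserves shape for H > 1 maps", {
  params <- ccnet_params(5, 2, seed = 2)
  arr <- array(rnorm(5 * 4 * 3), c(5, 4, 3))
  out <- criss_cross_attention(arr, params)
  expect_identical(dim(out), dim(arr))
  expect_true(all(is.finite(out)))
  expect_error(criss_cross_attention(matrix(0, 3, 2), params), "mismatch")
})

test_that("attention-weighted set gate lies strictly in (0, 1)", {
  set.seed(5)
  for (rep in 1:10) {
    d_w <- sample(4:16, 1)
    params <- attsoft_params(d_w, seed = rep)
    v_sets <- matrix(rnorm(d_w * 4), d_w, 4)
    a <- attsoft_weights(v_sets, params)
    expect_length(a, 4L)
    expect_true(all(a > 0 & a < 1))
  }
  # zero q and bias: sigmoid(0) = 0.5 for every set
  params <- attsoft_params(6, seed = 1)
  params$q[] <- 0; params$q_bias[] <- 0
  expect_equal(attsoft_weights(matrix(rnorm(24), 6, 4), params),
               rep(0.5, 4))
})

test_that("set gate equals the step-by-step reference composition", {
  set.seed(6)
  d_w <- 8L
  params <- attsoft_params(d_w, seed = 10)
  v_sets <- matrix(rnorm(d_w * 4), d_w, 4)
  att <- oracle_dense_attention(v_sets, params$ccnet)
  ref <- as.vector(1 / (1 + exp(-(params$q %*% as.vector(att) +
                                    params$q_bias))))
  expect_equal(attsoft_weights(v_sets, params), ref, tolerance = 1e-10)
})

test_that("unit weights reproduce the static softlexicon feature exactly", {
  set.seed(7)
  lex <- example_lexicon()
  words <- c(lex$words, "<NONE>", "<UNK>", "<PAD>")
  emb <- embedding_table(matrix(rnorm(length(words) * 6), length(words), 6,
                                dimnames = list(words, NULL)))
  params <- attsoft_params(6, seed = 3)
  x_c <- rnorm(5)
  for (i in 1:4) {
    ws <- match_word_sets(example_sentence(), lex, i)
    expect_identical(attsoft_feature(x_c, ws, emb, params,
                                     weights = c(1, 1, 1, 1)),
                     softlexicon_feature(x_c, ws, emb))
    # zero weights zero the word blocks but keep the character block
    blocked <- attsoft_feature(x_c, ws, emb, params, weights = rep(0, 4))
    expect_identical(blocked[1:5], x_c)
    expect_true(all(blocked[-(1:5)] == 0))
    # learned weights scale block-by-block
    a <- attsoft_weights(lexner:::set_vector_matrix(ws, emb), params)
    got <- attsoft_feature(x_c, ws, emb, params)
    base <- softlexicon_feature(x_c, ws, emb)
    for (b in 1:4) {
      idx <- 5 + (b - 1) * 6 + 1:6
      expect_equal(got[idx], a[b] * base[idx])
    }
  }
})

test_that("PCAT preserves shape and vanishes with zero convolutions", {
  set.seed(8)
  C <- 6L
  params <- pcat_params(C, seed = 4)
  for (W in c(1L, 2L, 5L, 17L, 40L)) {
    x <- matrix(rnorm(C * W), C, W)
    out <- pcat_forward(x, params)
    expect_identical(dim(out), c(C, W))
  }
  zp <- pcat_params(C, seed = 4)
  for (nm in c("b1_in", "b1_out", "b2_in", "b2_out")) {
    zp[[nm]] <- lapply(zp[[nm]], function(m) { m[] <- 0; m })
  }
  x <- matrix(rnorm(C * 5), C, 5)
  expect_equal(pcat_forward(x, zp), matrix(0, C, 5))
  expect_error(pcat_forward(matrix(0, 3, 2), params), "mismatch")
})

test_that("PCAT equals the five-stage reference composition", {
  set.seed(9)
  C <- 5L; W <- 7L
  params <- pcat_params(C, seed = 11)
  x <- matrix(rnorm(C * W), C, W)
  conv1 <- function(x, p) p$w %*% x + as.vector(p$b)
  conv3 <- function(x, p) {
    pad <- matrix(0, nrow(x), 1)
    xl <- cbind(pad, x[, -ncol(x), drop = FALSE])
    xr <- cbind(x[, -1, drop = FALSE], pad)
    p$w_left %*% xl + p$w_mid %*% x + p$w_right %*% xr + as.vector(p$b)
  }
  ref <- conv3(oracle_dense_attention(conv1(x, params$b1_in), params$b1_cc),
               params$b1_out) +
    conv3(oracle_dense_attention(conv3(x, params$b2_in), params$b2_cc),
          params$b2_out)
  expect_equal(pcat_forward(x, params), ref, tolerance = 1e-10)
})

test_that("CRF partition and Viterbi match exhaustive enumeration", {
  set.seed(10)
  for (rep in 1:12) {
    T_ <- sample(2:4, 1); W <- sample(1:5, 1)
    params <- crf_params(paste0("t", seq_len(T_)), seed = rep)
    emissions <- matrix(rnorm(W * T_, sd = 2), W, T_)
    oracle <- oracle_crf_enumerate(emissions, params)
    expect_lt(abs(crf_log_partition(emissions, params) -
                    oracle$log_partition), 1e-6)
    vit <- crf_viterbi(emissions, params)
    expect_lt(abs(vit$score - oracle$best_score), 1e-6)
    expect_identical(vit$path, unname(oracle$best_path))
    # max <= logsumexp always
    expect_lte(vit$score, crf_log_partition(emissions, params))
  }
})

test_that("single-position CRF partition has its closed form", {
  params <- crf_params(c("a", "b", "c"), seed = 2)
  em <- matrix(c(0.3, -1, 2), 1, 3)
  scores <- em[1, ] + params$trans[4, 1:3] + params$trans[1:3, 5]
  mx <- max(scores)
  expect_equal(crf_log_partition(em, params), mx + log(sum(exp(scores - mx))))
})

test_that("Viterbi ties break toward the lowest tag index", {
  params <- crf_params(c("a", "b"), seed = 1)
  params$trans[] <- 0
  em <- matrix(0, 3, 2)   # fully tied
  expect_identical(crf_viterbi(em, params)$path, c(1L, 1L, 1L))
})

test_that("the BMES forbidden mask blocks exactly the ill-formed moves", {
  mask <- lexner:::bmes_forbidden_mask(c("O", "B-X", "M-X", "E-X", "S-X",
                                         "B-Y", "M-Y", "E-Y", "S-Y"))
  expect_false(mask["B-X", "M-X"])
  expect_false(mask["B-X", "E-X"])
  expect_true(mask["B-X", "B-Y"])
  expect_true(mask["B-X", "O"])
  expect_true(mask["B-X", "M-Y"])
  expect_true(mask["O", "E-X"])
  expect_true(mask["O", "M-X"])
  expect_false(mask["O", "B-X"])
  expect_false(mask["E-X", "O"])
  expect_false(mask["S-X", "B-Y"])
  expect_true(mask["<START>", "M-X"])
  expect_true(mask["B-X", "<STOP>"])
  expect_false(mask["E-X", "<STOP>"])
})
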