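# ASCII letters are ordinary characters for the detector (the separator
# set is punctuation/whitespace), so these fixtures stay readable.

test_that("n-gram extraction counts every in-segment window once", {
  st <- extract_ngram_counts("\u519c\u4e1a\u75c5\u5bb3\u8bc6\u522b",
                             n_values = 2)
  expect_identical(sort(names(st$counts[["2"]])),
                   sort(c("\u519c\u4e1a", "\u4e1a\u75c5", "\u75c5\u5bb3",
                          "\u5bb3\u8bc6", "\u8bc6\u522b")))
  expect_true(all(st$counts[["2"]] == 1L))
  expect_identical(st$totals[["2"]], 5L)

  empty <- extract_ngram_counts(character(), n_values = 2:4)
  expect_identical(empty$totals[["2"]], 0L)
  expect_length(empty$counts[["3"]], 0L)
})

test_that("windows never cross punctuation and totals are conserved", {
  set.seed(21)
  for (rep in 1:10) {
    segs <- replicate(5, paste(sample(letters[1:6], sample(2:9, 1),
                                      replace = TRUE), collapse = ""))
    corpus <- paste(segs, collapse = ", ")
    st <- extract_ngram_counts(corpus, n_values = 2:3)
    for (n in 2:3) {
      expected <- sum(pmax(nchar(segs) - n + 1L, 0L))
      expect_identical(st$totals[[as.character(n)]], expected)
      expect_identical(sum(st$counts[[as.character(n)]]), expected)
    }
  }
  st <- extract_ngram_counts("ab, cd", n_values = 2)
  expect_false("bc" %in% names(st$counts[["2"]]))
  expect_false("b c" %in% names(st$counts[["2"]]))
})

test_that("mutual information matches closed-form cases", {
  # p(w12) = p(w1) = p(w2) = 0.125 -> log2(0.125 / 0.125^2) = 3 bits
  st <- structure(list(counts = list("1" = c(a = 2L, b = 2L),
                                     "2" = c(ab = 1L)),
                       totals = list("1" = 16L, "2" = 8L),
                       n_values = 2L),
                  class = "ngram_counts")
  expect_equal(mutual_information("ab", st), 3.0)

  # statistically independent parts: MI = 0
  st$counts[["2"]] <- c(ab = 2L)
  st$totals[["2"]] <- 128L
  expect_equal(mutual_information("ab", st), 0.0)

  expect_error(mutual_information("zz", st), "zero probability")
})

test_that("longer-gram MI is the minimum over binary splits", {
  set.seed(5)
  corpus <- replicate(80, paste(sample(letters[1:8], sample(3:9, 1),
                                       replace = TRUE), collapse = ""))
  st <- extract_ngram_counts(corpus, n_values = 2:4)
  p <- function(s) {
    k <- as.character(nchar(s))
    as.numeric(st$counts[[k]][s]) / st$totals[[k]]
  }
  cands3 <- names(st$counts[["3"]])[st$counts[["3"]] >= 2]
  for (w in head(cands3, 10)) {
    parts <- strsplit(w, "")[[1]]
    ref <- min(log2(p(w) / (p(parts[1]) * p(paste0(parts[2], parts[3])))),
               log2(p(w) / (p(paste0(parts[1], parts[2])) * p(parts[3]))))
    expect_equal(mutual_information(w, st), ref)
  }
  cands4 <- names(st$counts[["4"]])[st$counts[["4"]] >= 2]
  for (w in head(cands4, 5)) {
    pt <- strsplit(w, "")[[1]]
    splits <- c(
      log2(p(w) / (p(pt[1]) * p(paste(pt[2:4], collapse = "")))),
      log2(p(w) / (p(paste(pt[1:2], collapse = "")) *
                     p(paste(pt[3:4], collapse = "")))),
      log2(p(w) / (p(paste(pt[1:3], collapse = "")) * p(pt[4]))))
    expect_equal(mutual_information(w, st), min(splits))
  }
})

test_that("contextual entropy matches closed-form distributions", {
  # one left neighbour (el = 0), four distinct right neighbours (er = 2)
  corpus <- c("xABa", "xABb", "xABc", "xABd")
  ce <- contextual_entropy("AB", corpus)
  expect_equal(unname(ce["el"]), 0.0)
  expect_equal(unname(ce["er"]), 2.0)

  # left neighbour distribution (1/2, 1/4, 1/4) -> 1.5 bits
  ce <- contextual_entropy("AB", c("xABa", "xABb", "yABc", "zABd"))
  expect_equal(unname(ce["el"]), 1.5)

  # boundary occurrences contribute a distinguished pseudo-neighbour
  ce <- contextual_entropy("AB", c("AB", "xAB"))
  expect_equal(unname(ce["el"]), 1.0)   # {boundary, x}
  expect_equal(unname(ce["er"]), 0.0)   # always boundary
})

test_that("entropy respects its log2(#neighbours) upper bound", {
  set.seed(31)
  for (rep in 1:20) {
    k <- sample(2:6, 1)
    corpus <- paste0(sample(letters, k), "AB", sample(letters, k))
    ce <- contextual_entropy("AB", corpus)
    expect_lte(ce["el"], log2(k) + 1e-12)
    expect_lte(ce["er"], log2(k) + 1e-12)
    expect_gte(min(ce), 0)
  }
})

test_that("threshold semantics: wf gate, base-dict exclusion, no 1-grams", {
  corpus <- rep("xxAByy", 4)   # every 2-gram occurs 4 times
  det <- detect_new_words(corpus,
                          detection_thresholds(wf_min = 5, mi_min = 0,
                                               ce_min = 0))
  expect_identical(nrow(det), 0L)

  set.seed(77)
  corpus <- c(replicate(30, paste0(sample(letters, 2), "AB",
                                   sample(letters, 2), collapse = "")))
  det <- detect_new_words(corpus, detection_thresholds(5, 0, 0))
  expect_true("AB" %in% det$word)
  expect_true(all(nchar(det$word) >= 2))
  det2 <- detect_new_words(corpus, detection_thresholds(5, 0, 0),
                           base_dict = segmenter_dict("AB"))
  expect_false("AB" %in% det2$word)
})

test_that("filter cascade is monotone in every threshold", {
  fix <- memorization_fixture(seed = 3)
  corpus <- fix$corpora$raw
  base <- detect_new_words(corpus, detection_thresholds(3, 1, 0.5))
  for (th in list(detection_thresholds(6, 1, 0.5),
                  detection_thresholds(3, 3, 0.5),
                  detection_thresholds(3, 1, 2))) {
    tighter <- detect_new_words(corpus, th)
    expect_true(all(tighter$word %in% base$word))
  }
})

test_that("forward maximum matching segments deterministically", {
  d <- segmenter_dict(c("\u690d\u7269", "\u75c5\u5bb3"))
  expect_identical(segment_sentence("\u690d\u7269\u75c5\u5bb3", d),
                   c("\u690d\u7269", "\u75c5\u5bb3"))
  d2 <- segdict_add(d, "\u690d\u7269\u75c5\u5bb3")
  expect_identical(segment_sentence("\u690d\u7269\u75c5\u5bb3", d2),
                   "\u690d\u7269\u75c5\u5bb3")
  # idempotent add
  d3 <- segdict_add(d2, "\u690d\u7269\u75c5\u5bb3")
  expect_identical(segment_sentence("\u690d\u7269\u75c5\u5bb3", d3),
                   "\u690d\u7269\u75c5\u5bb3")
  # fallback to single characters, concatenation conserved
  set.seed(41)
  for (rep in 1:20) {
    s <- paste(sample(letters[1:5], sample(1:10, 1), replace = TRUE),
               collapse = "")
    segs <- segment_sentence(s, d)
    expect_identical(paste(segs, collapse = ""), s)
  }
})

test_that("segmenter adapter hook overrides the built-in matcher", {
  d <- segmenter_dict(c("ab"), segment_fun = function(s, dict) {
    strsplit(s, "")[[1]]
  })
  expect_identical(segment_sentence("ab", d), c("a", "b"))
})

test_that("lexicon building counts produced segments of length >= 2", {
  d <- segmenter_dict(c("\u690d\u7269", "\u75c5\u5bb3"))
  lex <- build_lexicon("\u690d\u7269\u75c5\u5bb3", d)
  expect_setequal(lex$words, c("\u690d\u7269", "\u75c5\u5bb3"))
  expect_equal(lexicon_freq(lex, "\u690d\u7269"), 1)

  d2 <- segdict_add(segmenter_dict(c("\u690d\u7269", "\u75c5\u5bb3")),
                    "\u690d\u7269\u75c5\u5bb3")
  lex2 <- build_lexicon("\u690d\u7269\u75c5\u5bb3", d2)
  expect_identical(lex2$words, "\u690d\u7269\u75c5\u5bb3")

  expect_length(build_lexicon(character(), d), 0L)
  # single-character fallback segments are excluded
  lex3 <- build_lexicon("xy\u690d\u7269", d)
  expect_identical(lex3$words, "\u690d\u7269")
})
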