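# Statistics-based new-word detection: n-gram candidates filtered in turn
# by word frequency (WF), mutual information (MI, cohesion) and contextual
# entropy (CE, left/right branching entropy), then lexicon construction by
# dictionary segmentation of a second corpus.

# Punctuation/whitespace that candidate windows must not cross.  Covers
# ASCII punctuation plus the common CJK full-width marks.
DEFAULT_PUNCT <- paste0(
  "[\\s!-/:-@\\[-`{-~",
  "　-〿！-／：-＠［-｀｛-･",
  "‘’“”…—·]+"
)

# Split raw sentences into punctuation-free segments.
split_segments <- function(corpus, punct_regex = DEFAULT_PUNCT) {
  segs <- unlist(strsplit(enc2utf8(unlist(corpus)), punct_regex, perl = TRUE))
  segs[nchar(segs) > 0L]
}

#' Detection thresholds for new-word filtering
#'
#' Defaults follow the calibration for low-frequency domain terms:
#' word frequency at least 5, mutual information at least 3.9 bits,
#' contextual entropy at least 2.7 bits.
#'
#' @param wf_min minimum occurrence count.
#' @param mi_min minimum cohesion (bits).
#' @param ce_min minimum branching entropy (bits), applied to
#'   `min(left, right)`.
#' @return A list of class `detection_thresholds`.
#' @export
detection_thresholds <- function(wf_min = 5, mi_min = 3.9, ce_min = 2.7) {
  stopifnot(wf_min >= 0, mi_min >= 0, ce_min >= 0)
  structure(list(wf_min = wf_min, mi_min = mi_min, ce_min = ce_min),
            class = "detection_thresholds")
}

#' Extract n-gram counts from a raw corpus
#'
#' Slides fixed windows of each requested length over every
#' punctuation-free segment of the corpus and counts each window once.
#' Windows never cross punctuation or whitespace.  Counts for length-1
#' grams are always included (they supply the marginal probabilities used
#' by mutual information).
#'
#' @param corpus character vector (or list) of raw sentences.
#' @param n_values candidate lengths, a subset of `2:4`.
#' @param punct_regex regex of separators that windows must not cross.
#' @return A list of class `ngram_counts` with elements `counts` (per
#'   length: named integer vector) and `totals` (per length: number of
#'   windows), indexed by length as character keys `"1"`, `"2"`, ...
#' @export
extract_ngram_counts <- function(corpus, n_values = c(2L, 3L, 4L),
                                 punct_regex = DEFAULT_PUNCT) {
  n_values <- sort(unique(as.integer(n_values)))
  if (!all(n_values %in% 2:4)) stop("n_values must be a subset of 2:4")
  segs <- split_segments(corpus, punct_regex)
  lens <- sort(unique(c(1L, n_values)))
  counts <- list(); totals <- list()
  for (n in lens) {
    key <- as.character(n)
    if (!length(segs)) { counts[[key]] <- integer(); totals[[key]] <- 0L; next }
    seg_n <- segs[nchar(segs) >= n]
    if (!length(seg_n)) { counts[[key]] <- integer(); totals[[key]] <- 0L; next }
    grams <- unlist(lapply(seg_n, function(s) {
      L <- nchar(s)
      substring(s, 1:(L - n + 1L), n:L)
    }))
    tb <- table(grams)
    counts[[key]] <- stats::setNames(as.integer(tb), names(tb))
    totals[[key]] <- length(grams)
  }
  structure(list(counts = counts, totals = totals, n_values = n_values),
            class = "ngram_counts")
}

gram_prob <- function(s, stats) {
  key <- as.character(nchar(s))
  cnt <- stats$counts[[key]][s]
  tot <- stats$totals[[key]]
  if (is.na(cnt) || is.null(tot) || tot == 0L) {
    stop("string ", dQuote(s), " (or a part of it) has zero probability ",
         "under the supplied counts")
  }
  as.numeric(cnt) / tot
}

#' Mutual information (cohesion) of a candidate string
#'
#' For a two-character candidate, returns
#' `log2(p(w12) / (p(w1) p(w2)))` with probabilities estimated as
#' `count / number of windows of that length`.  For candidates of length
#' 3-4 the cohesion is the minimum over all internal binary split points:
#' a string is only as cohesive as its weakest split.
#'
#' @param w candidate string, length 2-4 characters.
#' @param stats an [extract_ngram_counts()] result covering all needed
#'   lengths (1 up to `nchar(w)`).
#' @return Cohesion in bits.
#' @export
mutual_information <- function(w, stats) {
  w <- enc2utf8(w)
  L <- nchar(w)
  if (L < 2L || L > 4L) stop("candidate length must be 2-4 characters")
  p_w <- gram_prob(w, stats)
  vals <- vapply(seq_len(L - 1L), function(k) {
    left <- substr(w, 1L, k)
    right <- substr(w, k + 1L, L)
    log2(p_w / (gram_prob(left, stats) * gram_prob(right, stats)))
  }, numeric(1))
  min(vals)
}

# All overlapping match start positions of `pat` in `s` (1-based).
find_all_overlapping <- function(pat, s) {
  out <- integer()
  from <- 1L
  repeat {
    hit <- regexpr(pat, substring(s, from), fixed = TRUE)
    if (hit == -1L) break
    pos <- from + as.integer(hit) - 1L
    out <- c(out, pos)
    from <- pos + 1L
  }
  out
}

entropy_bits <- function(counts) {
  p <- counts / sum(counts)
  -sum(p * log2(p))
}

#' Left and right contextual entropy of a candidate string
#'
#' The branching entropy of the characters adjacent to each occurrence of
#' `w` in the corpus: `E_l = -sum p(c|w) log2 p(c|w)` over observed left
#' neighbours, and symmetrically for the right.  Occurrences at a segment
#' boundary contribute a distinguished boundary pseudo-neighbour.
#' High entropy on both sides indicates a free-standing word.
#'
#' @param w candidate string.
#' @param corpus character vector of raw sentences.
#' @param punct_regex segment separator regex, as in
#'   [extract_ngram_counts()].
#' @return Named numeric vector `c(el = ..., er = ...)` in bits.
#' @export
contextual_entropy <- function(w, corpus, punct_regex = DEFAULT_PUNCT) {
  segs <- split_segments(corpus, punct_regex)
  ce_from_segments(enc2utf8(w), segs)
}

ce_from_segments <- function(w, segs) {
  # join segments with a sentinel so one scan covers the corpus; the
  # sentinel doubles as the boundary pseudo-neighbour
  sep <- "\u0001"
  big <- paste(segs, collapse = sep)
  big <- paste0(sep, big, sep)
  pos <- find_all_overlapping(w, big)
  if (!length(pos)) stop("candidate ", dQuote(w), " does not occur in corpus")
  L <- nchar(w)
  left <- substring(big, pos - 1L, pos - 1L)
  right <- substring(big, pos + L, pos + L)
  c(el = entropy_bits(table(left)), er = entropy_bits(table(right)))
}

#' Detect new words in a raw corpus
#'
#' Generates n-gram candidates (lengths 2-4 by default) and filters them
#' in turn by word frequency, mutual information and contextual entropy,
#' excluding words already present in the base dictionary.  Single
#' characters are never candidates.
#'
#' @param corpus character vector of raw sentences.
#' @param thresholds a [detection_thresholds()].
#' @param base_dict a [segmenter_dict()] (or `NULL`): known words to
#'   exclude from the output.
#' @param n_values candidate lengths, subset of 2:4.
#' @param punct_regex segment separator regex.
#' @return A data.frame of class `newword_result` with columns `word`,
#'   `wf`, `mi`, `el`, `er`, sorted by decreasing `wf` then word; the
#'   statistics are attached for audit even though filtering already
#'   used them.
#' @export
detect_new_words <- function(corpus,
                             thresholds = detection_thresholds(),
                             base_dict = NULL,
                             n_values = c(2L, 3L, 4L),
                             punct_regex = DEFAULT_PUNCT) {
  if (!length(corpus)) stop("corpus is empty")
  stats <- extract_ngram_counts(corpus, n_values, punct_regex)
  segs <- split_segments(corpus, punct_regex)

  cand <- character(); wf <- numeric()
  for (n in stats$n_values) {
    cn <- stats$counts[[as.character(n)]]
    keep <- cn >= thresholds$wf_min
    cand <- c(cand, names(cn)[keep])
    wf <- c(wf, as.numeric(cn[keep]))
  }
  if (!is.null(base_dict)) {
    known <- vapply(cand, function(w) segdict_has(base_dict, w), logical(1))
    cand <- cand[!known]; wf <- wf[!known]
  }
  mi <- vapply(cand, mutual_information, numeric(1), stats = stats)
  keep <- mi >= thresholds$mi_min
  cand <- cand[keep]; wf <- wf[keep]; mi <- mi[keep]

  if (length(cand)) {
    ce <- t(vapply(cand, ce_from_segments, numeric(2), segs = segs))
    keep <- pmin(ce[, "el"], ce[, "er"]) >= thresholds$ce_min
    out <- data.frame(word = cand[keep], wf = wf[keep], mi = mi[keep],
                      el = ce[keep, "el"], er = ce[keep, "er"],
                      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(word = character(), wf = numeric(), mi = numeric(),
                      el = numeric(), er = numeric(), stringsAsFactors = FALSE)
  }
  out <- out[order(-out$wf, out$word, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("newword_result", "data.frame")
  out
}

#' @export
print.newword_result <- function(x, ...) {
  cat("<newword_result>", nrow(x), "detected words\n")
  if (nrow(x)) print.data.frame(utils::head(x, 20), digits = 4)
  invisible(x)
}

#' Construct a segmenter dictionary
#'
#' A word set backing the built-in forward-maximum-matching segmenter.
#' Adding a word is idempotent.  An external segmenter can be plugged in
#' through the `segment_fun` hook; the detection statistics and filters
#' are segmenter-independent.
#'
#' @param words character vector of base vocabulary words.
#' @param segment_fun optional function `(sentence, dict) -> character
#'   vector of segments` overriding the built-in longest-match segmenter.
#' @return Object of class `segmenter_dict`.
#' @export
segmenter_dict <- function(words = character(), segment_fun = NULL) {
  tab <- new.env(hash = TRUE, parent = emptyenv())
  words <- enc2utf8(words)
  for (w in words) assign(w, TRUE, envir = tab)
  structure(list(table = tab,
                 max_len = if (length(words)) max(nchar(words)) else 1L,
                 segment_fun = segment_fun),
            class = "segmenter_dict")
}

#' @export
print.segmenter_dict <- function(x, ...) {
  cat("<segmenter_dict>", length(ls(x$table)), "words\n")
  invisible(x)
}

segdict_has <- function(dict, w) !is.null(dict$table[[enc2utf8(w)]])

#' Add words to a segmenter dictionary
#' @param dict a [segmenter_dict()].
#' @param words character vector of words to add (idempotent).
#' @return The updated dictionary (modified in place and returned).
#' @export
segdict_add <- function(dict, words) {
  words <- enc2utf8(words)
  for (w in words) assign(w, TRUE, envir = dict$table)
  dict$max_len <- max(dict$max_len, if (length(words)) max(nchar(words)) else 1L)
  dict
}

#' Segment a sentence by forward maximum matching
#'
#' Deterministic left-to-right longest-match over the dictionary with
#' single characters as fallback; concatenating the segments reproduces
#' the input exactly.
#'
#' @param sentence a single string.
#' @param dict a [segmenter_dict()].
#' @return Character vector of segments.
#' @export
segment_sentence <- function(sentence, dict) {
  if (!is.null(dict$segment_fun)) return(dict$segment_fun(sentence, dict))
  s <- enc2utf8(sentence)
  n <- nchar(s)
  out <- character(); i <- 1L
  while (i <= n) {
    found <- 1L
    upper <- min(dict$max_len, n - i + 1L)
    for (len in seq(upper, 1L)) {
      cand <- substr(s, i, i + len - 1L)
      if (segdict_has(dict, cand)) { found <- len; break }
    }
    out <- c(out, substr(s, i, i + found - 1L))
    i <- i + found
  }
  out
}

#' Build an NER lexicon by segmenting a corpus
#'
#' Segments every sentence of the annotation-source corpus with the
#' dictionary segmenter (whose vocabulary should already include the
#' detected new words) and collects every produced segment of length >= 2
#' together with its production count `z(w)`.
#'
#' @param corpus_b character vector of raw sentences.
#' @param segmenter a [segmenter_dict()] with new words already added.
#' @return A [lexicon()].
#' @export
build_lexicon <- function(corpus_b, segmenter) {
  if (!length(corpus_b)) return(lexicon())
  segs <- unlist(lapply(corpus_b, segment_sentence, dict = segmenter))
  segs <- segs[nchar(segs) >= 2L]
  if (!length(segs)) return(lexicon())
  tb <- table(segs)
  lexicon(names(tb), as.integer(tb))
}
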