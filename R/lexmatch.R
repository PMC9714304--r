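# BMES word-set matching against a lexicon and frequency-weighted
# (Softlexicon) set vectors.

NONE_TOKEN <- "<NONE>"

#' Match the four BMES word sets for one character
#'
#' For character `i` of a sentence, collects every lexicon word that
#' contains the character and assigns it to one of four sets by the
#' character's position in the word: `b` (word begins at `i`), `m`
#' (character strictly interior), `e` (word ends at `i`), `s` (the
#' single-character word itself).  Empty sets are represented by the
#' `<NONE>` placeholder with frequency 1, so the frequency-weighted sum
#' stays defined.  Matching walks the lexicon trie from each feasible
#' start position, so cost is bounded by the longest lexicon word.
#'
#' @param sentence a single string (or character vector of characters).
#' @param lex a [lexicon()].
#' @param i character index, 1-based.
#' @return Object of class `word_sets`: list with elements `b`, `m`, `e`,
#'   `s`, each a data.frame with columns `word` and `z`, ordered by
#'   increasing start index then length.
#' @export
match_word_sets <- function(sentence, lex, i) {
  chars <- if (length(sentence) > 1L) enc2utf8(sentence) else split_chars(sentence)
  n <- length(chars)
  if (i < 1L || i > n) stop("character index ", i, " out of range 1..", n)

  b <- list(); m <- list(); e <- list(); s <- list()
  lo <- max(1L, i - lex$max_len + 1L)
  starts <- if (lex$max_len > 0L) lo:i else integer()
  for (j in starts) {
    # walk the trie from start j; any word found spans [j, k]
    node <- lex$trie
    k <- j
    while (k <= n && k < j + lex$max_len) {
      node <- node[[chars[[k]]]]
      if (is.null(node)) break
      if (isTRUE(node$.word) && k >= i) {
        w <- paste(chars[j:k], collapse = "")
        z <- lex$table[[w]]
        entry <- list(word = w, z = z, start = j, len = k - j + 1L)
        if (j == i && k == i) {
          s[[length(s) + 1L]] <- entry
        } else if (j == i) {
          b[[length(b) + 1L]] <- entry
        } else if (k == i) {
          e[[length(e) + 1L]] <- entry
        } else {
          m[[length(m) + 1L]] <- entry
        }
      }
      k <- k + 1L
    }
  }
  as_set_df <- function(lst) {
    if (!length(lst)) {
      return(data.frame(word = NONE_TOKEN, z = 1, stringsAsFactors = FALSE))
    }
    starts <- vapply(lst, `[[`, 0L, "start")
    lens <- vapply(lst, `[[`, 0L, "len")
    ord <- order(starts, lens)
    data.frame(word = vapply(lst, `[[`, "", "word")[ord],
               z = vapply(lst, `[[`, 0, "z")[ord],
               stringsAsFactors = FALSE)
  }
  structure(list(b = as_set_df(b), m = as_set_df(m),
                 e = as_set_df(e), s = as_set_df(s)),
            class = "word_sets")
}

#' @export
print.word_sets <- function(x, ...) {
  for (nm in c("b", "m", "e", "s")) {
    cat(toupper(nm), "= {",
        paste(sprintf("%s:%g", x[[nm]]$word, x[[nm]]$z), collapse = ", "),
        "}\n")
  }
  invisible(x)
}

# Brute-force reference matcher: enumerate all substrings covering i.
# Kept exported-free; used as the oracle route in tests.
match_word_sets_bruteforce <- function(sentence, lex, i) {
  chars <- if (length(sentence) > 1L) enc2utf8(sentence) else split_chars(sentence)
  n <- length(chars)
  if (i < 1L || i > n) stop("character index out of range")
  b <- list(); m <- list(); e <- list(); s <- list()
  for (j in seq_len(n)) {
    for (k in j:n) {
      if (j > i || k < i) next
      w <- paste(chars[j:k], collapse = "")
      if (!lexicon_has(lex, w)) next
      entry <- list(word = w, z = lex$table[[w]], start = j, len = k - j + 1L)
      if (j == i && k == i) s[[length(s) + 1L]] <- entry
      else if (j == i) b[[length(b) + 1L]] <- entry
      else if (k == i) e[[length(e) + 1L]] <- entry
      else m[[length(m) + 1L]] <- entry
    }
  }
  as_set_df <- function(lst) {
    if (!length(lst)) {
      return(data.frame(word = NONE_TOKEN, z = 1, stringsAsFactors = FALSE))
    }
    starts <- vapply(lst, `[[`, 0L, "start")
    lens <- vapply(lst, `[[`, 0L, "len")
    ord <- order(starts, lens)
    data.frame(word = vapply(lst, `[[`, "", "word")[ord],
               z = vapply(lst, `[[`, 0, "z")[ord],
               stringsAsFactors = FALSE)
  }
  structure(list(b = as_set_df(b), m = as_set_df(m),
                 e = as_set_df(e), s = as_set_df(s)),
            class = "word_sets")
}

#' Total frequency mass across the four word sets
#'
#' `Z = sum of z(w)` over the union of the B/M/E/S sets, `<NONE>`
#' placeholders included (each contributing 1).
#'
#' @param word_sets a [match_word_sets()] result.
#' @return Numeric scalar `Z`.
#' @export
word_sets_total <- function(word_sets) {
  sum(vapply(word_sets[c("b", "m", "e", "s")],
             function(df) sum(df$z), numeric(1)))
}

#' Frequency-weighted vector of one word set
#'
#' Returns `(4 / Z) * sum_w z(w) e^w(w)`: word embeddings weighted by
#' static lexicon frequency, normalised by the total mass `Z` over all
#' four sets.  Words missing from the embedding table fall back to the
#' `<UNK>` vector.
#'
#' @param set one element (`b`, `m`, `e` or `s`) of a
#'   [match_word_sets()] result.
#' @param z_total total mass `Z` from [word_sets_total()].
#' @param emb an [embedding_table()] over words.
#' @return Numeric vector of length `emb$dim`.
#' @export
weighted_set_vector <- function(set, z_total, emb) {
  vecs <- embedding_lookup(emb, set$word)
  as.numeric((4 / z_total) * crossprod(vecs, set$z))
}

#' Baseline Softlexicon character feature (static weighting)
#'
#' Concatenates the character embedding with the four frequency-weighted
#' set vectors: `[x_c; v(B); v(M); v(E); v(S)]`, dimension
#' `d_c + 4 d_w`.  This is the static baseline that the attention-weighted
#' variant ([attsoft_feature()]) reduces to when all set weights are 1.
#'
#' @param x_c character embedding vector (length `d_c`).
#' @param word_sets a [match_word_sets()] result.
#' @param emb word [embedding_table()].
#' @return Numeric vector of length `d_c + 4 * emb$dim`.
#' @export
softlexicon_feature <- function(x_c, word_sets, emb) {
  z <- word_sets_total(word_sets)
  c(x_c,
    weighted_set_vector(word_sets$b, z, emb),
    weighted_set_vector(word_sets$m, z, emb),
    weighted_set_vector(word_sets$e, z, emb),
    weighted_set_vector(word_sets$s, z, emb))
}

# Stack the four weighted set vectors as a [d_w x 4] matrix (columns in
# B, M, E, S order) for attention-based set weighting.
set_vector_matrix <- function(word_sets, emb) {
  z <- word_sets_total(word_sets)
  cbind(weighted_set_vector(word_sets$b, z, emb),
        weighted_set_vector(word_sets$m, z, emb),
        weighted_set_vector(word_sets$e, z, emb),
        weighted_set_vector(word_sets$s, z, emb))
}
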