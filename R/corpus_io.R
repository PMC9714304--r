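#' @keywords internal
"_PACKAGE"

# Reserved embedding tokens.  NONE marks an empty BMES word set, UNK an
# out-of-table word, PAD a padding position.
RESERVED_TOKENS <- c("<UNK>", "<NONE>", "<PAD>")

split_chars <- function(x) {
  strsplit(enc2utf8(x), "", fixed = TRUE)[[1]]
}

#' Construct a tagged sentence
#'
#' A tagged sentence pairs a character sequence with one BMES-O tag per
#' character.  Tags are either `"O"` or `"<pos>-<category>"` with
#' `pos` one of `B` (begin), `M` (middle), `E` (end), `S` (single).
#'
#' @param chars character vector of single characters (or a single string,
#'   which is split into characters).
#' @param tags character vector of tags, same length as `chars`.
#' @return An object of class `tagged_sentence`: a list with elements
#'   `chars` and `tags`.
#' @export
tagged_sentence <- function(chars, tags) {
  if (length(chars) == 1L && nchar(chars) > 1L) chars <- split_chars(chars)
  chars <- enc2utf8(chars)
  tags <- enc2utf8(tags)
  if (length(chars) != length(tags)) {
    stop("chars and tags must have equal length (", length(chars), " vs ",
         length(tags), ")")
  }
  if (length(chars) < 1L) stop("a sentence must contain at least one character")
  check_tags(tags)
  structure(list(chars = chars, tags = tags), class = "tagged_sentence")
}

check_tags <- function(tags) {
  bad <- !(tags == "O" | grepl("^[BMES]-.+$", tags))
  if (any(bad)) {
    stop("malformed tag(s): ", paste(unique(tags[bad]), collapse = ", "),
         " (expected \"O\" or \"<B|M|E|S>-<category>\")")
  }
  invisible(TRUE)
}

#' @export
print.tagged_sentence <- function(x, ...) {
  cat(paste(x$chars, collapse = ""), "\n")
  cat(paste(sprintf("%s/%s", x$chars, x$tags), collapse = " "), "\n")
  invisible(x)
}

#' Read a character-level tagged corpus
#'
#' Reads a CoNLL-style two-column file: one `character<TAB>tag` pair per
#' line, sentences separated by blank lines.  Tags follow the BMES-O
#' scheme (`B-X`/`M-X`/`E-X`/`S-X` for entity characters of category `X`,
#' `O` elsewhere).
#'
#' @param path path to the corpus file.
#' @param encoding text encoding, default `"UTF-8"`.
#' @return A list of [tagged_sentence()] objects with attribute
#'   `"categories"`: the sorted set of entity categories seen.
#' @export
read_tagged_corpus <- function(path, encoding = "UTF-8") {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, encoding = encoding)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  sentences <- list()
  chars <- character()
  tags <- character()
  flush_sentence <- function() {
    if (length(chars) > 0L) {
      sentences[[length(sentences) + 1L]] <<- tagged_sentence(chars, tags)
      chars <<- character(); tags <<- character()
    }
  }
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (line == "") { flush_sentence(); next }
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2L) {
      stop("line ", i, ": expected 2 tab-separated columns, got ",
           length(parts))
    }
    tag <- parts[[2]]
    if (!(tag == "O" || grepl("^[BMES]-.+$", tag))) {
      stop("line ", i, ": unknown tag ", dQuote(tag),
           " (position code must be one of B, M, E, S, or tag \"O\")")
    }
    chars <- c(chars, parts[[1]])
    tags <- c(tags, tag)
  }
  flush_sentence()
  cats <- sort(unique(unlist(lapply(sentences, function(s) {
    sub("^[BMES]-", "", s$tags[s$tags != "O"])
  }))))
  attr(sentences, "categories") <- if (length(cats)) cats else character()
  sentences
}

#' Write a character-level tagged corpus
#'
#' Inverse of [read_tagged_corpus()]: writes `char<TAB>tag` lines with a
#' blank line after each sentence.
#'
#' @param corpus list of [tagged_sentence()] objects.
#' @param path output file path.
#' @export
write_tagged_corpus <- function(corpus, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (s in corpus) {
    writeLines(paste(s$chars, s$tags, sep = "\t"), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Convert a BMES-O tag sequence to entity spans
#'
#' Decodes maximal well-formed entities: `S-X` yields a single-character
#' span, `B-X (M-X)* E-X` a multi-character span.  Coordinates are 0-based
#' and half-open.  Ill-formed runs (an `M` without a `B`, a category switch
#' mid-entity, a dangling `B`) yield no span for the ill-formed portion:
#' decoding is conservative so that evaluation never credits a prediction
#' the scheme cannot express.
#'
#' @param tags character vector of BMES-O tags.
#' @return A data.frame with columns `start`, `end` (0-based half-open)
#'   and `category`, sorted by `start`.
#' @export
tags_to_spans <- function(tags) {
  check_tags(tags)
  n <- length(tags)
  starts <- integer(); ends <- integer(); cats <- character()
  i <- 1L
  while (i <= n) {
    tag <- tags[[i]]
    pos <- substr(tag, 1L, 1L)
    if (pos == "S") {
      cat_i <- substring(tag, 3L)
      starts <- c(starts, i - 1L); ends <- c(ends, i); cats <- c(cats, cat_i)
      i <- i + 1L
    } else if (pos == "B") {
      cat_i <- substring(tag, 3L)
      j <- i + 1L
      while (j <= n && tags[[j]] == paste0("M-", cat_i)) j <- j + 1L
      if (j <= n && tags[[j]] == paste0("E-", cat_i)) {
        starts <- c(starts, i - 1L); ends <- c(ends, j); cats <- c(cats, cat_i)
        i <- j + 1L
      } else {
        i <- i + 1L   # dangling B: drop this position, rescan from next
      }
    } else {
      i <- i + 1L     # O, or stray M/E: no span
    }
  }
  data.frame(start = starts, end = ends, category = cats,
             stringsAsFactors = FALSE)
}

#' Convert entity spans to a BMES-O tag sequence
#'
#' Inverse of [tags_to_spans()].  Spans must be non-overlapping and lie
#' within `[0, n)`.
#'
#' @param spans data.frame with columns `start`, `end`, `category`
#'   (0-based half-open coordinates).
#' @param n sentence length in characters.
#' @return Character vector of `n` BMES-O tags.
#' @export
spans_to_tags <- function(spans, n) {
  tags <- rep("O", n)
  if (is.null(spans) || nrow(spans) == 0L) return(tags)
  if (any(spans$start < 0L) || any(spans$end > n) ||
      any(spans$start >= spans$end)) {
    stop("span out of range for sentence of length ", n)
  }
  covered <- logical(n)
  ord <- order(spans$start)
  for (k in ord) {
    idx <- (spans$start[k] + 1L):spans$end[k]
    if (any(covered[idx])) stop("overlapping spans")
    covered[idx] <- TRUE
    len <- length(idx)
    cat_k <- spans$category[k]
    if (len == 1L) {
      tags[idx] <- paste0("S-", cat_k)
    } else {
      tags[idx[1]] <- paste0("B-", cat_k)
      if (len > 2L) tags[idx[2:(len - 1L)]] <- paste0("M-", cat_k)
      tags[idx[len]] <- paste0("E-", cat_k)
    }
  }
  tags
}

#' Construct a lexicon
#'
#' A lexicon maps words to their corpus frequency `z(w)` and carries a trie
#' index for prefix-walk containment queries during BMES matching.
#'
#' @param words character vector of words (length >= 1 each).
#' @param freqs positive integer frequencies, recycled if length 1.
#' @return An object of class `lexicon`.
#' @export
lexicon <- function(words = character(), freqs = integer()) {
  words <- enc2utf8(words)
  if (length(freqs) == 1L) freqs <- rep(freqs, length(words))
  if (length(words) != length(freqs)) stop("words and freqs length mismatch")
  if (length(words) && any(nchar(words) < 1L)) stop("zero-length word")
  freqs <- as.numeric(freqs)
  if (length(freqs) && (any(freqs < 1) || any(freqs != floor(freqs)))) {
    stop("frequencies must be positive integers")
  }
  # merge duplicates by summation
  if (anyDuplicated(words)) {
    agg <- tapply(freqs, words, sum)
    words <- names(agg); freqs <- as.numeric(agg)
  }
  tab <- new.env(hash = TRUE, parent = emptyenv())
  for (k in seq_along(words)) assign(words[[k]], freqs[[k]], envir = tab)
  structure(list(table = tab,
                 words = words,
                 trie = build_trie(words),
                 max_len = if (length(words)) max(nchar(words)) else 0L),
            class = "lexicon")
}

build_trie <- function(words) {
  root <- new.env(hash = TRUE, parent = emptyenv())
  for (w in words) {
    node <- root
    for (ch in split_chars(w)) {
      nxt <- node[[ch]]
      if (is.null(nxt)) {
        nxt <- new.env(hash = TRUE, parent = emptyenv())
        assign(ch, nxt, envir = node)
      }
      node <- nxt
    }
    assign(".word", TRUE, envir = node)
  }
  root
}

#' @export
print.lexicon <- function(x, ...) {
  cat("<lexicon>", length(x$words), "words, max length", x$max_len, "\n")
  invisible(x)
}

#' @export
length.lexicon <- function(x) length(x$words)

#' Look up a word's frequency in a lexicon
#'
#' @param lex a [lexicon()].
#' @param word word to look up.
#' @return Frequency `z(w)`, or `NA` if absent.
#' @export
lexicon_freq <- function(lex, word) {
  v <- lex$table[[enc2utf8(word)]]
  if (is.null(v)) NA_real_ else v
}

#' Test lexicon membership
#' @param lex a [lexicon()].
#' @param word word to test.
#' @return `TRUE` if `word` is in the lexicon.
#' @export
lexicon_has <- function(lex, word) !is.null(lex$table[[enc2utf8(word)]])

#' Read a lexicon from a TSV file
#'
#' Lines are `word<TAB>frequency`.  Duplicate words are merged by summing
#' their frequencies (with a warning), so lexicon shards can be
#' concatenated.
#'
#' @param path input path.
#' @param encoding text encoding.
#' @return A [lexicon()].
#' @export
read_lexicon <- function(path, encoding = "UTF-8") {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, encoding = encoding)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines <- lines[lines != ""]
  if (!length(lines)) return(lexicon())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nc <- lengths(parts)
  if (any(nc != 2L)) {
    stop("line ", which(nc != 2L)[1],
         ": expected 2 tab-separated columns")
  }
  words <- vapply(parts, `[[`, "", 1L)
  freq_s <- vapply(parts, `[[`, "", 2L)
  freqs <- suppressWarnings(as.numeric(freq_s))
  bad <- is.na(freqs) | freqs <= 0 | freqs != floor(freqs)
  if (any(bad)) {
    stop("line ", which(bad)[1], ": frequency must be a positive integer, got ",
         dQuote(freq_s[which(bad)[1]]))
  }
  if (anyDuplicated(words)) {
    warning("duplicate lexicon entries merged by summing frequencies")
  }
  lexicon(words, freqs)
}

#' Write a lexicon to a TSV file
#' @param lex a [lexicon()].
#' @param path output path.
#' @export
write_lexicon <- function(lex, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  ord <- order(lex$words, method = "radix")
  for (k in ord) {
    writeLines(paste0(lex$words[[k]], "\t",
                      format(lex$table[[lex$words[[k]]]], scientific = FALSE)),
               con)
  }
  invisible(path)
}

#' Construct an embedding table
#'
#' @param mat numeric matrix, one row per token, with rownames.
#' @param seed seed used to draw vectors for missing reserved tokens
#'   (`<UNK>`, `<NONE>`, `<PAD>`), uniform on (-0.1, 0.1).
#' @return Object of class `embedding_table`: list with `dim` and `mat`.
#' @export
embedding_table <- function(mat, seed = 42L) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)))
  rownames(mat) <- enc2utf8(rownames(mat))
  d <- ncol(mat)
  missing_res <- setdiff(RESERVED_TOKENS, rownames(mat))
  if (length(missing_res)) {
    extra <- with_seed(seed, {
      matrix(stats::runif(length(missing_res) * d, -0.1, 0.1),
             nrow = length(missing_res), dimnames = list(missing_res, NULL))
    })
    mat <- rbind(mat, extra)
  }
  structure(list(dim = d, mat = mat), class = "embedding_table")
}

#' @export
print.embedding_table <- function(x, ...) {
  cat("<embedding_table>", nrow(x$mat), "tokens, dim", x$dim, "\n")
  invisible(x)
}

#' Look up embedding vectors
#'
#' Unknown tokens map to the `<UNK>` vector; a note is emitted once per
#' call for the distinct unknowns encountered.
#'
#' @param emb an [embedding_table()].
#' @param tokens character vector of tokens.
#' @param warn_unknown emit a message listing unknown tokens.
#' @return Numeric matrix, one row per requested token.
#' @export
embedding_lookup <- function(emb, tokens, warn_unknown = FALSE) {
  tokens <- enc2utf8(tokens)
  idx <- match(tokens, rownames(emb$mat))
  if (anyNA(idx)) {
    if (warn_unknown) {
      message("tokens missing from embedding table, using <UNK>: ",
              paste(unique(tokens[is.na(idx)]), collapse = " "))
    }
    idx[is.na(idx)] <- match("<UNK>", rownames(emb$mat))
  }
  out <- emb$mat[idx, , drop = FALSE]
  rownames(out) <- tokens
  out
}

#' Read word2vec-format text embeddings
#'
#' Accepts the word2vec text dialect: an optional header line
#' `"<count> <dim>"` followed by `"token v1 ... v_dim"` rows separated by
#' single spaces.  Reserved tokens `<UNK>`, `<NONE>`, `<PAD>` are appended
#' with seeded uniform(-0.1, 0.1) vectors when absent from the file.
#'
#' @param path input path.
#' @param dim expected vector dimension; checked against every row.
#' @param seed seed for reserved-token initialisation.
#' @return An [embedding_table()].
#' @export
read_embeddings <- function(path, dim, seed = 42L) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, encoding = "UTF-8")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines <- lines[lines != ""]
  if (!length(lines)) stop("empty embeddings file: ", path)
  first <- strsplit(trimws(lines[[1]]), " +")[[1]]
  has_header <- length(first) == 2L &&
    !anyNA(suppressWarnings(as.numeric(first)))
  if (has_header) lines <- lines[-1]
  toks <- character(length(lines))
  vecs <- matrix(0, nrow = length(lines), ncol = dim)
  for (i in seq_along(lines)) {
    parts <- strsplit(trimws(lines[[i]]), " +")[[1]]
    if (length(parts) != dim + 1L) {
      stop("token ", dQuote(parts[[1]]), ": expected ", dim,
           " values, got ", length(parts) - 1L)
    }
    vals <- suppressWarnings(as.numeric(parts[-1]))
    if (anyNA(vals)) stop("token ", dQuote(parts[[1]]), ": non-numeric value")
    toks[[i]] <- parts[[1]]
    vecs[i, ] <- vals
  }
  rownames(vecs) <- toks
  embedding_table(vecs, seed = seed)
}

#' Write embeddings in word2vec text format
#' @param emb an [embedding_table()].
#' @param path output path.
#' @param header write the `"count dim"` header line.
#' @export
write_embeddings <- function(emb, path, header = TRUE) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  if (header) writeLines(paste(nrow(emb$mat), emb$dim), con)
  for (i in seq_len(nrow(emb$mat))) {
    writeLines(paste(c(rownames(emb$mat)[i],
                       format(emb$mat[i, ], scientific = FALSE, trim = TRUE)),
                     collapse = " "), con)
  }
  invisible(path)
}

# Evaluate expr under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  expr
}
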