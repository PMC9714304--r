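# Seeded synthetic corpora that emulate the statistical structure of a
# domain NER corpus: multi-character domain words, six unevenly
# distributed entity categories, nested words, and sentences assembled by
# word concatenation so the gold segmentation is well defined.
#
# Pseudo-characters come from the Unicode private-use area, so nothing in
# the pipeline can rely on real-language regularities.

# Default uneven category mix, mirroring the kind of imbalance seen in
# hand-annotated agricultural corpora (varieties/parts/places abundant,
# diseases/chemicals rare).
DEFAULT_CATEGORY_COUNTS <- c(KIWI = 3763, DIS = 561, PEST = 1247,
                             PART = 5521, MED = 907, LOC = 5090)

#' Specification for a synthetic NER world
#'
#' @param alphabet_size number of pseudo-characters (private-use Unicode).
#' @param n_common_words non-entity vocabulary size (lengths 2-4).
#' @param n_domain_words entity vocabulary size (lengths 2-4).
#' @param n_categories number of entity categories.
#' @param category_proportions sampling proportions per category; must sum
#'   to 1.  The default is an uneven mix patterned on real annotated
#'   corpora.
#' @param nested_fraction fraction of domain words that contain a shorter
#'   vocabulary word as a proper substring.
#' @param n_sentences corpus size.
#' @param mean_words mean number of word tokens per sentence.
#' @param entity_share probability that a sampled word token is an entity.
#' @param zipf_exponent word-sampling weights are `rank^(-zipf_exponent)`.
#' @param seed RNG seed fixing all outputs.
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(alphabet_size = 300L, n_common_words = 150L,
                       n_domain_words = 60L, n_categories = 6L,
                       category_proportions = NULL, nested_fraction = 0.3,
                       n_sentences = 2000L, mean_words = 6,
                       entity_share = 0.35, zipf_exponent = 0.7,
                       seed = 1L) {
  if (is.null(category_proportions)) {
    base <- if (n_categories == 6L) DEFAULT_CATEGORY_COUNTS else {
      stats::setNames((seq_len(n_categories))^-1,
                      paste0("CAT", seq_len(n_categories)))
    }
    category_proportions <- base / sum(base)
  }
  if (length(category_proportions) != n_categories) {
    stop("category_proportions must have length n_categories")
  }
  if (abs(sum(category_proportions) - 1) > 1e-8) {
    stop("category_proportions must sum to 1")
  }
  if (is.null(names(category_proportions))) {
    names(category_proportions) <- paste0("CAT", seq_len(n_categories))
  }
  stopifnot(alphabet_size >= 10, nested_fraction >= 0, nested_fraction <= 1,
            n_sentences >= 1, mean_words >= 1,
            entity_share > 0, entity_share < 1)
  structure(list(alphabet_size = as.integer(alphabet_size),
                 n_common_words = as.integer(n_common_words),
                 n_domain_words = as.integer(n_domain_words),
                 n_categories = as.integer(n_categories),
                 category_proportions = category_proportions,
                 nested_fraction = nested_fraction,
                 n_sentences = as.integer(n_sentences),
                 mean_words = mean_words, entity_share = entity_share,
                 zipf_exponent = zipf_exponent, seed = as.integer(seed)),
            class = "synth_spec")
}

synth_alphabet <- function(n) {
  vapply(0xE000 + seq_len(n) - 1L, intToUtf8, "")
}

#' Generate the synthetic vocabulary and entity dictionary
#'
#' Draws a common (non-entity) vocabulary and a domain (entity)
#' vocabulary of multi-character pseudo-words, assigns each domain word a
#' category according to the spec's proportions, and makes exactly
#' `round(nested_fraction * n_domain_words)` domain words contain a
#' shorter vocabulary word as a proper substring.  Deterministic given
#' the spec's seed.
#'
#' @param spec a [synth_spec()].
#' @return A list of class `synth_world`: `alphabet`, `common` (data.frame
#'   word/weight), `domain` (data.frame word/category/weight/nested).
#' @export
generate_world <- function(spec) {
  n_total <- spec$n_common_words + spec$n_domain_words
  if (n_total > 0.25 * spec$alphabet_size^2) {
    stop("vocabulary too large for the requested alphabet")
  }
  with_seed(spec$seed, {
    ab <- synth_alphabet(spec$alphabet_size)
    seen <- new.env(hash = TRUE, parent = emptyenv())
    draw_word <- function(len) {
      repeat {
        w <- paste(sample(ab, len, replace = TRUE), collapse = "")
        if (is.null(seen[[w]])) { assign(w, TRUE, envir = seen); return(w) }
      }
    }
    common <- vapply(sample(2:4, spec$n_common_words, replace = TRUE,
                            prob = c(0.6, 0.25, 0.15)),
                     draw_word, "")
    n_nested <- round(spec$nested_fraction * spec$n_domain_words)
    lens <- sample(2:4, spec$n_domain_words, replace = TRUE,
                   prob = c(0.45, 0.35, 0.2))
    # nested words need room for a proper substring of length >= 2
    lens[seq_len(n_nested)] <- pmax(lens[seq_len(n_nested)], 3L)
    domain <- character(spec$n_domain_words)
    nested <- logical(spec$n_domain_words)
    for (k in seq_len(spec$n_domain_words)) {
      if (k <= n_nested) {
        repeat {
          inner <- sample(common[nchar(common) <= lens[k] - 1L], 1L)
          pad_n <- lens[k] - nchar(inner)
          pad <- sample(ab, pad_n, replace = TRUE)
          at_front <- stats::runif(1) < 0.5
          w <- if (at_front) {
            paste0(paste(pad, collapse = ""), inner)
          } else {
            paste0(inner, paste(pad, collapse = ""))
          }
          if (is.null(seen[[w]])) {
            assign(w, TRUE, envir = seen)
            domain[k] <- w; nested[k] <- TRUE
            break
          }
        }
      } else {
        domain[k] <- draw_word(lens[k])
      }
    }
    cats <- sample(names(spec$category_proportions), spec$n_domain_words,
                   replace = TRUE, prob = spec$category_proportions)
    zipf <- function(n) (seq_len(n))^(-spec$zipf_exponent)
    structure(list(alphabet = ab,
                   common = data.frame(word = common,
                                       weight = zipf(spec$n_common_words),
                                       stringsAsFactors = FALSE),
                   domain = data.frame(word = domain, category = cats,
                                       weight = zipf(spec$n_domain_words),
                                       nested = nested,
                                       stringsAsFactors = FALSE)),
              class = "synth_world")
  })
}

#' Generate synthetic corpora from a world
#'
#' Assembles sentences by concatenating sampled vocabulary words; every
#' sampled entity word becomes a gold entity span of its category.
#' Returns the raw text, the tagged corpus, and the gold lexicon whose
#' frequencies are the true token counts of every multi-character word.
#'
#' @param world a [generate_world()] result.
#' @param spec the same [synth_spec()] used for the world.
#' @return A list of class `synth_corpora`: `raw` (character vector),
#'   `tagged` (list of [tagged_sentence()]), `lexicon` (gold
#'   [lexicon()]), `boundaries` (list of word-token vectors).
#' @export
generate_corpora <- function(world, spec) {
  with_seed(spec$seed + 1L, {
    n <- spec$n_sentences
    raw <- character(n)
    tagged <- vector("list", n)
    boundaries <- vector("list", n)
    counts <- new.env(hash = TRUE, parent = emptyenv())
    for (s in seq_len(n)) {
      k <- 1L + stats::rpois(1L, spec$mean_words - 1)
      is_ent <- stats::runif(k) < spec$entity_share
      words <- character(k); cats <- character(k)
      n_ent <- sum(is_ent)
      if (n_ent) {
        idx <- sample.int(nrow(world$domain), n_ent, replace = TRUE,
                          prob = world$domain$weight)
        words[is_ent] <- world$domain$word[idx]
        cats[is_ent] <- world$domain$category[idx]
      }
      if (k - n_ent) {
        idx <- sample.int(nrow(world$common), k - n_ent, replace = TRUE,
                          prob = world$common$weight)
        words[!is_ent] <- world$common$word[idx]
      }
      lens <- nchar(words)
      ends <- cumsum(lens)
      starts0 <- ends - lens               # 0-based starts
      spans <- data.frame(start = starts0[is_ent], end = ends[is_ent],
                          category = cats[is_ent], stringsAsFactors = FALSE)
      sent <- paste(words, collapse = "")
      raw[s] <- sent
      tagged[[s]] <- tagged_sentence(sent, spans_to_tags(spans, sum(lens)))
      boundaries[[s]] <- words
      for (w in words[lens >= 2L]) {
        prev <- counts[[w]]
        assign(w, if (is.null(prev)) 1L else prev + 1L, envir = counts)
      }
    }
    lex_words <- ls(counts)
    lex <- lexicon(lex_words,
                   vapply(lex_words, function(w) counts[[w]], 0L))
    structure(list(raw = raw, tagged = tagged, lexicon = lex,
                   boundaries = boundaries),
              class = "synth_corpora")
  })
}
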