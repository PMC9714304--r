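# Entity-level evaluation: strict span matching (exact boundaries and
# category), micro-averaged overall plus per-category breakdown.

#' Harmonic-mean F1 from precision and recall
#'
#' `F1 = 2PR / (P + R)` on the percent scale; returns 0 (not an error)
#' when `P + R` is 0.
#'
#' @param p precision in percent.
#' @param r recall in percent.
#' @return F1 in percent.
#' @export
prf_f1 <- function(p, r) ifelse(p + r > 0, 2 * p * r / (p + r), 0)

safe_pct <- function(num, den) if (den > 0) 100 * num / den else 0

#' Entity-level precision, recall and F1
#'
#' Compares predicted and gold tag sequences at the entity level: a
#' predicted entity counts as a true positive iff its (start, end,
#' category) triple matches a gold entity exactly.  Overall scores are
#' micro-averaged over all sentences; per-category scores restrict both
#' sides to one category.  Zero denominators yield 0 with `defined =
#' FALSE` rather than an error.
#'
#' @param gold list of [tagged_sentence()] (reference).
#' @param pred list of [tagged_sentence()] (predictions), aligned with
#'   `gold`.
#' @return Object of class `prf_report`: list with `tp`, `fp`, `fn`,
#'   `p`, `r`, `f1`, `defined`, and `per_category` (a data.frame).
#' @export
entity_prf <- function(gold, pred) {
  if (length(gold) != length(pred)) {
    stop("gold and pred have different numbers of sentences (",
         length(gold), " vs ", length(pred), ")")
  }
  span_key <- function(sp, k) {
    if (!nrow(sp)) return(character())
    paste(k, sp$start, sp$end, sp$category, sep = ":")
  }
  g_keys <- character(); p_keys <- character()
  g_cat <- character(); p_cat <- character()
  for (k in seq_along(gold)) {
    ng <- length(gold[[k]]$tags); np <- length(pred[[k]]$tags)
    if (ng != np) {
      stop("sentence ", k, ": gold has ", ng, " characters but prediction has ",
           np)
    }
    gs <- tags_to_spans(gold[[k]]$tags)
    ps <- tags_to_spans(pred[[k]]$tags)
    g_keys <- c(g_keys, span_key(gs, k)); g_cat <- c(g_cat, gs$category)
    p_keys <- c(p_keys, span_key(ps, k)); p_cat <- c(p_cat, ps$category)
  }
  hit <- p_keys %in% g_keys
  tp <- sum(hit); fp <- sum(!hit); fn <- sum(!(g_keys %in% p_keys))
  p <- safe_pct(tp, tp + fp); r <- safe_pct(tp, tp + fn)

  cats <- sort(unique(c(g_cat, p_cat)))
  per <- do.call(rbind, lapply(cats, function(cc) {
    tpk <- sum(hit & p_cat == cc)
    fpk <- sum(!hit & p_cat == cc)
    fnk <- sum(!(g_keys[g_cat == cc] %in% p_keys))
    pk <- safe_pct(tpk, tpk + fpk); rk <- safe_pct(tpk, tpk + fnk)
    data.frame(category = cc, tp = tpk, fp = fpk, fn = fnk,
               p = pk, r = rk, f1 = prf_f1(pk, rk),
               stringsAsFactors = FALSE)
  }))
  if (is.null(per)) {
    per <- data.frame(category = character(), tp = integer(), fp = integer(),
                      fn = integer(), p = numeric(), r = numeric(),
                      f1 = numeric(), stringsAsFactors = FALSE)
  }
  structure(list(tp = tp, fp = fp, fn = fn, p = p, r = r, f1 = prf_f1(p, r),
                 defined = (tp + fp > 0) && (tp + fn > 0),
                 per_category = per),
            class = "prf_report")
}

#' @export
print.prf_report <- function(x, digits = 2, ...) {
  cat(sprintf("Entity-level scores (micro): P %.2f  R %.2f  F1 %.2f\n",
              round(x$p, digits), round(x$r, digits), round(x$f1, digits)))
  cat(sprintf("  TP %d  FP %d  FN %d\n", x$tp, x$fp, x$fn))
  if (nrow(x$per_category)) {
    per <- x$per_category
    per$p <- round(per$p, digits); per$r <- round(per$r, digits)
    per$f1 <- round(per$f1, digits)
    print(per, row.names = FALSE)
  }
  invisible(x)
}

#' Write an evaluation report as JSON
#'
#' @param report a [entity_prf()] result.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_prf_json <- function(report, path) {
  per <- report$per_category
  per_list <- stats::setNames(lapply(seq_len(nrow(per)), function(i) {
    list(tp = per$tp[i], fp = per$fp[i], fn = per$fn[i],
         p = round(per$p[i], 2), r = round(per$r[i], 2),
         f1 = round(per$f1[i], 2))
  }), per$category)
  jsonlite::write_json(
    list(overall = list(tp = report$tp, fp = report$fp, fn = report$fn,
                        p = round(report$p, 2), r = round(report$r, 2),
                        f1 = round(report$f1, 2)),
         per_category = per_list),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
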