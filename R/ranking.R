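# Termhood scoring: C-value, the C1 context-counting variant, and the
# NC-value re-ranking over shared one-word contexts.
#
# For a candidate p with total frequency freq(p) (standalone + nested),
# super-phrase set LP and context-type count r:
#
#   C(p) = l(p) * freq(p)                        if r = 0
#   C(p) = l(p) * (freq(p) - (1/r) * sum_{lp in LP} freq(lp))   otherwise
#
# with l(p) = log2(length(p)) for length >= 2 and a small constant
# (default 0.1) for single words. A nested-only candidate with at most one
# context type is scored 0 (it is taken to be an incomplete fragment).
# The three context-counting schemes differ only in r:
#   original      - number of distinct super phrases;
#   grouped_words - distinct adjacent words from both sides pooled;
#   max_separate  - max of distinct left words and distinct right words
#                   (this is the C1 variant; empty-side markers never count).

#' Length weight l(p)
#'
#' `log2(length)` for phrases of two or more tokens; a positive constant
#' (default 0.1) for single words, which keeps one-word candidates on the
#' list without letting them crowd out multiword terms.
#'
#' @param length_tokens integer vector of phrase token lengths (>= 1).
#' @param unigram_l weight used for length-1 phrases.
#' @return numeric vector.
#' @export
length_weight <- function(length_tokens, unigram_l = 0.1) {
  stopifnot(unigram_l > 0)
  if (any(length_tokens < 1L)) stop("phrase length must be >= 1", call. = FALSE)
  ifelse(length_tokens == 1L, unigram_l, log2(length_tokens))
}

#' Number of distinct context types of a nested candidate
#'
#' @param record a term record from a [build_inventory()] inventory.
#' @param scheme `"original"` (distinct super phrases), `"grouped_words"`
#'   (distinct adjacent words, both sides pooled) or `"max_separate"` (the
#'   C1 scheme: maximum over the two sides counted separately).
#' @return integer; 0 for a candidate that never occurs nested.
#' @export
context_type_count <- function(record,
                               scheme = c("max_separate", "original",
                                          "grouped_words")) {
  scheme <- match.arg(scheme)
  switch(scheme,
    original = length(record$super),
    grouped_words = length(unique(c(record$left[nzchar(record$left)],
                                    record$right[nzchar(record$right)]))),
    max_separate = max(length(unique(record$left[nzchar(record$left)])),
                       length(unique(record$right[nzchar(record$right)])))
  )
}

#' C-value of one term record
#'
#' @inheritParams context_type_count
#' @param unigram_l length weight for single words (see [length_weight()]).
#' @param zero_rule score a candidate 0 when it never occurs standalone and
#'   has at most one context type (default TRUE).
#' @return numeric score. Using `scheme = "max_separate"` gives the C1
#'   variant.
#' @export
c_value <- function(record, scheme = c("max_separate", "original",
                                       "grouped_words"),
                    unigram_l = 0.1, zero_rule = TRUE) {
  scheme <- match.arg(scheme)
  l <- length_weight(record$length, unigram_l)
  freq <- record$freq_standalone + record$freq_nested
  r <- context_type_count(record, scheme)
  if (zero_rule && record$freq_standalone == 0L && r <= 1L) return(0)
  if (r == 0L) return(l * freq)
  l * (freq - sum(record$super) / r)
}

#' Score every term of an inventory
#'
#' Computes the original-scheme C-value and the C1 variant for all records.
#'
#' @param inventory a `clt_inventory`.
#' @inheritParams c_value
#' @return data.frame with columns `form`, `length`, `freq_standalone`,
#'   `freq_nested`, `freq`, `c_value`, `c1_value`.
#' @export
score_inventory <- function(inventory, unigram_l = 0.1, zero_rule = TRUE) {
  recs <- inventory$records
  df <- as.data.frame(inventory)
  df$freq <- df$freq_standalone + df$freq_nested
  df$c_value <- vapply(recs, c_value, 0, scheme = "original",
                       unigram_l = unigram_l, zero_rule = zero_rule)
  df$c1_value <- vapply(recs, c_value, 0, scheme = "max_separate",
                        unigram_l = unigram_l, zero_rule = zero_rule)
  rownames(df) <- NULL
  df
}

.clt_default_context_pos <- c("subst", "ger", "adj", "ppas",
                              "fin", "praet", "inf", "verb")

.clt_ext_context_lemmas <- function(record, context_pos) {
  ctx <- c(record$ext_left, record$ext_right)
  ctx <- ctx[!is.na(ctx)]
  if (!length(ctx)) return(character())
  pos <- sub(":.*$", "", ctx)
  lem <- sub("^[^:]*:", "", ctx)
  lem[pos %in% context_pos]
}

#' NC-value re-ranking
#'
#' Builds the context model from the one-word sentence contexts (restricted
#' to nouns, adjectives and verbs; punctuation and other classes are
#' ignored) of the occurrences of the `top_k` highest-scoring terms, then
#' scores every term as
#' `NC(t) = alpha * C(t) + beta * sum_b f_t(b) * weight(b)` with
#' `weight(b) = t(b) / n`, where `t(b)` is the number of top terms the
#' context word `b` occurs with and `n` the number of top terms considered.
#'
#' @param scores data.frame from [score_inventory()].
#' @param inventory the inventory the scores were computed from.
#' @param base name of the score column the ranking and the NC formula use
#'   (default `"c1_value"`).
#' @param top_k number of leading terms whose contexts define the model
#'   (default 300); if larger than the term list, all terms are used with a
#'   warning.
#' @param alpha,beta weights of the two components (defaults 0.8 / 0.2).
#' @param context_pos word classes admitted as context words.
#' @return `scores` with an `nc_value` column added.
#' @export
nc_value <- function(scores, inventory, base = "c1_value", top_k = 300L,
                     alpha = 0.8, beta = 0.2,
                     context_pos = .clt_default_context_pos) {
  if (!base %in% names(scores)) {
    stop(sprintf("unknown score column '%s'", base), call. = FALSE)
  }
  recs <- inventory$records[scores$form]
  if (top_k > nrow(scores)) {
    warning(sprintf("top_k = %d exceeds the %d available terms; using all",
                    top_k, nrow(scores)))
    top_k <- nrow(scores)
  }
  ord <- order(-scores[[base]], -(scores$freq_standalone + scores$freq_nested),
               scores$form)
  top <- ord[seq_len(top_k)]
  n <- length(top)
  tb <- new.env(parent = emptyenv())      # context word -> t(b)
  for (i in top) {
    for (b in unique(.clt_ext_context_lemmas(recs[[i]], context_pos))) {
      tb[[b]] <- (if (is.null(tb[[b]])) 0L else tb[[b]]) + 1L
    }
  }
  scores$nc_value <- vapply(seq_len(nrow(scores)), function(i) {
    ctx <- .clt_ext_context_lemmas(recs[[i]], context_pos)
    s <- 0
    if (length(ctx)) {
      ft <- table(ctx)
      for (b in names(ft)) {
        w <- tb[[b]]
        if (!is.null(w)) s <- s + as.integer(ft[[b]]) * (w / n)
      }
    }
    alpha * scores[[base]][[i]] + beta * s
  }, 0)
  scores
}

#' Order terms and apply a cut-off
#'
#' Stable ordering by the chosen score (descending), ties broken by total
#' frequency (descending) and then by form; ranks are contiguous from 1.
#'
#' @param scores scored data.frame.
#' @param by score column to rank by (e.g. `"nc_value"`, `"c1_value"`).
#' @param cutoff_rank keep only the first `cutoff_rank` rows (optional).
#' @param cutoff_score keep only rows with score >= `cutoff_score`
#'   (optional; applied after ranking).
#' @return the data.frame re-ordered, with a `rank` column.
#' @export
rank_terms <- function(scores, by = "nc_value", cutoff_rank = NULL,
                       cutoff_score = NULL) {
  if (!by %in% names(scores)) {
    stop(sprintf("unknown score column '%s'", by), call. = FALSE)
  }
  freq <- scores$freq_standalone + scores$freq_nested
  out <- scores[order(-scores[[by]], -freq, scores$form), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  if (!is.null(cutoff_score)) out <- out[out[[by]] >= cutoff_score, , drop = FALSE]
  if (!is.null(cutoff_rank)) out <- utils::head(out, cutoff_rank)
  rownames(out) <- NULL
  out
}

#' Score distribution bands
#'
#' Summarises a score column into the bands used to describe C-value
#' distributions: `C = 0`, `0 < C < 1`, `C = 1`, `1 < C <= 2.5`, `C > 2.5`.
#'
#' @param scores scored data.frame.
#' @param column score column name.
#' @return data.frame with `band` and `n`; the bands partition the list.
#' @export
score_bands <- function(scores, column = "c1_value") {
  x <- scores[[column]]
  data.frame(
    band = c("C=0", "0<C<1", "C=1", "1<C<=2.5", "C>2.5"),
    n = c(sum(x == 0), sum(x > 0 & x < 1), sum(x == 1),
          sum(x > 1 & x <= 2.5), sum(x > 2.5)),
    stringsAsFactors = FALSE
  )
}

#' Export / import a ranked term list as TSV
#'
#' Scores are printed with two decimals; the in-memory objects keep full
#' precision.
#'
#' @param ranked data.frame from [rank_terms()].
#' @param path TSV file path.
#' @export
write_ranked <- function(ranked, path) {
  out <- ranked
  for (col in intersect(c("c_value", "c1_value", "nc_value"), names(out))) {
    out[[col]] <- sprintf("%.2f", out[[col]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_ranked
#' @export
read_ranked <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                    fileEncoding = "UTF-8")
}
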