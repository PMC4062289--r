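# Matching extracted terms against a controlled vocabulary (e.g. a MeSH
# translation): exact form, containment in a longer entry, and approximate
# per-word matching after suffix stripping with a position-weighted edit
# distance (differences near the end of a word - where inflection lives -
# cost less than differences near the beginning).

#' Default inflectional-suffix table
#'
#' @return character vector of strippable endings, from the shipped table of
#'   Polish noun/adjective case endings.
#' @export
default_suffixes <- function() {
  path <- system.file("extdata", "pl_case_suffixes.txt", package = "clinterm")
  .clt_read_lemma_list(path)
}

#' Strip one inflectional suffix from a word
#'
#' Removes the longest listed suffix whose removal leaves at least
#' `min_stem` characters; words with no such suffix are returned unchanged.
#'
#' @param word character vector.
#' @param suffixes suffix table (default [default_suffixes()]).
#' @param min_stem minimum stem length (default 3).
#' @return character vector of stems.
#' @export
#' @examples
#' stem_word("grypy")   # "gryp"
stem_word <- function(word, suffixes = default_suffixes(), min_stem = 3L) {
  suffixes <- suffixes[order(-nchar(suffixes))]
  vapply(word, function(w) {
    nw <- nchar(w)
    for (suf in suffixes) {
      ns <- nchar(suf)
      if (nw - ns >= min_stem && endsWith(w, suf)) {
        return(substr(w, 1L, nw - ns))
      }
    }
    w
  }, "", USE.NAMES = FALSE)
}

.clt_pos_weight <- function(i, L) 1 - (i - 1) / (2 * L)

#' Position-weighted edit similarity of two words
#'
#' Weighted Levenshtein distance in which an edit at alignment position
#' `i` (1-based over the longer word, length `L`) costs
#' `1 - (i - 1) / (2 L)`, so an edit at the last position costs about half
#' an edit at the first; similarity is `1 - d / d_max` with `d_max` the
#' weighted cost of editing every position. Two words differing only near
#' the end (typically by inflection residue) therefore score higher than
#' words differing at the start.
#'
#' @param a,b non-empty strings.
#' @param weight_fn positional cost factor, a function of the position `i`
#'   and the length `L` of the longer word; must be positive and
#'   non-increasing in `i`.
#' @return similarity in `[0, 1]`; 1 iff the words are identical.
#' @export
positional_edit_similarity <- function(a, b, weight_fn = .clt_pos_weight) {
  if (!nzchar(a) || !nzchar(b)) stop("words must be non-empty", call. = FALSE)
  ca <- strsplit(a, "")[[1L]]
  cb <- strsplit(b, "")[[1L]]
  la <- length(ca)
  lb <- length(cb)
  L <- max(la, lb)
  w <- weight_fn(seq_len(L), L)
  d <- matrix(0, la + 1L, lb + 1L)
  for (i in seq_len(la)) d[i + 1L, 1L] <- d[i, 1L] + w[[i]]
  for (j in seq_len(lb)) d[1L, j + 1L] <- d[1L, j] + w[[j]]
  for (i in seq_len(la)) {
    for (j in seq_len(lb)) {
      cw <- w[[max(i, j)]]
      sub_cost <- if (ca[[i]] == cb[[j]]) 0 else cw
      d[i + 1L, j + 1L] <- min(d[i, j] + sub_cost,
                               d[i, j + 1L] + cw,
                               d[i + 1L, j] + cw)
    }
  }
  1 - d[la + 1L, lb + 1L] / sum(w)
}

#' Read a thesaurus file
#'
#' Plain text, one entry per line; the main term and its synonyms are
#' separated by `|`, words within a term by spaces. Stems are precomputed
#' for the approximate tier.
#'
#' @param path file path.
#' @param suffixes,min_stem stemming parameters (see [stem_word()]).
#' @return list of entries of class `clt_thesaurus`; each entry has `term`,
#'   `synonyms` (list of word vectors) and `stems` (stem vectors, main term
#'   first).
#' @export
read_thesaurus <- function(path, suffixes = default_suffixes(),
                           min_stem = 3L) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop(sprintf("%s: empty thesaurus", path), call. = FALSE)
  entries <- lapply(lines, function(ln) {
    variants <- strsplit(tolower(ln), "|", fixed = TRUE)[[1L]]
    words <- lapply(variants, function(v)
      strsplit(trimws(v), "\\s+")[[1L]])
    words <- Filter(length, words)
    list(term = words[[1L]],
         synonyms = words[-1L],
         stems = lapply(words, stem_word, suffixes = suffixes,
                        min_stem = min_stem))
  })
  structure(entries, class = "clt_thesaurus")
}

.clt_is_subseq <- function(x, y) {
  # contiguous subsequence test, x strictly shorter than y
  lx <- length(x)
  ly <- length(y)
  if (lx >= ly) return(FALSE)
  for (s in seq_len(ly - lx + 1L)) {
    if (identical(y[s:(s + lx - 1L)], x)) return(TRUE)
  }
  FALSE
}

#' Match one term against the thesaurus
#'
#' Tiers are tried in order and the first success wins:
#' \describe{
#'   \item{exact}{the term's word sequence equals an entry or synonym; the
#'     exact tier is also tried on any caller-supplied grammatical forms,
#'     which recovers gerund-headed terms whose lemmas differ strongly from
#'     the vocabulary's nominal forms;}
#'   \item{nested_in_entry}{the sequence occurs contiguously inside a longer
#'     entry;}
#'   \item{approximate}{some entry contains, for every term word, a word
#'     whose stem-level positional similarity reaches `threshold`;}
#'   \item{none}{otherwise.}
#' }
#'
#' @param words the term as a word vector (its simplified base form), or a
#'   space-separated string.
#' @param thesaurus a `clt_thesaurus`.
#' @param threshold approximate-tier similarity threshold (default 0.8).
#' @param suffixes,min_stem stemming parameters; must match those used to
#'   load the thesaurus.
#' @param grammatical_forms optional list of additional word vectors (e.g.
#'   reconstructed grammatical phrases) tried in the exact and nested tiers.
#' @return list of class `clt_match`: `tier`, `entry` (matched entry's main
#'   term as a string, or NA), `word_sims` (per-term-word best stem
#'   similarity for the approximate tier, else NULL).
#' @export
match_term <- function(words, thesaurus, threshold = 0.8,
                       suffixes = default_suffixes(), min_stem = 3L,
                       grammatical_forms = NULL) {
  if (!length(thesaurus)) stop("empty thesaurus", call. = FALSE)
  if (is.character(words) && length(words) == 1L && grepl(" ", words)) {
    words <- strsplit(words, " ", fixed = TRUE)[[1L]]
  }
  words <- tolower(words)
  forms <- c(list(words), lapply(grammatical_forms, tolower))
  res <- function(tier, entry = NA_character_, word_sims = NULL) {
    structure(list(tier = tier, entry = entry, word_sims = word_sims),
              class = "clt_match")
  }
  for (e in thesaurus) {
    for (v in c(list(e$term), e$synonyms)) {
      for (f in forms) {
        if (identical(f, v)) {
          return(res("exact", paste(e$term, collapse = " ")))
        }
      }
    }
  }
  for (e in thesaurus) {
    for (v in c(list(e$term), e$synonyms)) {
      for (f in forms) {
        if (.clt_is_subseq(f, v)) {
          return(res("nested_in_entry", paste(e$term, collapse = " ")))
        }
      }
    }
  }
  stems <- stem_word(words, suffixes = suffixes, min_stem = min_stem)
  for (e in thesaurus) {
    for (v_stems in e$stems) {
      sims <- vapply(stems, function(st)
        max(vapply(v_stems, positional_edit_similarity, 0, a = st)), 0)
      if (all(sims >= threshold)) {
        return(res("approximate", paste(e$term, collapse = " "),
                   word_sims = unname(sims)))
      }
    }
  }
  res("none")
}

#' Match many terms and tabulate the report
#'
#' @param forms character vector of space-separated simplified forms.
#' @inheritParams match_term
#' @return data.frame: `term`, `tier`, `entry`, `min_sim` (minimum per-word
#'   similarity for approximate matches, NA otherwise).
#' @export
match_terms <- function(forms, thesaurus, threshold = 0.8,
                        suffixes = default_suffixes(), min_stem = 3L) {
  rows <- lapply(forms, function(f) {
    m <- match_term(f, thesaurus, threshold = threshold, suffixes = suffixes,
                    min_stem = min_stem)
    data.frame(term = f, tier = m$tier,
               entry = m$entry,
               min_sim = if (is.null(m$word_sims)) NA_real_
                         else min(m$word_sims),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
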