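# Reading, writing and normalising vertically tagged corpora.
#
# A corpus is a list of sentences; a sentence is a data.frame with one row
# per token and columns:
#   surface  - token as written
#   lemma    - base form (lower-cased on read)
#   tag      - raw colon-joined morphosyntactic tag, kept verbatim
#   pos      - word class (first tag part): subst, ger, adj, ppas, adja,
#              adv, brev, foreign, foreign_subst, conj, prep, qub, interp,
#              num, ...
#   case, gender, number - agreement features parsed out of the tag
#                          (NA for non-inflecting classes)
#   is_special - single special-character token (interp)
#   line     - source line number, for diagnostics

.clt_cases   <- c("nom", "gen", "dat", "acc", "inst", "loc", "voc")
.clt_numbers <- c("sg", "pl")
.clt_genders <- c("m", "m1", "m2", "m3", "f", "n")

.clt_pick <- function(parts, values) {
  hit <- parts[parts %in% values]
  if (length(hit)) hit[[1L]] else NA_character_
}

#' Parse a colon-joined morphosyntactic tag
#'
#' Splits a tag such as `"subst:nom:m:sg"` into its word class and the
#' agreement triple (case, gender, number). Feature values are recognised by
#' membership, not position, so unknown or extra tag parts are preserved in
#' the raw tag but ignored here.
#'
#' @param tag character vector of colon-joined tags.
#' @return data.frame with columns `pos`, `case`, `gender`, `number`.
#' @export
parse_tag <- function(tag) {
  parts <- strsplit(tag, ":", fixed = TRUE)
  data.frame(
    pos    = vapply(parts, function(p) if (length(p)) p[[1L]] else NA_character_, ""),
    case   = vapply(parts, .clt_pick, "", values = .clt_cases),
    gender = vapply(parts, .clt_pick, "", values = .clt_genders),
    number = vapply(parts, .clt_pick, "", values = .clt_numbers),
    stringsAsFactors = FALSE
  )
}

.clt_sentence <- function(surface, lemma, tag, line = NA_integer_) {
  feats <- parse_tag(tag)
  out <- data.frame(
    surface = surface,
    lemma   = tolower(lemma),
    tag     = tag,
    pos     = feats$pos,
    case    = feats$case,
    gender  = feats$gender,
    number  = feats$number,
    is_special = feats$pos == "interp" & nchar(surface) == 1L,
    line    = line,
    stringsAsFactors = FALSE
  )
  class(out) <- c("clt_sentence", "data.frame")
  out
}

#' Build one tagged sentence from parallel vectors
#'
#' Convenience constructor used by tests and the fixture generator.
#'
#' @param surface,lemma,tag character vectors of equal length.
#' @return a sentence data.frame (see [read_vertical()]).
#' @export
#' @examples
#' tagged_sentence(c("ostry", "dyzur"), c("ostry", "dyzur"),
#'                 c("adj:nom:m:sg", "subst:nom:m:sg"))
tagged_sentence <- function(surface, lemma, tag) {
  stopifnot(length(surface) == length(lemma), length(lemma) == length(tag))
  .clt_sentence(surface, lemma, tag)
}

#' Read a vertical (one token per line) tagged corpus
#'
#' The format is tab-separated `surface<TAB>lemma<TAB>tag`, UTF-8, with a
#' blank line closing each sentence. Lemmas are lower-cased on read (term
#' identity is lemma-sequence based); surfaces and raw tags are preserved.
#'
#' @param path path to the corpus file.
#' @return list of sentences, class `clt_corpus`. An empty file yields an
#'   empty corpus.
#' @export
read_vertical <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  sentences <- list()
  buf <- list()
  flush <- function() {
    if (!length(buf)) return(invisible())
    sentences[[length(sentences) + 1L]] <<- .clt_sentence(
      vapply(buf, `[[`, "", 1L),
      vapply(buf, `[[`, "", 2L),
      vapply(buf, `[[`, "", 3L),
      vapply(buf, function(b) b[[4L]], 0L)
    )
    buf <<- list()
  }
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(trimws(ln))) { flush(); next }
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(fields) != 3L) {
      stop(sprintf("%s: line %d: expected 3 tab-separated fields, got %d",
                   path, i, length(fields)), call. = FALSE)
    }
    buf[[length(buf) + 1L]] <- list(fields[[1L]], fields[[2L]], fields[[3L]], i)
  }
  flush()
  structure(sentences, class = "clt_corpus")
}

#' Write a corpus in the vertical format
#'
#' Inverse of [read_vertical()]: writes `surface<TAB>lemma<TAB>tag` lines with
#' a blank line after every sentence. Raw tags are written verbatim, so a
#' well-formed file (with lower-case lemmas) round-trips byte-identically.
#'
#' @param corpus list of sentences.
#' @param path output file path.
#' @export
write_vertical <- function(corpus, path) {
  blocks <- vapply(corpus, function(s) {
    paste(paste(s$surface, s$lemma, s$tag, sep = "\t"), collapse = "\n")
  }, "")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(blocks, collapse = "\n\n"), con, useBytes = TRUE)
  invisible(path)
}

#' Segment plain text into word, number and special-character tokens
#'
#' Words and numbers are maximal runs; words may contain digits but never
#' start with one, so `"12mm"` splits into a number and a word while `"B12"`
#' stays one word. Every other non-space character becomes a single
#' special-character token.
#'
#' @param text a character scalar.
#' @return data.frame with columns `surface` and `class`
#'   (`word` / `number` / `special`).
#' @export
#' @examples
#' tokenize_plain("12mm")$surface   # "12" "mm"
#' tokenize_plain("B12")$surface    # "B12"
tokenize_plain <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  m <- gregexpr("\\p{L}[\\p{L}\\p{N}]*|\\p{N}+|\\S", text, perl = TRUE)[[1L]]
  toks <- if (m[[1L]] == -1L) character() else regmatches(text, list(m))[[1L]]
  cls <- ifelse(grepl("^\\p{N}+$", toks, perl = TRUE), "number",
         ifelse(grepl("^\\p{L}", toks, perl = TRUE), "word", "special"))
  data.frame(surface = toks, class = cls, stringsAsFactors = FALSE)
}

#' Read context-free token correction rules
#'
#' A YAML list of rules, each with a `match` map (any of `surface`, `lemma`,
#' `pos`, `tag`) and a `set` map (any of `lemma`, `tag`, `pos`). Rules apply
#' to single tokens regardless of their neighbours; file order is kept.
#'
#' @param path YAML file path.
#' @return list of rules, class `clt_corrections`.
#' @export
read_correction_rules <- function(path) {
  rules <- yaml::read_yaml(path)
  if (is.null(rules)) rules <- list()
  for (i in seq_along(rules)) {
    r <- rules[[i]]
    if (is.null(r$match) || is.null(r$set)) {
      stop(sprintf("%s: rule %d must have 'match' and 'set' entries", path, i),
           call. = FALSE)
    }
    bad <- setdiff(names(r$match), c("surface", "lemma", "pos", "tag"))
    if (length(bad)) {
      stop(sprintf("%s: rule %d: unknown match field(s): %s",
                   path, i, paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  structure(rules, class = "clt_corrections")
}

.clt_token_matches <- function(sent, i, match) {
  for (f in names(match)) {
    if (!identical(sent[[f]][[i]], match[[f]])) return(FALSE)
  }
  TRUE
}

#' Apply global correction rules to every token
#'
#' Each token is rewritten by the first matching rule only (rule order is the
#' file order). Token count and sentence segmentation never change.
#'
#' @param corpus list of sentences.
#' @param rules list of rules from [read_correction_rules()] (or built
#'   in code with the same shape).
#' @return the corrected corpus; the number of applications per rule is
#'   attached as attribute `"applied"`.
#' @export
apply_corrections <- function(corpus, rules) {
  applied <- integer(length(rules))
  out <- lapply(corpus, function(sent) {
    for (i in seq_len(nrow(sent))) {
      for (k in seq_along(rules)) {
        r <- rules[[k]]
        if (.clt_token_matches(sent, i, r$match)) {
          applied[[k]] <<- applied[[k]] + 1L
          if (!is.null(r$set$lemma)) sent$lemma[[i]] <- tolower(r$set$lemma)
          if (!is.null(r$set$tag)) {
            sent$tag[[i]] <- r$set$tag
            feats <- parse_tag(r$set$tag)
            sent$pos[[i]]    <- feats$pos
            sent$case[[i]]   <- feats$case
            sent$gender[[i]] <- feats$gender
            sent$number[[i]] <- feats$number
          } else if (!is.null(r$set$pos)) {
            sent$pos[[i]] <- r$set$pos
            sent$tag[[i]] <- r$set$pos
          }
          break
        }
      }
    }
    sent
  })
  structure(out, class = "clt_corpus", applied = applied)
}

#' Read an abbreviation dictionary
#'
#' Tab-separated file: `abbreviation<TAB>full-form-lemma`. Keys are
#' normalised (lower-cased, trailing period stripped) so `"godz"` and
#' `"godz."` hit the same entry.
#'
#' @param path TSV file path.
#' @return named character vector (normalised abbreviation -> full lemma).
#' @export
read_abbrev_dict <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          quote = "", comment.char = "#",
                          col.names = c("abbrev", "full"),
                          fileEncoding = "UTF-8")
  key <- tolower(sub("\\.$", "", df$abbrev))
  if (anyDuplicated(key)) {
    stop(sprintf("%s: duplicate abbreviation keys: %s", path,
                 paste(unique(key[duplicated(key)]), collapse = ", ")),
         call. = FALSE)
  }
  val <- tolower(df$full)
  if (any(!nzchar(val))) stop(sprintf("%s: empty full form", path), call. = FALSE)
  stats::setNames(val, key)
}

#' Expand abbreviations to their full-form lemmas
#'
#' For every abbreviation token (`pos == "brev"`) whose normalised surface is
#' in the dictionary, the lemma is replaced by the full-form lemma; the
#' surface is left untouched. Different shorthands of the same word thereby
#' collapse to one simplified base form downstream.
#'
#' @param corpus list of sentences.
#' @param dict named character vector from [read_abbrev_dict()].
#' @return the corpus with expanded lemmas.
#' @export
expand_abbreviations <- function(corpus, dict) {
  out <- lapply(corpus, function(sent) {
    idx <- which(sent$pos == "brev")
    for (i in idx) {
      key <- tolower(sub("\\.$", "", sent$surface[[i]]))
      if (!is.na(dict[key])) sent$lemma[[i]] <- unname(dict[key])
    }
    sent
  })
  structure(out, class = "clt_corpus")
}

#' @export
print.clt_corpus <- function(x, ...) {
  n_tok <- sum(vapply(x, nrow, 0L))
  cat(sprintf("<clt_corpus: %d sentence(s), %d token(s)>\n", length(x), n_tok))
  invisible(x)
}
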