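# The cascaded shallow grammar: compilation and sentence parsing.
#
# Parsing works on a flat list of "items". Initially every token is an item;
# each cascade level scans left to right, takes at every position the longest
# match over the level's rules (ties broken by file order), replaces the
# matched items by a single new item carrying the head's case/gender/number,
# and continues after it. After level 6 the X items are the maximal noun
# phrases; everything else (including NZ/AZ stop items) is discarded.

.clt_categories <- c("N", "NC", "AJ", "AC", "CN", "NZ", "AZ",
                     "A", "ADJP", "NB", "NG", "X")
.clt_np_categories <- c("NB", "NG", "X")
.clt_features <- c("case", "gender", "number")

.clt_parse_item <- function(item, rule_id, path) {
  known <- c("tok", "cat", "surface", "lemma", "stop", "opt", "vars",
             "case", "gender", "number")
  bad <- setdiff(names(item), known)
  if (length(bad)) {
    stop(sprintf("%s: rule %s: unknown item key(s): %s",
                 path, rule_id, paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (is.null(item$tok) && is.null(item$cat) && is.null(item$surface)) {
    stop(sprintf("%s: rule %s: item needs one of tok/cat/surface",
                 path, rule_id), call. = FALSE)
  }
  out <- list(
    tok = if (!is.null(item$tok))
      strsplit(strsplit(item$tok, "|", fixed = TRUE)[[1L]], ":", fixed = TRUE),
    cat = if (!is.null(item$cat)) strsplit(item$cat, "|", fixed = TRUE)[[1L]],
    surface = item$surface,
    lemma = item$lemma,
    stop = item$stop,
    opt = isTRUE(item$opt),
    vars = if (!is.null(item$vars)) {
      v <- strsplit(item$vars, ",", fixed = TRUE)[[1L]]
      stats::setNames(trimws(v), .clt_features[seq_along(v)])
    },
    fixed = Filter(Negate(is.null),
                   list(case = item$case, gender = item$gender,
                        number = item$number))
  )
  if (!is.null(out$cat)) {
    unknown <- setdiff(out$cat, .clt_categories)
    if (length(unknown)) {
      stop(sprintf("%s: rule %s: undefined category reference: %s",
                   path, rule_id, paste(unknown, collapse = ", ")),
           call. = FALSE)
    }
  }
  out
}

.clt_strip_features <- function(rule) {
  rule$rhs <- lapply(rule$rhs, function(it) {
    it$vars <- NULL
    it$fixed <- list()
    it
  })
  rule
}

.clt_read_lemma_list <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(sub("#.*", "", lines))
  tolower(lines[nzchar(lines)])
}

#' Compile the cascaded noun-phrase grammar
#'
#' Reads a YAML rule file (the shipped default reproduces the six-level
#' grammar: core nouns/gerunds, foreign and abbreviation words, adjectives
#' with adverbs and hyphenated compounds, adjectival phrases with the
#' conjunction *i*, noun + adjectival-phrase combinations, genitive-modifier
#' chains, and the final phrase level) together with the NZ/AZ stop-lemma
#' lists.
#'
#' @param rule_file YAML grammar file; default is the shipped grammar.
#' @param stop_nz,stop_az plain lemma-per-line stop lists for noun (NZ) and
#'   modifier (AZ) stop items.
#' @param mode `"full"` enforces case/gender/number constraints;
#'   `"simplified"` drops every morphological constraint and matches on word
#'   class alone.
#' @param trailing_nc keep the final-level rule that attaches a trailing
#'   non-inflecting acronym to a phrase. On by default; it can pick up
#'   improperly structured phrases when punctuation is sparse, so it is
#'   switchable.
#' @return a `clt_cascade` object.
#' @export
compile_cascade <- function(rule_file = system.file("extdata", "grammar.yml",
                                                    package = "clinterm"),
                            stop_nz = system.file("extdata", "stop_nz.txt",
                                                  package = "clinterm"),
                            stop_az = system.file("extdata", "stop_az.txt",
                                                  package = "clinterm"),
                            mode = c("full", "simplified"),
                            trailing_nc = TRUE) {
  mode <- match.arg(mode)
  spec <- yaml::read_yaml(rule_file)
  if (is.null(spec$levels) || !length(spec$levels)) {
    stop(sprintf("%s: no 'levels' declared", rule_file), call. = FALSE)
  }
  levels <- vector("list", length(spec$levels))
  for (li in seq_along(spec$levels)) {
    lv <- spec$levels[[li]]
    rules <- list()
    for (ri in seq_along(lv$rules)) {
      r <- lv$rules[[ri]]
      rule_id <- sprintf("level %s #%d (%s)", lv$level, ri,
                         if (is.null(r$lhs)) "?" else r$lhs)
      if (is.null(r$lhs) || !r$lhs %in% .clt_categories) {
        stop(sprintf("%s: rule %s: lhs must be one of the declared categories",
                     rule_file, rule_id), call. = FALSE)
      }
      if (identical(r$flag, "trailing_nc") && !trailing_nc) next
      rhs <- lapply(r$rhs, .clt_parse_item, rule_id = rule_id, path = rule_file)
      vars <- unlist(lapply(rhs, `[[`, "vars"), use.names = FALSE)
      single <- names(table(vars))[table(vars) == 1L]
      if (length(single)) {
        stop(sprintf("%s: rule %s: agreement variable(s) used once: %s",
                     rule_file, rule_id, paste(single, collapse = ", ")),
             call. = FALSE)
      }
      head <- if (is.null(r$head)) 1L else as.integer(r$head)
      if (head < 1L || head > length(rhs)) {
        stop(sprintf("%s: rule %s: head index %d outside RHS",
                     rule_file, rule_id, head), call. = FALSE)
      }
      rule <- list(lhs = r$lhs, rhs = rhs, head = head, id = rule_id)
      if (mode == "simplified") rule <- .clt_strip_features(rule)
      rules[[length(rules) + 1L]] <- rule
    }
    levels[[li]] <- rules
  }
  structure(list(levels = levels,
                 stops = list(nz = .clt_read_lemma_list(stop_nz),
                              az = .clt_read_lemma_list(stop_az)),
                 mode = mode,
                 trailing_nc = trailing_nc),
            class = "clt_cascade")
}

#' @export
print.clt_cascade <- function(x, ...) {
  cat(sprintf("<clt_cascade: %d levels, %s mode, %d NZ / %d AZ stop lemmas>\n",
              length(x$levels), x$mode,
              length(x$stops$nz), length(x$stops$az)))
  invisible(x)
}

# ---- matching ----------------------------------------------------------

.clt_items_init <- function(sentence) {
  lapply(seq_len(nrow(sentence)), function(i) {
    list(cat = NA_character_,
         tag_parts = strsplit(sentence$tag[[i]], ":", fixed = TRUE)[[1L]],
         pos = sentence$pos[[i]],
         lemma = sentence$lemma[[i]],
         surface = sentence$surface[[i]],
         case = sentence$case[[i]], gender = sentence$gender[[i]],
         number = sentence$number[[i]],
         start = i, end = i, kids = NULL)
  })
}

.clt_item_matches <- function(item, spec, stops, bind) {
  if (!is.null(spec$cat)) {
    if (is.na(item$cat) || !(item$cat %in% spec$cat)) return(NULL)
  }
  if (!is.null(spec$tok)) {
    if (!is.na(item$cat)) return(NULL)
    ok <- FALSE
    for (pat in spec$tok) {
      if (pat[[1L]] == item$pos && all(pat %in% item$tag_parts)) { ok <- TRUE; break }
    }
    if (!ok) return(NULL)
  }
  if (!is.null(spec$surface)) {
    if (!is.na(item$cat) || !identical(item$surface, spec$surface)) return(NULL)
  }
  if (!is.null(spec$lemma) && !identical(item$lemma, spec$lemma)) return(NULL)
  if (!is.null(spec$stop) && !(item$lemma %in% stops[[spec$stop]])) return(NULL)
  for (f in names(spec$fixed)) {
    # a fixed value test (e.g. the genitive requirement on complement
    # chains) demands the feature be present and equal; only variable
    # unification below lets a missing feature pass
    v <- item[[f]]
    if (is.na(v) || v != spec$fixed[[f]]) return(NULL)
  }
  for (f in names(spec$vars)) {
    v <- item[[f]]
    if (is.na(v)) next                      # missing feature unifies freely
    var <- spec$vars[[f]]
    if (!is.null(bind[[var]]) && bind[[var]] != v) return(NULL)
    bind[[var]] <- v
  }
  bind
}

# Longest match of `rule` starting at items[[k]]; returns NULL or
# list(n = items consumed, slots = rhs-position -> item index (NA if skipped)).
.clt_match_rule <- function(items, k, rule, stops) {
  n_items <- length(items)
  best <- NULL
  recurse <- function(j, i, bind, slots) {
    if (j > length(rule$rhs)) {
      consumed <- i - k
      if (consumed > 0L && (is.null(best) || consumed > best$n)) {
        best <<- list(n = consumed, slots = slots)
      }
      return(invisible())
    }
    spec <- rule$rhs[[j]]
    if (i <= n_items) {
      nb <- .clt_item_matches(items[[i]], spec, stops, bind)
      if (!is.null(nb)) {
        slots2 <- slots; slots2[[j]] <- i
        recurse(j + 1L, i + 1L, nb, slots2)
      }
    }
    if (spec$opt) recurse(j + 1L, i, bind, slots)
    invisible()
  }
  recurse(1L, k, list(), rep(NA_integer_, length(rule$rhs)))
  best
}

.clt_apply_level <- function(items, rules, stops) {
  out <- list()
  k <- 1L
  n <- length(items)
  while (k <= n) {
    best <- NULL
    best_rule <- NULL
    for (rule in rules) {
      m <- .clt_match_rule(items, k, rule, stops)
      if (!is.null(m) && (is.null(best) || m$n > best$n)) {
        best <- m
        best_rule <- rule
      }
    }
    if (is.null(best)) {
      out[[length(out) + 1L]] <- items[[k]]
      k <- k + 1L
      next
    }
    kids <- items[k:(k + best$n - 1L)]
    head_idx <- best$slots[[best_rule$head]]
    head_item <- if (!is.na(head_idx)) items[[head_idx]] else kids[[1L]]
    out[[length(out) + 1L]] <- list(
      cat = best_rule$lhs,
      tag_parts = character(), pos = NA_character_,
      lemma = head_item$lemma, surface = NA_character_,
      case = head_item$case, gender = head_item$gender,
      number = head_item$number,
      start = kids[[1L]]$start, end = kids[[length(kids)]]$end,
      kids = kids)
    k <- k + best$n
  }
  out
}

#' Parse one sentence into maximal noun phrases
#'
#' Runs the cascade over the sentence and returns the maximal phrases (final
#' X items). Each phrase records its token span (1-based, inclusive), the
#' unified case/gender/number of its head, and its derivation.
#'
#' @param sentence a sentence data.frame.
#' @param cascade a compiled [compile_cascade()] object.
#' @return list of phrases, each a list with `start`, `end`, `category`,
#'   `case`, `gender`, `number` and `kids` (the derivation). Phrases are
#'   pairwise non-overlapping and sorted by start position.
#' @export
#' @examples
#' s <- tagged_sentence(c("ostry", "dyzur"), c("ostry", "dyzur"),
#'                      c("adj:nom:m:sg", "subst:nom:m:sg"))
#' length(parse_sentence(s, compile_cascade()))
parse_sentence <- function(sentence, cascade) {
  stopifnot(inherits(cascade, "clt_cascade"))
  if (!nrow(sentence)) return(list())
  items <- .clt_items_init(sentence)
  for (rules in cascade$levels) {
    items <- .clt_apply_level(items, rules, cascade$stops)
  }
  phrases <- Filter(function(it) identical(it$cat, "X"), items)
  lapply(phrases, function(p) {
    list(start = p$start, end = p$end, category = p$cat,
         case = p$case, gender = p$gender, number = p$number,
         kids = p$kids)
  })
}

#' Parse every sentence of a corpus
#'
#' @param corpus list of sentences.
#' @inheritParams parse_sentence
#' @return list (one element per sentence) of phrase lists.
#' @export
parse_corpus <- function(corpus, cascade) {
  lapply(corpus, parse_sentence, cascade = cascade)
}

#' Token length of a phrase
#'
#' Number of corpus tokens spanned, counting special-character tokens such as
#' the hyphen in hyphenated compounds (so *oddzial chirurgiczno - urazowy*
#' has length 4). This is the length entering the logarithmic weight of the
#' C-value.
#'
#' @param phrase a phrase from [parse_sentence()].
#' @return integer token count.
#' @export
phrase_token_length <- function(phrase) {
  phrase$end - phrase$start + 1L
}

#' Does a token sequence form a single noun phrase?
#'
#' Re-applies the cascade to the token slice and checks that the result is
#' exactly one maximal phrase covering the whole slice. Used to decide which
#' fragments of a maximal phrase are themselves noun-phrase candidates
#' (adjective-only fragments, for instance, are not).
#'
#' @param sentence a sentence data.frame.
#' @param start,end token span (1-based, inclusive).
#' @inheritParams parse_sentence
#' @return logical scalar.
#' @export
is_noun_phrase <- function(sentence, start, end, cascade) {
  slice <- sentence[start:end, , drop = FALSE]
  ph <- parse_sentence(slice, cascade)
  length(ph) == 1L && ph[[1L]]$start == 1L && ph[[1L]]$end == nrow(slice)
}
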