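# Nested-phrase enumeration, simplified base forms, and corpus-level
# aggregation of standalone/nested frequencies and contexts.

#' Simplified base form of a token span
#'
#' The sequence of lower-cased lemmas of the span's tokens, with
#' special-character tokens (hyphens, periods) contributing their surface.
#' Simplified forms are the identity of a term: all inflected variants of a
#' phrase collapse onto one lemma sequence, at the cost of a few documented
#' merges (number of genitive modifiers, adjective degree, negation,
#' gerund/participle pairs).
#'
#' @param sentence a sentence data.frame.
#' @param start,end token span (1-based, inclusive); defaults to the whole
#'   sentence.
#' @return character vector of lemmas (length `end - start + 1`).
#' @export
simplify_phrase <- function(sentence, start = 1L, end = nrow(sentence)) {
  idx <- start:end
  ifelse(sentence$is_special[idx],
         sentence$surface[idx],
         tolower(sentence$lemma[idx]))
}

.clt_form_key <- function(lemmas) paste(lemmas, collapse = " ")

#' Enumerate the nested noun phrases of a maximal phrase
#'
#' Every proper sub-span of the phrase that the grammar itself accepts as a
#' noun phrase (see [is_noun_phrase()]) is a nested candidate; fragments the
#' grammar rejects - adjective-only spans in particular - are not.
#'
#' @param phrase a phrase from [parse_sentence()].
#' @param sentence the sentence the phrase was found in.
#' @param cascade the compiled cascade.
#' @return data.frame with columns `start`, `end` (absolute token positions)
#'   and `form` (simplified base form); zero rows for a single-token phrase.
#' @export
enumerate_nested <- function(phrase, sentence, cascade) {
  s <- phrase$start
  e <- phrase$end
  starts <- integer()
  ends <- integer()
  forms <- character()
  if (e > s) {
    for (i in s:e) {
      for (j in i:e) {
        if (i == s && j == e) next         # the phrase itself is not nested
        if (is_noun_phrase(sentence, i, j, cascade)) {
          starts <- c(starts, i)
          ends <- c(ends, j)
          forms <- c(forms, .clt_form_key(simplify_phrase(sentence, i, j)))
        }
      }
    }
  }
  data.frame(start = starts, end = ends, form = forms,
             stringsAsFactors = FALSE)
}

# Per-sentence extraction events, cached by sentence fingerprint inside
# build_inventory() so that repeated sentences (very common in clinical
# boilerplate) are analysed once.
.clt_sentence_events <- function(sentence, cascade) {
  phrases <- parse_sentence(sentence, cascade)
  events <- vector("list", length(phrases))
  for (pi in seq_along(phrases)) {
    p <- phrases[[pi]]
    lem <- simplify_phrase(sentence, p$start, p$end)
    form <- .clt_form_key(lem)
    surf <- paste(sentence$surface[p$start:p$end], collapse = " ")
    nested <- enumerate_nested(p, sentence, cascade)
    n <- nrow(nested)
    left <- character(n)
    right <- character(n)
    lengths <- integer(n)
    if (n) {
      for (k in seq_len(n)) {
        i <- nested$start[[k]]; j <- nested$end[[k]]
        left[[k]] <- if (i > p$start)
          tolower(sentence$lemma[[i - 1L]]) else ""
        right[[k]] <- if (j < p$end)
          tolower(sentence$lemma[[j + 1L]]) else ""
        lengths[[k]] <- j - i + 1L
      }
    }
    ext <- function(i) {
      if (i < 1L || i > nrow(sentence)) return(NA_character_)
      paste0(sentence$pos[[i]], ":", tolower(sentence$lemma[[i]]))
    }
    events[[pi]] <- list(form = form, length = p$end - p$start + 1L,
                         surface = surf,
                         nested_form = nested$form,
                         nested_length = lengths,
                         nested_left = left, nested_right = right,
                         ext_left = ext(p$start - 1L),
                         ext_right = ext(p$end + 1L))
  }
  events
}

.clt_new_record <- function(form, length) {
  list(form = form, lemmas = strsplit(form, " ", fixed = TRUE)[[1L]],
       length = length,
       freq_standalone = 0L, freq_nested = 0L,
       super = integer(),            # named: super form -> nested count
       left = character(), right = character(),  # per nested occurrence ("" at edge)
       ext_left = character(), ext_right = character(),  # "pos\rlemma" per standalone occ.
       surfaces = character())
}

#' Aggregate a parsed corpus into a term inventory
#'
#' Walks every sentence, takes each maximal phrase occurrence as a standalone
#' occurrence of its simplified form, and every grammar-accepted sub-span as
#' a nested occurrence of its own form; the containing phrase's form and the
#' single adjacent lemma on each side (an empty marker at the phrase edge)
#' are recorded with each nested occurrence. External one-word sentence
#' contexts of the maximal occurrences are kept for the NC-value step.
#' Forms that never occur standalone are retained.
#'
#' @param corpus list of sentences.
#' @param cascade compiled cascade; defaults to the shipped full grammar.
#' @return a `clt_inventory`: list with `records` (named list of term
#'   records), `n_sentences`, `n_tokens` and `n_phrase_occurrences`.
#' @export
build_inventory <- function(corpus, cascade = compile_cascade()) {
  cache <- new.env(parent = emptyenv())
  recs <- new.env(parent = emptyenv())
  n_phrase <- 0L
  n_tokens <- 0L
  get_rec <- function(form, length) {
    r <- recs[[form]]
    if (is.null(r)) r <- .clt_new_record(form, length)
    r
  }
  for (sentence in corpus) {
    n_tokens <- n_tokens + nrow(sentence)
    key <- paste(sentence$surface, sentence$lemma, sentence$tag,
                 collapse = "\r")
    events <- cache[[key]]
    if (is.null(events)) {
      events <- .clt_sentence_events(sentence, cascade)
      cache[[key]] <- events
    }
    for (ev in events) {
      n_phrase <- n_phrase + 1L
      r <- get_rec(ev$form, ev$length)
      r$freq_standalone <- r$freq_standalone + 1L
      r$surfaces <- union(r$surfaces, ev$surface)
      r$ext_left <- c(r$ext_left, ev$ext_left)
      r$ext_right <- c(r$ext_right, ev$ext_right)
      recs[[ev$form]] <- r
      for (k in seq_along(ev$nested_form)) {
        nf <- ev$nested_form[[k]]
        nr <- get_rec(nf, ev$nested_length[[k]])
        nr$freq_nested <- nr$freq_nested + 1L
        cur <- nr$super[ev$form]
        nr$super[ev$form] <- if (is.na(cur)) 1L else cur + 1L
        nr$left <- c(nr$left, ev$nested_left[[k]])
        nr$right <- c(nr$right, ev$nested_right[[k]])
        recs[[nf]] <- nr
      }
    }
  }
  records <- as.list(recs)
  if (length(records)) records <- records[order(names(records))]
  structure(list(records = records,
                 n_sentences = length(corpus),
                 n_tokens = n_tokens,
                 n_phrase_occurrences = n_phrase),
            class = "clt_inventory")
}

#' @export
print.clt_inventory <- function(x, ...) {
  cat(sprintf(paste0("<clt_inventory: %d term(s) from %d sentence(s), ",
                     "%d maximal phrase occurrence(s)>\n"),
              length(x$records), x$n_sentences, x$n_phrase_occurrences))
  invisible(x)
}

#' @export
as.data.frame.clt_inventory <- function(x, ...) {
  recs <- x$records
  data.frame(
    form = vapply(recs, `[[`, "", "form"),
    length = vapply(recs, `[[`, 0L, "length"),
    freq_standalone = vapply(recs, `[[`, 0L, "freq_standalone"),
    freq_nested = vapply(recs, `[[`, 0L, "freq_nested"),
    n_super_forms = vapply(recs, function(r) length(r$super), 0L),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

# ---- TSV round trip ----------------------------------------------------

.clt_ser_counts <- function(x, empty = "<none>") {
  if (!length(x)) return("")
  x[x == ""] <- empty
  tab <- table(x)
  paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = "|")
}

.clt_ser_named <- function(x) {
  if (!length(x)) return("")
  paste(sprintf("%s=%d", names(x), as.integer(x)), collapse = "|")
}

.clt_deser_counts <- function(s, empty = "<none>") {
  if (is.na(s) || !nzchar(s)) return(character())
  parts <- strsplit(s, "|", fixed = TRUE)[[1L]]
  key <- sub("=[0-9]+$", "", parts)
  cnt <- as.integer(sub("^.*=", "", parts))
  key[key == empty] <- ""
  rep(key, cnt)
}

.clt_deser_named <- function(s) {
  if (is.na(s) || !nzchar(s)) return(stats::setNames(integer(), character()))
  parts <- strsplit(s, "|", fixed = TRUE)[[1L]]
  stats::setNames(as.integer(sub("^.*=", "", parts)),
                  sub("=[0-9]+$", "", parts))
}

#' Export / import an inventory as TSV
#'
#' One row per term with the frequency fields and the super-phrase and
#' context multisets serialised as `key=count` pairs joined by `|`
#' (`<none>` marks the empty-side marker, `<na>` a sentence edge). The file
#' is meant for inspection and for reuse as a reference-corpus inventory.
#'
#' @param inventory a `clt_inventory`.
#' @param path TSV file path.
#' @export
write_inventory <- function(inventory, path) {
  recs <- inventory$records
  df <- data.frame(
    form = vapply(recs, `[[`, "", "form"),
    length = vapply(recs, `[[`, 0L, "length"),
    freq_standalone = vapply(recs, `[[`, 0L, "freq_standalone"),
    freq_nested = vapply(recs, `[[`, 0L, "freq_nested"),
    super = vapply(recs, function(r) .clt_ser_named(r$super), ""),
    left = vapply(recs, function(r) .clt_ser_counts(r$left), ""),
    right = vapply(recs, function(r) .clt_ser_counts(r$right), ""),
    ext_left = vapply(recs, function(r)
      .clt_ser_counts(ifelse(is.na(r$ext_left), "<na>", r$ext_left)), ""),
    ext_right = vapply(recs, function(r)
      .clt_ser_counts(ifelse(is.na(r$ext_right), "<na>", r$ext_right)), ""),
    surfaces = vapply(recs, function(r) paste(r$surfaces, collapse = "|"), ""),
    stringsAsFactors = FALSE
  )
  header <- sprintf("# clinterm inventory\tsentences=%d\ttokens=%d\tphrases=%d",
                    inventory$n_sentences, inventory$n_tokens,
                    inventory$n_phrase_occurrences)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(header, con, useBytes = TRUE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "")
  invisible(path)
}

#' @rdname write_inventory
#' @export
read_inventory <- function(path) {
  header <- readLines(path, n = 1L, encoding = "UTF-8")
  meta <- regmatches(header, gregexpr("[a-z]+=[0-9]+", header))[[1L]]
  meta <- stats::setNames(as.integer(sub("^.*=", "", meta)),
                          sub("=.*$", "", meta))
  df <- utils::read.delim(path, skip = 1L, stringsAsFactors = FALSE,
                          quote = "", fileEncoding = "UTF-8",
                          colClasses = "character")
  recs <- lapply(seq_len(nrow(df)), function(i) {
    ext_l <- .clt_deser_counts(df$ext_left[[i]])
    ext_r <- .clt_deser_counts(df$ext_right[[i]])
    ext_l[ext_l == "<na>"] <- NA_character_
    ext_r[ext_r == "<na>"] <- NA_character_
    list(form = df$form[[i]],
         lemmas = strsplit(df$form[[i]], " ", fixed = TRUE)[[1L]],
         length = as.integer(df$length[[i]]),
         freq_standalone = as.integer(df$freq_standalone[[i]]),
         freq_nested = as.integer(df$freq_nested[[i]]),
         super = .clt_deser_named(df$super[[i]]),
         left = .clt_deser_counts(df$left[[i]]),
         right = .clt_deser_counts(df$right[[i]]),
         ext_left = ext_l, ext_right = ext_r,
         surfaces = strsplit(df$surfaces[[i]], "|", fixed = TRUE)[[1L]])
  })
  names(recs) <- df$form
  structure(list(records = recs,
                 n_sentences = unname(meta["sentences"]),
                 n_tokens = unname(meta["tokens"]),
                 n_phrase_occurrences = unname(meta["phrases"])),
            class = "clt_inventory")
}
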