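# Synthetic tagged-corpus generation with analytically known ground truth.
#
# Each template is a short tagged sentence emulating clinical discharge-note
# text (noun-phrase-dominated, genitive chains, hyphenated compounds,
# abbreviations, stop-word prefixes, agreement violations). For every
# template the maximal noun phrases and their noun-phrase sub-spans are
# annotated BY HAND (from the grammar's published rule semantics, not by
# running the parser), so a generated corpus comes with an independently
# derived expected inventory and expected C-value scores: the central
# end-to-end oracle of the package.

.clt_template <- function(surface, lemma, tag, maximal) {
  list(surface = surface, lemma = lemma, tag = tag, maximal = maximal)
}

# maximal: list of list(span = c(start, end), nested = list of c(start, end))

#' Built-in fixture templates
#'
#' Returns the named list of sentence templates known to the generator.
#' Each template carries its tagged tokens plus hand-annotated maximal
#' phrase spans and nested noun-phrase sub-spans (the ground truth used by
#' [fixture_truth()]). The annotations describe the full (agreement-aware)
#' grammar.
#'
#' @return named list of templates.
#' @export
fixture_templates <- function() {
  list(
    # hospital-treatment-information-card, 4 tokens, noun+adj + gerund+adj
    karta4 = .clt_template(
      c("karta", "informacyjna", "leczenia", "szpitalnego"),
      c("karta", "informacyjny", "leczyć", "szpitalny"),
      c("subst:nom:f:sg", "adj:nom:f:sg", "ger:gen:n:sg", "adj:gen:n:sg"),
      list(list(span = c(1L, 4L),
                nested = list(c(1L, 1L), c(1L, 2L), c(1L, 3L),
                              c(3L, 3L), c(3L, 4L))))),
    # the same phrase with a leading adjective (5 tokens)
    karta5 = .clt_template(
      c("poprzednia", "karta", "informacyjna", "leczenia", "szpitalnego"),
      c("poprzedni", "karta", "informacyjny", "leczyć", "szpitalny"),
      c("adj:nom:f:sg", "subst:nom:f:sg", "adj:nom:f:sg",
        "ger:gen:n:sg", "adj:gen:n:sg"),
      list(list(span = c(1L, 5L),
                nested = list(c(1L, 2L), c(1L, 3L), c(1L, 4L),
                              c(2L, 2L), c(2L, 3L), c(2L, 4L), c(2L, 5L),
                              c(4L, 4L), c(4L, 5L))))),
    # noun + agreeing adjective
    pediatria2 = .clt_template(
      c("pediatria", "ogólna"), c("pediatria", "ogólny"),
      c("subst:nom:f:sg", "adj:nom:f:sg"),
      list(list(span = c(1L, 2L), nested = list(c(1L, 1L))))),
    zalecenie2 = .clt_template(
      c("zalecenie", "lekarskie"), c("zalecenie", "lekarski"),
      c("subst:nom:n:sg", "adj:nom:n:sg"),
      list(list(span = c(1L, 2L), nested = list(c(1L, 1L))))),
    # noun + genitive noun
    kod2 = .clt_template(
      c("kod", "pacjenta"), c("kod", "pacjent"),
      c("subst:nom:m:sg", "subst:gen:m:sg"),
      list(list(span = c(1L, 2L), nested = list(c(1L, 1L), c(2L, 2L))))),
    # hyphenated compound adjective: 4 tokens including the hyphen
    oddzial4 = .clt_template(
      c("oddział", "chirurgiczno", "-", "urazowy"),
      c("oddział", "chirurgiczno", "-", "urazowy"),
      c("subst:nom:m:sg", "adja", "interp", "adj:nom:m:sg"),
      list(list(span = c(1L, 4L), nested = list(c(1L, 1L))))),
    # the four lymph-node-enlargement context phrases
    pw3 = .clt_template(
      c("powiększenie", "węzłów", "chłonnych"),
      c("powiększenie", "węzeł", "chłonny"),
      c("subst:nom:n:sg", "subst:gen:m:pl", "adj:gen:m:pl"),
      list(list(span = c(1L, 3L),
                nested = list(c(1L, 1L), c(1L, 2L), c(2L, 2L), c(2L, 3L))))),
    pwk4 = .clt_template(
      c("powiększenie", "węzłów", "chłonnych",
        "krezkowych"),
      c("powiększenie", "węzeł", "chłonny", "krezkowy"),
      c("subst:nom:n:sg", "subst:gen:m:pl", "adj:gen:m:pl", "adj:gen:m:pl"),
      list(list(span = c(1L, 4L),
                nested = list(c(1L, 1L), c(1L, 2L), c(1L, 3L),
                              c(2L, 2L), c(2L, 3L), c(2L, 4L))))),
    zpw4 = .clt_template(
      c("znaczne", "powiększenie", "węzłów",
        "chłonnych"),
      c("znaczny", "powiększenie", "węzeł", "chłonny"),
      c("adj:nom:n:sg", "subst:nom:n:sg", "subst:gen:m:pl", "adj:gen:m:pl"),
      list(list(span = c(1L, 4L),
                nested = list(c(1L, 2L), c(1L, 3L), c(2L, 2L), c(2L, 3L),
                              c(2L, 4L), c(3L, 3L), c(3L, 4L))))),
    pws4 = .clt_template(
      c("powiększenie", "węzłów", "chłonnych",
        "szyji"),
      c("powiększenie", "węzeł", "chłonny", "szyja"),
      c("subst:nom:n:sg", "subst:gen:m:pl", "adj:gen:m:pl", "subst:gen:f:sg"),
      list(list(span = c(1L, 4L),
                nested = list(c(1L, 1L), c(1L, 2L), c(1L, 3L),
                              c(2L, 2L), c(2L, 3L), c(2L, 4L), c(4L, 4L))))),
    # left kidney normal: adjective on each side of the noun
    nerka3 = .clt_template(
      c("lewa", "nerka", "prawidłowa"),
      c("lewy", "nerka", "prawidłowy"),
      c("adj:nom:f:sg", "subst:nom:f:sg", "adj:nom:f:sg"),
      list(list(span = c(1L, 3L),
                nested = list(c(1L, 2L), c(2L, 2L), c(2L, 3L))))),
    pecherzyk3 = .clt_template(
      c("pęcherzyk", "żółciowy", "prawidłowy"),
      c("pęcherzyk", "żółciowy", "prawidłowy"),
      c("subst:nom:m:sg", "adj:nom:m:sg", "adj:nom:m:sg"),
      list(list(span = c(1L, 3L), nested = list(c(1L, 1L), c(1L, 2L))))),
    # genitive chain: infection - virus - influenza
    zakazenie3 = .clt_template(
      c("zakażenia", "wirusa", "grypy"),
      c("zakażenie", "wirus", "grypa"),
      c("subst:gen:n:sg", "subst:gen:m:sg", "subst:gen:f:sg"),
      list(list(span = c(1L, 3L),
                nested = list(c(1L, 1L), c(1L, 2L), c(2L, 2L), c(2L, 3L),
                              c(3L, 3L))))),
    # acronym head with genitive complement
    usg3 = .clt_template(
      c("USG", "jamy", "brzusznej"),
      c("usg", "jama", "brzuszny"),
      c("brev:npun:nw", "subst:gen:f:sg", "adj:gen:f:sg"),
      list(list(span = c(1L, 3L),
                nested = list(c(1L, 1L), c(1L, 2L), c(2L, 2L), c(2L, 3L))))),
    # stop-word (NZ) prefix: only the trailing noun is a phrase
    trakcie3 = .clt_template(
      c("w", "trakcie", "choroby"),
      c("w", "trakt", "choroba"),
      c("prep:loc", "subst:loc:m:sg", "subst:gen:f:sg"),
      list(list(span = c(3L, 3L), nested = list()))),
    # gender agreement violation: no 2-token phrase under the full grammar
    clash2 = .clt_template(
      c("ostra", "dyżur"), c("ostry", "dyżur"),
      c("adj:nom:f:sg", "subst:nom:m:sg"),
      list(list(span = c(2L, 2L), nested = list()))),
    ostry2 = .clt_template(
      c("ostry", "dyżur"), c("ostry", "dyżur"),
      c("adj:nom:m:sg", "subst:nom:m:sg"),
      list(list(span = c(1L, 2L), nested = list(c(2L, 2L))))),
    # humerus only ever nested under a side adjective
    kosc3 = .clt_template(
      c("lewa", "kość", "ramienna"),
      c("lewy", "kość", "ramienny"),
      c("adj:nom:f:sg", "subst:nom:f:sg", "adj:nom:f:sg"),
      list(list(span = c(1L, 3L),
                nested = list(c(1L, 2L), c(2L, 2L), c(2L, 3L))))),
    # non-phrase filler material
    filler3 = .clt_template(
      c("w", "bardzo", "."), c("w", "bardzo", "."),
      c("prep:loc", "adv", "interp"),
      list())
  )
}

.clt_template_sentence <- function(tpl) {
  tagged_sentence(tpl$surface, tpl$lemma, tpl$tag)
}

#' Generate a synthetic tagged corpus from an occurrence plan
#'
#' The plan maps template names (see [fixture_templates()]) to occurrence
#' counts; the corpus realises exactly those counts, optionally interleaved
#' with non-phrase filler sentences and shuffled reproducibly.
#'
#' @param plan named integer vector or list: template name -> count.
#' @param seed integer seed for the sentence order (and nothing else; the
#'   sentences themselves are deterministic).
#' @param filler number of filler sentences to intersperse.
#' @param shuffle shuffle sentence order (default TRUE).
#' @return list of class `clt_fixture` with `corpus` (a `clt_corpus`) and
#'   `plan`.
#' @export
generate_fixture <- function(plan, seed = 1L, filler = 0L, shuffle = TRUE) {
  plan <- unlist(plan)
  templates <- fixture_templates()
  unknown <- setdiff(names(plan), names(templates))
  if (length(unknown)) {
    stop(sprintf("plan refers to unknown template(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  if (any(plan < 0)) stop("plan counts must be >= 0", call. = FALSE)
  sentences <- list()
  for (nm in names(plan)) {
    if (plan[[nm]] == 0L) next
    s <- .clt_template_sentence(templates[[nm]])
    sentences <- c(sentences, rep(list(s), plan[[nm]]))
  }
  if (filler > 0L) {
    f <- .clt_template_sentence(templates[["filler3"]])
    sentences <- c(sentences, rep(list(f), filler))
  }
  if (shuffle && length(sentences) > 1L) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    set.seed(seed)
    sentences <- sentences[sample.int(length(sentences))]
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }
  structure(list(corpus = structure(sentences, class = "clt_corpus"),
                 plan = plan),
            class = "clt_fixture")
}

#' Expected inventory of a fixture plan
#'
#' Computes, from the hand-annotated template truth alone (the cascade
#' parser is never invoked), the term records a correct pipeline must
#' produce on the generated corpus: standalone and nested frequencies,
#' super-phrase counts, and the adjacent-word context multisets.
#'
#' @param plan named counts as given to [generate_fixture()].
#' @return named list of truth records with fields `form`, `length`,
#'   `freq_standalone`, `freq_nested`, `super`, `left`, `right`.
#' @export
fixture_truth <- function(plan) {
  plan <- unlist(plan)
  templates <- fixture_templates()
  recs <- list()
  touch <- function(form, len) {
    if (is.null(recs[[form]])) {
      recs[[form]] <<- list(form = form, length = len,
                            freq_standalone = 0L, freq_nested = 0L,
                            super = integer(),
                            left = character(), right = character())
    }
  }
  for (nm in names(plan)) {
    count <- plan[[nm]]
    if (count == 0L) next
    tpl <- templates[[nm]]
    sent <- .clt_template_sentence(tpl)
    for (mx in tpl$maximal) {
      s <- mx$span[[1L]]; e <- mx$span[[2L]]
      form <- .clt_form_key(simplify_phrase(sent, s, e))
      touch(form, e - s + 1L)
      recs[[form]]$freq_standalone <- recs[[form]]$freq_standalone + count
      for (sp in mx$nested) {
        i <- sp[[1L]]; j <- sp[[2L]]
        nf <- .clt_form_key(simplify_phrase(sent, i, j))
        touch(nf, j - i + 1L)
        r <- recs[[nf]]
        r$freq_nested <- r$freq_nested + count
        cur <- r$super[form]
        r$super[form] <- if (is.na(cur)) count else cur + count
        r$left <- c(r$left,
                    rep(if (i > s) tolower(sent$lemma[[i - 1L]]) else "", count))
        r$right <- c(r$right,
                     rep(if (j < e) tolower(sent$lemma[[j + 1L]]) else "", count))
        recs[[nf]] <- r
      }
    }
  }
  if (length(recs)) recs[order(names(recs))] else recs
}

#' Expected C-values from a fixture plan
#'
#' A direct transcription of the C-value formula applied to the
#' [fixture_truth()] records, kept independent of the ranking module's code
#' path so pipeline scores can be checked against it.
#'
#' @inheritParams fixture_truth
#' @param scheme context-counting scheme (see [context_type_count()]).
#' @param unigram_l,zero_rule as in [c_value()].
#' @return data.frame with `form` and `expected`.
#' @export
fixture_expected_scores <- function(plan, scheme = "max_separate",
                                    unigram_l = 0.1, zero_rule = TRUE) {
  truth <- fixture_truth(plan)
  expected <- vapply(truth, function(r) {
    l <- if (r$length == 1L) unigram_l else log2(r$length)
    f <- r$freq_standalone + r$freq_nested
    r_ctx <- switch(scheme,
      original = length(r$super),
      grouped_words = length(unique(c(r$left[nzchar(r$left)],
                                      r$right[nzchar(r$right)]))),
      max_separate = max(length(unique(r$left[nzchar(r$left)])),
                         length(unique(r$right[nzchar(r$right)]))),
      stop("unknown scheme", call. = FALSE))
    if (zero_rule && r$freq_standalone == 0L && r_ctx <= 1L) return(0)
    if (r_ctx == 0L) l * f else l * (f - sum(r$super) / r_ctx)
  }, 0)
  data.frame(form = names(truth), expected = unname(expected),
             stringsAsFactors = FALSE)
}

#' Canned corpus of the worked-example phrases
#'
#' A deterministic corpus containing every phrase used in the in-text
#' worked examples: the treatment-information-card pair at 1164/1
#' occurrences, the four lymph-node-enlargement context phrases, the left
#' kidney / gall bladder / influenza-virus-infection phrases, an acronym
#' phrase, a stop-word-prefixed span, and an agreement-violating span.
#'
#' @param karta_n occurrences of the 4-token card phrase (default 1164).
#' @return a `clt_fixture` (see [generate_fixture()]).
#' @export
paper_examples_fixture <- function(karta_n = 1164L) {
  plan <- c(karta4 = karta_n, karta5 = 1L,
            pw3 = 1L, pwk4 = 1L, zpw4 = 1L, pws4 = 1L,
            nerka3 = 1L, pecherzyk3 = 1L, zakazenie3 = 1L, usg3 = 1L,
            trakcie3 = 1L, clash2 = 1L, ostry2 = 1L, kosc3 = 1L)
  generate_fixture(plan, shuffle = FALSE)
}
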