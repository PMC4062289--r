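test_that("the shipped grammar compiles into six non-empty levels", {
  casc <- casc_full()
  expect_length(casc$levels, 6L)
  expect_true(all(lengths(casc$levels) >= 1L))
  expect_true(length(casc$stops$nz) > 10L)
  expect_true(length(casc$stops$az) > 5L)
})

test_that("compile errors name the offending rule", {
  bad <- withr::local_tempfile(fileext = ".yml")
  writeLines(c("levels:",
               "- level: 1",
               "  rules:",
               "  - {lhs: QQ, rhs: [{tok: subst}]}"), bad)
  expect_error(compile_cascade(bad), "level 1 #1")
  writeLines(c("levels:",
               "- level: 1",
               "  rules:",
               "  - {lhs: NB, rhs: [{cat: ZZZ}]}"), bad)
  expect_error(compile_cascade(bad), "undefined category")
  # an agreement variable with no partner cannot force anything
  writeLines(c("levels:",
               "- level: 1",
               "  rules:",
               "  - {lhs: NB, rhs: [{tok: subst, vars: 'C'}, {tok: adj}]}"), bad)
  expect_error(compile_cascade(bad), "used once")
})

test_that("head annotation copies features from the marked element", {
  # hyphenated compound: features must come from the trailing adjective
  s <- sent("oddział/oddział/subst:nom:m:sg", "chirurgiczno/chirurgiczno/adja",
            "-/-/interp", "urazowy/urazowy/adj:nom:m:sg")
  ph <- parse_sentence(s, casc_full())
  expect_length(ph, 1L)
  expect_equal(c(ph[[1L]]$start, ph[[1L]]$end), c(1L, 4L))
  expect_equal(phrase_token_length(ph[[1L]]), 4L)   # hyphen counts as a token
  expect_equal(ph[[1L]]$case, "nom")
  # adverb + adjective: phrase keeps the adjective's features
  s2 <- sent("bardzo/bardzo/adv", "ostry/ostry/adj:nom:m:sg",
             "dyżur/dyżur/subst:nom:m:sg")
  ph2 <- parse_sentence(s2, casc_full())
  expect_length(ph2, 1L)
  expect_equal(c(ph2[[1L]]$start, ph2[[1L]]$end), c(1L, 3L))
})

test_that("agreement separates the full and simplified grammars", {
  clash <- sent("ostra/ostry/adj:nom:f:sg", "dyżur/dyżur/subst:nom:m:sg")
  full <- parse_sentence(clash, casc_full())
  expect_length(full, 1L)
  expect_equal(c(full[[1L]]$start, full[[1L]]$end), c(2L, 2L))
  simpl <- parse_sentence(clash, casc_simplified())
  expect_length(simpl, 1L)
  expect_equal(c(simpl[[1L]]$start, simpl[[1L]]$end), c(1L, 2L))

  agree <- sent("ostry/ostry/adj:nom:m:sg", "dyżur/dyżur/subst:nom:m:sg")
  ph <- parse_sentence(agree, casc_full())
  expect_equal(c(ph[[1L]]$start, ph[[1L]]$end), c(1L, 2L))
})

test_that("acronym heads, genitive complements and stop words parse as described", {
  usg <- sent("USG/usg/brev:npun:nw", "jamy/jama/subst:gen:f:sg",
              "brzusznej/brzuszny/adj:gen:f:sg")
  ph <- parse_sentence(usg, casc_full())
  expect_length(ph, 1L)
  expect_equal(c(ph[[1L]]$start, ph[[1L]]$end), c(1L, 3L))

  stopw <- sent("w/w/prep:loc", "trakcie/trakt/subst:loc:m:sg",
                "choroby/choroba/subst:gen:f:sg")
  ph2 <- parse_sentence(stopw, casc_full())
  expect_length(ph2, 1L)
  expect_equal(c(ph2[[1L]]$start, ph2[[1L]]$end), c(3L, 3L))  # not from "trakcie"

  # foreign-word runs are capped at three tokens
  latin <- sent("alpha/alpha/foreign", "beta/beta/foreign",
                "gamma/gamma/foreign", "delta/delta/foreign")
  ph3 <- parse_sentence(latin, casc_full())
  expect_equal(vapply(ph3, function(p) p$end - p$start + 1L, 0L), c(3L, 1L))
})

test_that("maximal phrases are deterministic, non-overlapping and sorted", {
  fx <- generate_fixture(c(karta4 = 2, pws4 = 2, zakazenie3 = 2, usg3 = 2,
                           trakcie3 = 1, clash2 = 1, oddzial4 = 1),
                         seed = 11, filler = 3)
  for (s in fx$corpus) {
    p1 <- parse_sentence(s, casc_full())
    p2 <- parse_sentence(s, casc_full())
    expect_identical(p1, p2)
    if (length(p1) > 1L) {
      starts <- vapply(p1, `[[`, 0L, "start")
      ends <- vapply(p1, `[[`, 0L, "end")
      expect_true(all(diff(starts) > 0))
      expect_true(all(starts[-1L] > ends[-length(ends)]))
    }
  }
})

test_that("the simplified grammar accepts a superset of the full grammar's candidates", {
  fx <- generate_fixture(c(karta4 = 2, karta5 = 1, pws4 = 1, zpw4 = 1,
                           zakazenie3 = 1, usg3 = 1, nerka3 = 1, clash2 = 2,
                           oddzial4 = 1, kosc3 = 1), seed = 3)
  spans <- function(cascade) {
    out <- character()
    for (si in seq_along(fx$corpus)) {
      s <- fx$corpus[[si]]
      for (p in parse_sentence(s, cascade)) {
        out <- c(out, sprintf("%d:%d-%d", si, p$start, p$end))
        nested <- enumerate_nested(p, s, cascade)
        if (nrow(nested)) {
          out <- c(out, sprintf("%d:%d-%d", si, nested$start, nested$end))
        }
      }
    }
    unique(out)
  }
  full <- spans(casc_full())
  simpl <- spans(casc_simplified())
  expect_true(all(full %in% simpl))
  expect_gt(length(simpl), length(full))   # the clash spans are extra
})

test_that("adjective-only fragments are never noun phrases", {
  s <- sent("pęcherzyk/pęcherzyk/subst:nom:m:sg",
            "żółciowy/żółciowy/adj:nom:m:sg",
            "prawidłowy/prawidłowy/adj:nom:m:sg")
  casc <- casc_full()
  expect_false(is_noun_phrase(s, 2L, 3L, casc))
  expect_false(is_noun_phrase(s, 2L, 2L, casc))
  expect_true(is_noun_phrase(s, 1L, 2L, casc))
})

test_that("the trailing-acronym phrase rule can be switched off", {
  s <- sent("badanie/badanie/subst:nom:n:sg", "USG/usg/brev:npun:nw")
  with_nc <- parse_sentence(s, casc_full())
  expect_equal(vapply(with_nc, `[[`, 0L, "end") -
               vapply(with_nc, `[[`, 0L, "start"), 1L)
  casc_off <- compile_cascade(trailing_nc = FALSE)
  without <- parse_sentence(s, casc_off)
  expect_length(without, 2L)   # two one-token phrases instead
})
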