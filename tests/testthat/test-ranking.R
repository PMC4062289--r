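rec <- function(length, standalone, nested_by_super = integer(),
                left = character(), right = character()) {
  list(form = "t", lemmas = "t", length = length,
       freq_standalone = standalone, freq_nested = sum(nested_by_super),
       super = nested_by_super, left = left, right = right,
       ext_left = character(), ext_right = character(), surfaces = "t")
}

test_that("length weight is log2 with a small unigram constant", {
  expect_equal(length_weight(2L), 1.0)
  expect_equal(length_weight(4L), 2.0)
  expect_equal(length_weight(1L), 0.1)
  expect_equal(length_weight(1L, unigram_l = 1), 1)
  expect_error(length_weight(0L), "length")
})

test_that("the three context-counting schemes give 4 / 3 / 2 on the enlargement example", {
  fx <- generate_fixture(c(pw3 = 1, pwk4 = 1, zpw4 = 1, pws4 = 1),
                         shuffle = FALSE)
  inv <- build_inventory(fx$corpus, casc_full())
  r <- inv$records[["węzeł chłonny"]]
  expect_equal(context_type_count(r, "original"), 4L)
  expect_equal(context_type_count(r, "grouped_words"), 3L)
  expect_equal(context_type_count(r, "max_separate"), 2L)
  # a standalone-only record has no contexts under any scheme
  solo <- rec(2L, 5L)
  for (s in c("original", "grouped_words", "max_separate")) {
    expect_equal(context_type_count(solo, s), 0L)
  }
})

test_that("C-value reproduces the printed score patterns", {
  # 4 tokens, 116 standalone, never nested
  expect_equal(c_value(rec(4L, 116L)), 232)
  # 4 tokens, 1164 standalone, once nested in a single super phrase
  r <- rec(4L, 1164L, c(super = 1L), left = "poprzedni", right = "")
  expect_equal(c_value(r, "max_separate"), 2 * (1165 - 1))
  # nested-only with a single context type is zeroed; with the rule off the
  # subtracted mean exhausts the whole frequency and lands on 0 as well
  r0 <- rec(3L, 0L, c(s1 = 1164L, s2 = 1L),
            left = c(rep("", 1164L), "poprzedni"), right = rep("a", 1165L))
  expect_equal(c_value(r0, "max_separate"), 0)
  expect_equal(c_value(r0, "max_separate", zero_rule = FALSE), 0)
  # with two context types the same record scores positive
  expect_gt(c_value(r0, "original"), 0)
  # and not for a standalone-occurring term with one context
  r1 <- rec(2L, 10L, c(s1 = 2L), left = c("", ""), right = c("b", "b"))
  expect_gt(c_value(r1, "max_separate"), 0)
})

test_that("C-value equals the direct-formula oracle on random records", {
  set.seed(101)
  for (i in 1:200) {
    r <- random_record()
    scheme <- sample(c("original", "grouped_words", "max_separate"), 1L)
    expect_equal(c_value(r, scheme),
                 brute_c_value(r$length, r$freq_standalone, r$freq_nested,
                               r$super, r$left, r$right, scheme))
  }
})

test_that("C1 never exceeds the original C-value and matches it for un-nested terms", {
  set.seed(202)
  for (i in 1:200) {
    r <- random_record()
    c_orig <- c_value(r, "original")
    c1 <- c_value(r, "max_separate")
    expect_lte(c1, c_orig + 1e-12)
    if (r$freq_nested == 0L) expect_equal(c1, c_orig)
  }
  # monotonicity in the standalone frequency
  base <- rec(3L, 5L, c(a = 2L, b = 1L), left = c("x", "x", "y"),
              right = c("", "z", ""))
  more <- base
  more$freq_standalone <- 6L
  expect_gt(c_value(more, "original"), c_value(base, "original"))
})

test_that("pipeline scores equal brute-force Eq-style scores on a 30-sentence fixture", {
  plan <- c(karta4 = 5, karta5 = 2, pw3 = 3, pwk4 = 2, zpw4 = 2, pws4 = 2,
            nerka3 = 3, pecherzyk3 = 2, zakazenie3 = 2, usg3 = 2,
            ostry2 = 3, kosc3 = 2)
  fx <- generate_fixture(plan, seed = 6)
  inv <- build_inventory(fx$corpus, casc_full())
  sc <- score_inventory(inv)
  for (scheme in c("original", "max_separate")) {
    exp_df <- fixture_expected_scores(plan, scheme = scheme)
    got <- vapply(inv$records[exp_df$form], c_value, 0, scheme = scheme)
    expect_equal(unname(got), exp_df$expected, info = scheme)
  }
  expect_setequal(sc$form, fixture_expected_scores(plan)$form)
})

test_that("NC-value weights shared contexts and falls back to 0.8 C without them", {
  # ten one-phrase sentences; three terms share the left verb context
  mk <- function(noun, verb = NULL) {
    toks <- c(if (!is.null(verb)) sprintf("%s/%s/fin:sg", verb, verb),
              sprintf("%s/%s/subst:nom:f:sg", noun, noun))
    do.call(sent, as.list(toks))
  }
  corpus <- structure(c(
    lapply(c("alfa", "beta", "gamma"), mk, verb = "stwierdzono"),
    lapply(c("delta", "epsilon", "dzeta", "eta", "teta", "jota", "kappa"), mk)
  ), class = "clt_corpus")
  inv <- build_inventory(corpus, casc_full())
  sc <- score_inventory(inv)
  expect_equal(nrow(sc), 10L)
  out <- nc_value(sc, inv, top_k = 10L)
  # weight(stwierdzono) = 3/10; each flanked term has f_t(b) = 1
  flanked <- out$form %in% c("alfa", "beta", "gamma")
  expect_equal(out$nc_value[flanked],
               0.8 * out$c1_value[flanked] + 0.2 * (1 * 3 / 10))
  expect_equal(out$nc_value[!flanked], 0.8 * out$c1_value[!flanked])
  # punctuation-only contexts contribute nothing
  punct <- structure(list(
    tagged_sentence(c(".", "alfa", "."), c(".", "alfa", "."),
                    c("interp", "subst:nom:f:sg", "interp"))),
    class = "clt_corpus")
  hmm <- build_inventory(punct, casc_full())
  sp <- suppressWarnings(nc_value(score_inventory(hmm), hmm, top_k = 300L))
  expect_equal(sp$nc_value, 0.8 * sp$c1_value)
  # oversized top_k warns and uses all terms
  expect_warning(nc_value(sc, inv, top_k = 300L), "exceeds")
})

test_that("ranking is stable, tie-broken by frequency then form, and cut correctly", {
  df <- data.frame(form = c("b b", "a a", "c c", "d d"),
                   length = 2L,
                   freq_standalone = c(5L, 7L, 7L, 1L),
                   freq_nested = 0L,
                   c1_value = c(3, 3, 3, 1),
                   stringsAsFactors = FALSE)
  r <- rank_terms(df, by = "c1_value")
  expect_equal(r$form, c("a a", "c c", "b b", "d d"))
  expect_equal(r$rank, 1:4)
  expect_equal(nrow(rank_terms(df, by = "c1_value", cutoff_rank = 2)), 2L)
  expect_equal(nrow(rank_terms(df, by = "c1_value", cutoff_rank = 200)), 4L)
  expect_equal(nrow(rank_terms(df, by = "c1_value", cutoff_score = 3)), 3L)
  expect_error(rank_terms(df, by = "nope"), "unknown score column")
  # determinism across repeated full-pipeline runs
  fx <- generate_fixture(c(karta4 = 3, usg3 = 2, pws4 = 1), seed = 13)
  run <- function() {
    inv <- build_inventory(fx$corpus, casc_full())
    suppressWarnings(rank_terms(nc_value(score_inventory(inv), inv)))
  }
  expect_identical(run(), run())
})

test_that("score bands partition the term list", {
  fx <- generate_fixture(c(karta4 = 4, karta5 = 1, pw3 = 1, pwk4 = 1,
                           zpw4 = 1, pws4 = 1, kosc3 = 2), seed = 8)
  inv <- build_inventory(fx$corpus, casc_full())
  sc <- score_inventory(inv)
  bands <- score_bands(sc, "c1_value")
  expect_equal(sum(bands$n), nrow(sc))
  expect_true(all(bands$n >= 0))
})
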