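# Shared helpers: memoised cascades, small hand-built sentences, and the
# independent oracles used by the property tests.

clt_test_env <- new.env(parent = emptyenv())

casc_full <- function() {
  if (is.null(clt_test_env$full)) clt_test_env$full <- compile_cascade()
  clt_test_env$full
}

casc_simplified <- function() {
  if (is.null(clt_test_env$simpl)) {
    clt_test_env$simpl <- compile_cascade(mode = "simplified")
  }
  clt_test_env$simpl
}

# shorthand sentence builder: sent("surface/lemma/tag", ...)
sent <- function(...) {
  parts <- strsplit(c(...), "/", fixed = TRUE)
  tagged_sentence(vapply(parts, `[[`, "", 1L),
                  vapply(parts, `[[`, "", 2L),
                  vapply(parts, `[[`, "", 3L))
}

# Independent brute-force aggregation: direct triple loop over sentences,
# maximal phrases and all sub-spans; tallies into flat named vectors without
# any of build_inventory()'s record bookkeeping.
brute_counts <- function(corpus, cascade) {
  standalone <- integer()
  nested <- integer()
  bump <- function(v, key) {
    cur <- v[key]
    v[key] <- if (is.na(cur)) 1L else cur + 1L
    v
  }
  for (s in corpus) {
    for (p in parse_sentence(s, cascade)) {
      standalone <- bump(standalone,
                         paste(simplify_phrase(s, p$start, p$end), collapse = " "))
      if (p$end > p$start) {
        for (i in p$start:p$end) {
          for (j in i:p$end) {
            if (i == p$start && j == p$end) next
            if (is_noun_phrase(s, i, j, cascade)) {
              nested <- bump(nested,
                             paste(simplify_phrase(s, i, j), collapse = " "))
            }
          }
        }
      }
    }
  }
  list(standalone = standalone, nested = nested)
}

# Direct transcription of the C-value formula from a bare record, used as
# the ranking oracle on synthetic records.
brute_c_value <- function(length, freq_standalone, freq_nested, super,
                          left, right, scheme, unigram_l = 0.1,
                          zero_rule = TRUE) {
  l <- if (length == 1L) unigram_l else log2(length)
  f <- freq_standalone + freq_nested
  r <- switch(scheme,
    original = base::length(super),
    grouped_words = base::length(unique(c(left[nzchar(left)],
                                          right[nzchar(right)]))),
    max_separate = max(base::length(unique(left[nzchar(left)])),
                       base::length(unique(right[nzchar(right)]))))
  if (zero_rule && freq_standalone == 0L && r <= 1L) return(0)
  if (r == 0L) l * f else l * (f - sum(super) / r)
}

# Random synthetic term record (never touches the parser). As in real
# aggregation, every nested occurrence inside one super form sees that
# form's fixed adjacent words, so context variety cannot exceed the number
# of distinct super phrases.
random_record <- function() {
  n_super <- sample(0:4, 1L)
  super <- if (n_super) {
    stats::setNames(sample(1:20, n_super, replace = TRUE),
                    paste0("super", seq_len(n_super)))
  } else integer()
  words <- c("", "alfa", "beta", "gamma")
  left <- character()
  right <- character()
  for (k in seq_len(n_super)) {
    l <- sample(words, 1L)
    # a proper sub-span always has at least one in-phrase neighbour
    r <- if (l == "") sample(words[-1L], 1L) else sample(words, 1L)
    left <- c(left, rep(l, super[[k]]))
    right <- c(right, rep(r, super[[k]]))
  }
  list(form = "x y", lemmas = c("x", "y"), length = sample(1:5, 1L),
       freq_standalone = sample(0:30, 1L), freq_nested = sum(super),
       super = super, left = left, right = right,
       ext_left = character(), ext_right = character(),
       surfaces = "x y")
}

# Exhaustive-path oracle for the position-weighted edit distance: minimum
# weighted cost over all monotone edit scripts, found by plain recursion.
# An operation that brings the consumed prefix lengths to (i, j) costs the
# weight at position max(i, j).
brute_weighted_distance <- function(a, b, weight_fn) {
  ca <- strsplit(a, "")[[1L]]
  cb <- strsplit(b, "")[[1L]]
  la <- length(ca)
  lb <- length(cb)
  L <- max(la, lb)
  w <- weight_fn(seq_len(L), L)
  rec <- function(i, j) {
    if (i > la && j > lb) return(0)
    cost <- Inf
    if (i <= la && j <= lb) {
      step <- if (ca[[i]] == cb[[j]]) 0 else w[[max(i, j)]]
      cost <- min(cost, step + rec(i + 1L, j + 1L))
    }
    if (i <= la) cost <- min(cost, w[[max(i, j - 1L)]] + rec(i + 1L, j))
    if (j <= lb) cost <- min(cost, w[[max(i - 1L, j)]] + rec(i, j + 1L))
    cost
  }
  rec(1L, 1L)
}

brute_similarity <- function(a, b, weight_fn) {
  L <- max(nchar(a), nchar(b))
  1 - brute_weighted_distance(a, b, weight_fn) / sum(weight_fn(seq_len(L), L))
}
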