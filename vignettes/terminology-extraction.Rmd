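---
title: "Extracting clinical terminology from tagged Polish text"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting clinical terminology from tagged Polish text}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clinterm)
```

## The task and its setting

Hospital discharge notes are dense, noun-phrase-dominated text full of
local vocabulary that no published dictionary covers. `clinterm`
implements a complete terminology-extraction pipeline for such material in
a strongly inflectional language (Polish): select candidate noun phrases
with a shallow grammar, normalise them so that inflected variants count as
one candidate, weight them by a termhood statistic, and optionally compare
the result against a general-language corpus and a controlled vocabulary.

The input is a corpus that has already been tokenised and morphologically
tagged (running a tagger is out of scope); the package reads a vertical
one-token-per-line format carrying surface, lemma and a colon-joined tag
with word class and case/gender/number.

## Candidate selection: the cascaded grammar

Candidates are nominal phrases: a noun or acronym head, agreeing
adjectival modifiers (including adverb-modified and hyphenated compound
adjectives, and coordination with *i* inside the adjectival phrase), and
chains of genitive complements. Prepositional phrases and noun
coordination are deliberately outside the grammar.

Recognition uses six ordered levels of rewrite rules
(`inst/extdata/grammar.yml`). Each level scans a sentence left to right;
at every position the longest match over that level's rules wins (file
order breaks ties), the matched items are replaced by a single categorised
item, and scanning resumes after it. Level 1 builds word-level categories
(N for nouns/gerunds, NC for non-inflecting heads such as acronyms,
abbreviations and up to three foreign words, AJ/AC for adjectives), level
2 attaches adverbs and builds hyphenated compounds, level 3 adjectival
phrases, level 4 noun + adjectival-phrase blocks, level 5 genitive chains
and level 6 the final maximal phrases.

Morphological constraints come in two kinds, and they behave differently:

* **agreement variables** (case/gender/number shared between items):
  unification is permissive about *missing* features, because
  non-inflecting items cannot supply a value;
* **fixed value tests** (the genitive requirement on complement chains):
  strict — the feature must be present and equal. If caseless
  acronym-derived items were allowed through genitive slots, every
  trailing acronym would silently join the preceding phrase and the
  dedicated (switchable) trailing-acronym rule would be unreachable.

Two word lists (NZ for nouns, AZ for modifiers: time and duration words,
month and weekday names, introductory words such as 'goal' or 'feature')
are rewritten into inert stop categories at level 1; no later rule
consumes them, so a candidate can never start with — or contain — such a
word. The printed membership of these lists is an editable configuration,
not a closed set.

`mode = "simplified"` drops every morphological constraint and matches on
word class alone, emulating extraction when tag features are unreliable.
On any corpus it accepts a superset of the full grammar's candidate spans;
the extra material is mostly agreement-violating noise, which is exactly
the trade-off the mode exists to study.

## Counting: simplified base forms and nested phrases

Phrase identity is the **simplified base form**: the sequence of
lower-cased token lemmas (hyphens keep their surface). This makes
*zakażenia wirusa grypy* and its nominative variant the same candidate
without generating correct phrase-level lemmas, at the cost of a few
documented merges (number of genitive modifiers, adjective degree, negated
participles, gerund/participle pairs sharing an infinitive lemma). We
accept these merges; they are inherent to the approach.

Every maximal phrase occurrence also counts as one occurrence of each
**nested** candidate: every proper sub-span that the grammar itself
accepts as a noun phrase. Sub-spans are re-parsed with the cascade rather
than read off the derivation, because counted fragments (e.g. *nerka
prawidłowa* inside *lewa nerka prawidłowa*) routinely cross constituent
boundaries of the particular derivation chosen. Adjective-only fragments
are never candidates. For each nested occurrence the containing phrase's
form and the single adjacent lemma on each side (an empty marker at the
edge) are recorded; one-word sentence neighbours of maximal occurrences
are kept separately for the NC step. A candidate that never occurs on its
own is retained — clinically real terms such as *kość ramienna* surface
only inside longer phrases.

## Scoring

For a candidate $p$ with total frequency $f(p)$, super-phrase multiset
$LP$ and $r$ distinct context types,

$$C(p) = \begin{cases} l(p)\, f(p) & r = 0\\
l(p)\left(f(p) - \tfrac{1}{r}\sum_{lp \in LP} f(lp)\right) & r > 0
\end{cases}, \qquad
l(p) = \begin{cases} 0.1 & |p| = 1\\ \log_2 |p| & |p| \ge 2.\end{cases}$$

The unigram weight 0.1 (not 1) keeps single words from crowding the top
of the list; it is a tunable parameter (`unigram_l`). A nested-only
candidate with at most one context type scores 0 — with our aggregation
this also follows from the formula itself when $r = 1$, since the whole
frequency is then subtracted, but the rule is kept explicit
(`zero_rule`) because it documents intent. The zero rule is never applied
to candidates that do occur standalone.

Three context-counting schemes define $r$: `original` counts distinct
super phrases; `grouped_words` counts distinct adjacent words pooled over
both sides; `max_separate` — the **C₁** variant and the default — takes
the maximum of the two sides counted separately, with empty-side markers
never counted. Only $r$ changes between schemes; the subtracted sum always
runs over all nested occurrences. C₁ therefore never exceeds the original
C-value on aggregated data, and deflates fragments whose many "contexts"
are really one super phrase with interchangeable outer words.

The **NC-value** re-ranks by shared external context:
$NC(t) = 0.8\,C(t) + 0.2\sum_b f_t(b)\,w(b)$, with $w(b) = t(b)/n$ over
the `top_k = 300` leading terms. Context words are lemmas (not surfaces —
the right choice in an inflectional language) of nouns, adjectives and
verbs immediately adjacent to occurrences of those terms; we scan the
neighbours of maximal-phrase occurrences, since the inside of a super
phrase belongs to the C-value's own context notion. The weights 0.8/0.2
and the cut at 300 follow the published parametrisation and are exposed
in `nc_value()`.

## Auxiliary stages

`compare_to_reference()` annotates each domain term as absent / present /
present-with-higher-score relative to the same pipeline run on a
general-language corpus, and tabulates the overlap split into single-word
and multiword terms. It deliberately does not filter: in near-purely
clinical text the overlap is small and largely medical itself.

`match_term()` compares simplified forms against a controlled vocabulary
in four ordered tiers: exact, nested-in-entry, approximate, none. The
approximate tier strips one inflectional suffix per word (longest listed
ending that leaves at least 3 characters; the shipped table covers common
Polish case endings) and uses a position-weighted edit distance: an edit
at position $i$ of an alignment over the longer word (length $L$) costs
$1 - (i-1)/(2L)$, so end-of-word differences — where inflection residue
lives — cost about half of word-initial ones. The exact shape of the
discount is not fixed by any published account; the linear half-discount
is this package's choice, isolated behind the `weight_fn` parameter, and
the qualitative property (later edits cost less) is what the tests pin
down. The similarity threshold (default 0.8) is likewise a configurable
design choice. Because gerund lemmas differ strongly from nominal
vocabulary entries (*leczyć* vs *leczenie*), the exact tier also accepts
caller-supplied grammatical forms when available.

## The synthetic-data generator and what the tests show

No clinical corpus can be shipped, so validation rests on
`generate_fixture()`: tagged sentence templates emulating discharge-note
characteristics — short noun-phrase sentences, genitive chains, hyphenated
compounds, acronym heads, stop-word prefixes, agreement violations,
non-phrase filler. For every template the maximal phrases and their
noun-phrase sub-spans are annotated by hand from the rule semantics, so a
plan (template → count) yields an analytically derived expected inventory
(`fixture_truth()`) and expected scores (`fixture_expected_scores()`, a
direct transcription of the formula) that never touch the parser or the
ranking code. Equality of the pipeline with this ground truth on mixed
corpora — plus a brute-force re-enumeration of all grammar-accepted
sub-spans — is the package's central oracle.

The generator reproduces the *structure* of clinical text, not its
statistics: templates are clean, tags are correct, spelling is perfect and
sentence boundaries are explicit. Passing tests therefore demonstrate the
algorithmic correctness of candidate selection, counting and scoring, not
robustness to tagger errors, misspellings or ad-hoc abbreviations, which
in real deployments are handled upstream (correction rules, abbreviation
dictionaries) and degrade results in ways only a real corpus can measure.

Problem sizes are chosen to keep every check analytic and quick: fixture
corpora of up to a few dozen distinct sentences (repeated boilerplate
sentences, e.g. 1164 copies of one phrase, are cached and cost nothing),
exhaustive edit-distance oracles over all 3-letter-alphabet word pairs up
to length 3 with seeded longer samples, and 200-case randomised record
suites for the score invariants.

## Numerical and degenerate-input choices

* Ties in ranking break by total frequency, then lexicographically by
  form; ties between equally long rule matches break by rule file order.
  Both choices exist for reproducibility, which the determinism tests
  assert.
* An empty corpus yields an empty inventory, not an error; an empty rule
  file, an unknown category, or an agreement variable used only once is a
  compile-time error naming the rule.
* `top_k` larger than the candidate list warns and uses the whole list.
* Scores are exported with two decimals but compared at full precision in
  memory; all score arithmetic is double precision with no rounding.
* Foreign-word runs cap at three tokens; longer runs split.

## Known limitations

Coordination of noun phrases, prepositional-phrase terms and acronym
definition mining are out of scope by design. The simplified-form merges
listed above are irreversible at this layer. The NC step inherits the
weakness that in noun-phrase-only text most neighbours are punctuation,
so its corrections are small. The stop-word lists and the suffix table
are starting points meant to be edited per deployment, not linguistic
ground truth.
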