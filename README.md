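# clinterm

Automatic terminology extraction from morphologically tagged clinical text
in an inflectional language (Polish).

Clinical notes are written almost entirely in noun phrases and are full of
local vocabulary — *karta informacyjna leczenia szpitalnego*, *USG jamy
brzusznej*, *kość ramienna* — that no published dictionary covers.
`clinterm` turns a tagged corpus of such text into a ranked terminology
list:

1. **Candidate selection.** A six-level cascaded shallow grammar with
   case/gender/number unification recognises maximal nominal phrases
   (noun or acronym heads, agreeing adjectival modifiers, hyphenated
   compounds, genitive complement chains) and excludes spans opened by
   stop words (time expressions, introductory words). A `simplified` mode
   matches on part of speech alone.
2. **Normalisation and counting.** Phrases are identified by their
   *simplified base form* — the sequence of token lemmas — so inflected
   variants merge; every grammar-accepted sub-span of a phrase is counted
   as a nested occurrence of its own candidate, with its super-phrase and
   adjacent-word contexts.
3. **Ranking.** Candidates are scored by the C-value

   C(p) = l(p) · ( f(p) − (1/r) · Σ_{lp ∈ LP} f(lp) ),  r > 0
   (and l(p) · f(p) when r = 0), with l(p) = log₂|p| for multiword
   phrases and 0.1 for single words,

   where LP are the phrases containing p and r is the number of distinct
   context types. The default context counting is the **C₁** variant
   (maximum of distinct left-adjacent and right-adjacent words, counted
   separately), which zeroes truncated fragments that live inside a
   single super phrase. The **NC-value**
   `NC(t) = 0.8·C(t) + 0.2·Σ_b f_t(b)·weight(b)` re-ranks by one-word
   contexts shared with the top 300 terms.
4. **Comparisons.** Annotation against the same pipeline's output on a
   general-language reference corpus, and matching against a controlled
   vocabulary (exact / nested / approximate tiers, with suffix stripping
   and a position-weighted edit distance under which end-of-word
   differences cost less).

Because real clinical corpora are confidential, the package ships a
synthetic tagged-corpus generator whose templates carry hand-annotated
ground truth; the test suite proves the pipeline equal to that analytic
truth end to end.

## Worked example

```r
library(clinterm)

fx  <- generate_fixture(c(karta4 = 116, karta5 = 1, usg3 = 12,
                          ostry2 = 3, kosc3 = 5), seed = 42)
inv <- build_inventory(fx$corpus, compile_cascade())
inv
#> <clt_inventory: 21 term(s) from 137 sentence(s), 137 maximal phrase occurrence(s)>

scores <- nc_value(score_inventory(inv), inv)
ranked <- rank_terms(scores, by = "nc_value")
head(ranked[, c("rank", "form", "freq_standalone", "freq_nested",
                "c1_value", "nc_value")], 8)
#>   rank                                          form freq_standalone freq_nested c1_value nc_value
#> 1    1           karta informacyjny leczyć szpitalny             116           1  232.000  185.600
#> 2    2                             usg jama brzuszny              12           0   19.020   15.216
#> 3    3                            lewy kość ramienny               5           0    7.925    6.340
#> 4    4                                   ostry dyżur               3           0    3.000    2.400
#> 5    5 poprzedni karta informacyjny leczyć szpitalny               1           0    2.322    1.858
#> 6    6                                         karta               0         117    0.000    0.000
#> 7    7                            karta informacyjny               0         117    0.000    0.000
#> 8    8                     karta informacyjny leczyć               0         117    0.000    0.000
```

The 4-token card phrase heads the list: length weight log₂4 = 2 times its
117 occurrences, minus the mean super-phrase frequency over its single C₁
context type, gives C₁ = 232, and with no qualifying external context
words NC = 0.8 · 232 = 185.60. The fragments *karta*, *karta
informacyjna* and *karta informacyjna leczenia* occur 117 times each but
only ever inside that same phrase — one context type, never standalone —
so the C₁ zero rule correctly scores them 0, while *kość ramienna*-style
nested terms with genuine variety survive.

A command-line wrapper with `extract`, `rank`, `compare-ref`,
`match-thesaurus` and `gen-fixtures` subcommands is installed at
`system.file("cli", "clinterm.R", package = "clinterm")`:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "clinterm.R", package = "clinterm"))') \
    extract --corpus corpus.tsv --out inventory.tsv
```

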