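Package: clinterm
Title: Automatic Terminology Extraction from Tagged Clinical Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts multiword domain terminology from morphologically tagged
    corpora of inflectional-language (Polish) clinical text. Candidate noun
    phrases are recognised by a six-level cascaded shallow grammar with
    case/gender/number agreement, normalised to simplified base forms (lemma
    sequences), and counted together with all nested noun-phrase fragments.
    Terms are ranked by the C-value statistic, its C1 context-counting
    variant, and the NC-value re-ranking over shared one-word contexts.
    Includes comparison against a reference-corpus term list, approximate
    matching against a controlled vocabulary (suffix stemming plus
    position-weighted edit distance), and a synthetic tagged-corpus generator
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
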