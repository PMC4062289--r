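# Context-free token corrections: the first matching rule rewrites the token.
- match: {surface: "por."}
  set: {tag: "brev:pun:nw", lemma: "poradnia"}
- match: {surface: "por"}
  set: {tag: "brev:npun:nw", lemma: "poradnia"}
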