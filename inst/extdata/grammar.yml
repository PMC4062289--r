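# Six-level cascaded shallow grammar for Polish nominal phrases.
#
# Each rule rewrites a matched sequence of items (tokens or previously built
# categories) into a single item of category `lhs`. Item keys:
#   tok     - terminal: '|'-separated tag patterns; a pattern matches when its
#             colon-separated parts are all present in the token's tag and the
#             first part equals the token's word class
#   cat     - non-terminal: '|'-separated category codes
#   surface - literal surface form (special characters)
#   lemma   - literal lemma
#   stop    - name of a stop-lemma list the item's lemma must belong to
#   opt     - item may be skipped
#   vars    - agreement variables, any of C,G,N,C2,G2,N2; items sharing a
#             variable must carry compatible case/gender/number values
#   case/gender/number - fixed feature constraint
# `head` on a rule names the item (RHS position) whose morphological features
# the new item copies; default 1 (first matched item).
#
# Category inventory: N NC AJ AC CN NZ AZ A ADJP NB NG X.
# NZ/AZ mark stop-lemma nouns/modifiers; no rule consumes them, so they can
# never enter a phrase.  Maximal noun phrases are the X items left after
# level 6.
levels:
- level: 1
  rules:
  - {lhs: NZ, rhs: [{tok: subst, stop: nz}]}
  - {lhs: AZ, rhs: [{tok: "adj|ppas|adja", stop: az}]}
  - {lhs: "N",  rhs: [{tok: "subst|ger"}]}
  - {lhs: NC, rhs: [{tok: "foreign_subst|foreign"}, {tok: foreign, opt: true},
                    {tok: foreign, opt: true}]}
  - {lhs: NC, rhs: [{tok: "brev:npun:nw|brev:npun:nphr"}]}
  - {lhs: NC, rhs: [{tok: "brev:pun:nw|brev:pun:nphr"}, {surface: ".", opt: true}]}
  - {lhs: AJ, head: 2, rhs: [{tok: adv, opt: true}, {tok: "adj|ppas"}]}
  - {lhs: AC, rhs: [{tok: "brev:npun:adjw|brev:pun:adjw"}, {surface: ".", opt: true}]}
  - {lhs: CN, rhs: [{tok: conj, lemma: i}]}
- level: 2
  rules:
  - {lhs: A,  rhs: [{cat: AJ}, {tok: adv, opt: true}]}
  - {lhs: A,  head: 3, rhs: [{cat: AC}, {surface: "-"}, {cat: AJ}]}
  - {lhs: A,  head: 3, rhs: [{tok: adja}, {surface: "-"}, {cat: AJ}]}
  - {lhs: AC, rhs: [{cat: AC}, {surface: "-"}, {cat: AC}]}
  - {lhs: "N",  rhs: [{cat: "N", vars: "C,G,N"}, {cat: AJ, vars: "C,G,N"}]}
  - {lhs: "N",  rhs: [{cat: AJ, vars: "C,G,N"}, {cat: "N", vars: "C,G,N"}]}
- level: 3
  rules:
  - {lhs: ADJP, rhs: [{cat: A}]}
  - {lhs: ADJP, rhs: [{cat: A, vars: "C,G,N", opt: true}, {cat: A, vars: "C,G,N", opt: true},
                      {cat: A, vars: "C,G,N", opt: true}, {cat: A, vars: "C,G,N", opt: true},
                      {cat: CN}, {cat: A, vars: "C,G,N"}]}
  - {lhs: ADJP, rhs: [{cat: A, vars: "C,G,N", opt: true}, {cat: A, vars: "C,G,N", opt: true},
                      {cat: A, vars: "C,G,N", opt: true}, {cat: A, vars: "C,G,N"},
                      {cat: AC, opt: true}]}
- level: 4
  rules:
  - {lhs: NB, head: 2, rhs: [{cat: NC}, {cat: ADJP}]}
  - {lhs: NB, head: 2, rhs: [{cat: AC}, {cat: "N"}]}
  - {lhs: NB, rhs: [{cat: "N"}, {cat: AC}]}
  - {lhs: NB, rhs: [{cat: ADJP}, {cat: NC}]}
  - {lhs: NB, rhs: [{cat: ADJP, vars: "C,G,N", opt: true}, {cat: "N", vars: "C,G,N"},
                    {cat: ADJP, vars: "C,G,N", opt: true}]}
- level: 5
  rules:
  - {lhs: NG, rhs: [{cat: NB, case: gen, opt: true}, {cat: NB, case: gen, opt: true},
                    {cat: NB, case: gen, opt: true}, {cat: NB, case: gen, opt: true},
                    {cat: CN, opt: true}, {cat: NB, case: gen}]}
  - {lhs: NG, rhs: [{cat: NB}]}
- level: 6
  rules:
  - {lhs: X, rhs: [{cat: NG, vars: "C,G,N"}, {cat: NG, case: gen, opt: true},
                   {cat: ADJP, vars: "C,G,N", opt: true}]}
  - {lhs: X, rhs: [{cat: NC}, {cat: NG, case: gen, opt: true}]}
  - {lhs: X, flag: trailing_nc, rhs: [{cat: NG}, {cat: NC}]}
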