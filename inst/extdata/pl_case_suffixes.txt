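# Inflectional endings stripped before approximate thesaurus matching.
# Longest listed ending that still leaves the minimum stem length is removed.
iego
iemu
ego
emu
ych
ich
ymi
imi
ami
ach
owi
iej
ią
om
ów
em
ie
ej
ym
im
ii
a
e
i
o
u
y
ą
ę
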