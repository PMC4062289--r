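# Noun lemmas barred from term candidates (NZ): pronoun-like heads,
# introductory/intension words, general time and duration words, month and
# weekday names. One lemma per line; '#' starts a comment.
to
co
obręb
kierunek
cel
czas
możliwość
podstawa
ciąg
cecha
trakt
okres
moment
chwila
termin
data
dzień
doba
godzina
tydzień
miesiąc
rok
początek
koniec
styczeń
luty
marzec
kwiecień
maj
czerwiec
lipiec
sierpień
wrzesień
październik
listopad
grudzień
poniedziałek
wtorek
środa
czwartek
piątek
sobota
niedziela
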