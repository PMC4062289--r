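# Modifier lemmas barred from term candidates (AZ).
aktualny
daleki
gdy
pewien
wzgląd
ten
inny
sam
niektóry
wczesny
obecny
kolejny
następny
powyższy
dotychczasowy
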