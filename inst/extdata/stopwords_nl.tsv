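# Compact Dutch stopword list. Note: modifier words (negators/intensifiers)
# configured in the active lexicon are always exempt from stopword removal
# during tokenization, even if listed here.
de
het
een
en
van
ik
te
dat
die
in
is
op
aan
met
als
voor
er
maar
om
door
over
ze
zich
bij
ook
tot
je
mij
uit
der
daar
haar
naar
heb
hoe
heeft
hebben
deze
u
want
nog
zal
me
zij
nu
ge
gij
omdat
iets
worden
toch
al
waren
veel
meer
doen
toen
moet
ben
zonder
kan
hun
dus
alles
onder
ja
eens
hier
wie
werd
altijd
doch
wordt
wezen
kunnen
zijn
was
hij
wij
dan
zou
of
wat
mijn
men
dit
zo
kon
niets
uw
iemand
geweest
haar
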