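# German function words removed before stemming.
# One token per line; lines starting with '#' are comments.
aber
alle
allem
allen
aller
alles
als
also
am
an
andere
anderem
anderen
anderer
auch
auf
aus
bei
beim
bin
bis
bist
da
damit
dann
das
dass
dem
den
der
des
dessen
die
dies
diese
diesem
diesen
dieser
dieses
doch
dort
durch
ein
eine
einem
einen
einer
eines
er
es
ihr
ihre
im
in
ins
ist
ja
jede
jedem
jeden
jeder
jedes
für
gegen
kann
kein
keine
man
mehr
mein
mit
nach
nicht
noch
nun
nur
ob
oder
ohne
sehr
sein
seine
sich
sie
sind
so
über
um
und
uns
unter
vom
von
vor
war
waren
was
weil
wenn
werden
wie
wieder
wir
wird
wo
zu
zum
zur
zwischen
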