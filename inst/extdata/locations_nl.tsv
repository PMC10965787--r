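# Small gazetteer of Dutch place names for the de-identification pass.
# Illustrative only; extend for real use.
amsterdam
rotterdam
utrecht
eindhoven
groningen
tilburg
almere
breda
nijmegen
enschede
haarlem
arnhem
zaandam
amersfoort
apeldoorn
hoofddorp
maastricht
leiden
dordrecht
zoetermeer
zwolle
deventer
delft
alkmaar
leeuwarden
venlo
hilversum
hengelo
amstelveen
roosendaal
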