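# Demonstration Dutch polarity lexicon (illustrative only).
# word	polarity
goed	+1
fijn	+1
blij	+1
rustig	+1
sterk	+1
trots	+1
positief	+1
gelukkig	+1
tevreden	+1
hoopvol	+1
beter	+1
prettig	+1
gemotiveerd	+1
stabiel	+1
vooruitgang	+1
succes	+1
energie	+1
ontspannen	+1
vrolijk	+1
zelfverzekerd	+1
slecht	-1
somber	-1
angstig	-1
verdrietig	-1
boos	-1
moe	-1
onrustig	-1
negatief	-1
gespannen	-1
terugval	-1
paniek	-1
schuldig	-1
eenzaam	-1
hopeloos	-1
zwak	-1
pijn	-1
stress	-1
onzeker	-1
huilen	-1
wanhopig	-1
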