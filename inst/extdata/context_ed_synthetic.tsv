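# Synthetic stand-in for a context-specific eating-disorder word list:
# expressions (1-3 tokens) that carry sentiment in an ED treatment context
# but are typically absent from, or mis-signed in, general lexicons.
# expression	polarity	context
herstellijn	+1	ED
mooie herstellijn	+1	ED
ruimte innemen	+1	ED
meer voelen	+1	ED
eetmoment gelukt	+1	ED
sporten	-1	AN
compenseren	-1	AN
lijnen	-1	ED
overgeven	-1	BN
eetbui	-1	BED
lichaamsbeleving	-1	ED
emotieregulatie	-1	ED
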