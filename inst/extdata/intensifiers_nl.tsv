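# Dutch intensifiers (reinforcers): double the score of the following
# sentiment word.
heel
zeer
extreem
erg
enorm
ontzettend
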