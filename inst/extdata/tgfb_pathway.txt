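# Primary genes of the TGF-beta signalling pathway used as the
# demonstration pathway gene set: ligands, receptors, SMAD transducers
# and SAR1A.
TGFB2
TGFB3
TGFBR1
TGFBR2
SMAD2
SMAD3
SMAD4
SAR1A
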