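# member lexicons of the BCC gazetteer bundle
subtype.lst
diagnosis.lst
prognostic.lst
level.lst
margin.lst
site.lst
laterality.lst
axis.lst
units.lst
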