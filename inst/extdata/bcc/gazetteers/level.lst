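# level of invasion
dermis	level	dermis
papillary dermis	level	dermis
reticular dermis	level	dermis
subcutis	level	subcutis
subcutaneous fat	level	subcutis
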