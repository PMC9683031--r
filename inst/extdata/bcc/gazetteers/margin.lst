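# margin / completeness-of-excision vocabulary
completely excised	margin	complete
incompletely excised	margin	incomplete
excision complete	margin	complete
excision incomplete	margin	incomplete
excision appears complete	margin	complete
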