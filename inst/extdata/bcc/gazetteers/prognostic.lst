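# prognostic factors
perineural invasion	prognostic	perineural
lymphovascular invasion	prognostic	lymphovascular
ulceration	prognostic	ulceration
residual disease	prognostic	residual
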