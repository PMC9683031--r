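# BCC histological subtypes (WHO-derived)
nodular	subtype	nodular	C1266092
superficial	subtype	superficial	C1266090
infiltrative	subtype	infiltrative	C1266093
micronodular	subtype	micronodular	C1266094
morphoeic	subtype	morphoeic	C1266095
basosquamous	subtype	basosquamous	C1710537
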