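# anatomical sites
cheek	site	head
nose	site	head
ear	site	head
forehead	site	head
scalp	site	head
temple	site	head
chin	site	head
eyelid	site	head
lip	site	head
neck	site	neck
shoulder	site	trunk
back	site	trunk
chest	site	trunk
arm	site	limb
leg	site	limb
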