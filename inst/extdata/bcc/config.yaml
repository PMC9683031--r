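tokenizer:
  policy: general
sections:
  headers: default
resources:
  gazetteers: gazetteers/index.def
  rules: rules
  triggers: triggers/context.lst
  schema: schema.yaml
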