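# Remove raw Lookup annotations from the output; entities carry everything
# downstream consumers need.
phase:
  name: cleanup
  control: all
  input: [Lookup]
rules:
  - name: DropLookup
    priority: 0
    pattern:
      - {category: Lookup, bind: l}
    actions:
      - remove: l
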