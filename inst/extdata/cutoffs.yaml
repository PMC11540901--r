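c1: 32
c2: 21
fractions:
- 0.1
- 0.3
provenance: default
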