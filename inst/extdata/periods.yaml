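P0b:
- 1
- 14
P1b:
  weeks:
  - 5
  - 6
P2b:
  weeks:
  - 23
  - 24
week5:
  weeks:
  - 5
  - 5
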