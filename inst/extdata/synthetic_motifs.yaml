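motifs:
- start: 101
  end: 112
- start: 131
  end: 140
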