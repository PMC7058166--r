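species_specific:
- family: ORC4
  taxon: Cang
  min_dup: 1
- family: ORC4
  taxon: Amac
  min_dup: 1
forbidden_clades:
- family: ORC4
  clade_id: Amac..Cang
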