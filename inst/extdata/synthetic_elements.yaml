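# Sidecar metadata for synthetic_elements.fa (synthetic consensus stand-ins).
# Positions are 1-based on the element sequence, 5'->3'.
families:
  AluY:
    class: Alu
    length: 281
    diagnostic_sites: []
  AluYa5:
    class: Alu
    length: 281
    diagnostic_sites: [76, 119, 144, 196, 237]
  AluYb8:
    class: Alu
    length: 288
    # 8 diagnostic substitutions plus a 7-bp insertion after position 246
    diagnostic_sites: [64, 98, 151, 174, 201, 228, 251, 271]
    insertion_after: 246
    insertion_length: 7
  L1:
    class: L1
    length: 6021
    orf1_start: 910
    orf1_end: 1926
    orf2_start: 1992
    orf2_end: 5816
    # trinucleotide discriminating the young L1 subsets: ACA = Ta, ACG = pre-Ta
    ta_diagnostic_start: 5930
    ta_base: ACA
    preta_base: ACG
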