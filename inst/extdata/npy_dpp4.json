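{
  "enzyme_protein_id": "DPP4",
  "intact_sequence": "YPSKPDNPGEDAPAEDMAR",
  "cleaved_sequence": "SKPDNPGEDAPAEDMAR",
  "reference_sequence": "HYINLITRQR",
  "truncation_length": 2
}
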