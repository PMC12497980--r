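- drug: atezolizumab
  class: PD-L1 inhibitor
  synonyms: [Tecentriq]
- drug: durvalumab
  class: PD-L1 inhibitor
  synonyms: [Imfinzi]
- drug: avelumab
  class: PD-L1 inhibitor
  synonyms: [Bavencio]
- drug: tislelizumab
  class: PD-1 inhibitor
  synonyms: [Tevimbra, Baizean]
- drug: pembrolizumab
  class: PD-1 inhibitor
  synonyms: [Keytruda]
- drug: nivolumab
  class: PD-1 inhibitor
  synonyms: [Opdivo]
- drug: ipilimumab
  class: CTLA-4 inhibitor
  synonyms: [Yervoy]
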