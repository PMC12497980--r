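name: pancreatitis
pts:
  - Pancreatitis
  - Pancreatitis acute
  - Pancreatitis chronic
  - Immune-mediated pancreatitis
  - Autoimmune pancreatitis
  - Obstructive pancreatitis
  - Pancreatitis necrotising
  - Oedematous pancreatitis
  - Pancreatitis haemorrhagic
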