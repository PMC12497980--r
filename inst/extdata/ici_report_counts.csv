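drug,variable,category,count
atezolizumab,sex,missing,162
durvalumab,sex,missing,83
avelumab,sex,missing,15
tislelizumab,sex,missing,8
pembrolizumab,sex,missing,333
nivolumab,sex,missing,418
ipilimumab,sex,missing,147
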