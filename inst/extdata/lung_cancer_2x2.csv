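cell,exposure,outcome,count
a,never_smoked,other,8120
b,ever_smoked,other,4331
c,never_smoked,lung_cancer_death,36
d,ever_smoked,lung_cancer_death,177
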