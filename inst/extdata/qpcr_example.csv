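sample,group,ct_target,ct_reference
neg_1,CD25neg,28,20
neg_2,CD25neg,28.4,20.2
neg_3,CD25neg,27.6,19.8
low_1,CD25low,25,20
low_2,CD25low,25.6,20.2
low_3,CD25low,24.6,19.8
high_1,CD25high,22,20
high_2,CD25high,22.2,20.2
high_3,CD25high,21.8,19.8
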