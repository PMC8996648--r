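label,included_n,retrieved_n,sensitivity,specificity
Kamiya,12,120,100,46
Pinheiro,3,1314,100,37
Westby,16,784,31.25,70
Aldin,22,5562,100,35
Yang,13,565,100,44
Takagi,7,100,100,14
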