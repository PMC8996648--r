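label,events,total
Kamiya,12,12
Pinheiro,3,3
Westby,5,16
Aldin,22,22
Yang,13,13
Takagi,7,7
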