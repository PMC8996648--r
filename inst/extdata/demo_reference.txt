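2000001
2000002
2000003
2000004
2000005
2000006
2000007
2000008
2000009
2000010
2000011
2000012
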