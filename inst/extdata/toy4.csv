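a,b,c,class
0.12,0.41,0.61,Y
0.21,0.15,0.14,Y
0.31,0.11,0.26,N
0.61,0.13,0.23,N
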