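run,X1,X2,X3,response_pct
1,-1,-1,-1,7.14
2,1,-1,-1,5.03
3,-1,1,-1,22.61
4,1,1,-1,20.27
5,-1,-1,1,10.00
6,1,-1,1,10.07
7,-1,1,1,36.23
8,1,1,1,35.24
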