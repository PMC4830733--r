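run,X1,X2,X3,response_pct
1,-1,-1,-1,5.43
2,1,-1,-1,7.66
3,-1,1,-1,25.43
4,1,1,-1,27.69
5,-1,-1,1,11.69
6,1,-1,1,10.25
7,-1,1,1,32.51
8,1,1,1,36.42
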