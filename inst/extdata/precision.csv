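level,nominal_mg,day,replicate,found_mg
80%,10,1,1,10
80%,10,1,2,10.05
80%,10,1,3,10.03
80%,10,2,1,10.02
80%,10,2,2,10.03
80%,10,2,3,10.03
80%,10,3,1,10
80%,10,3,2,10.09
80%,10,3,3,10.04
100%,12.5,1,1,12.45
100%,12.5,1,2,12.42
100%,12.5,1,3,12.33
100%,12.5,2,1,12.42
100%,12.5,2,2,12.41
100%,12.5,2,3,12.49
100%,12.5,3,1,12.45
100%,12.5,3,2,12.42
100%,12.5,3,3,12.46
120%,15,1,1,14.09
120%,15,1,2,14.02
120%,15,1,3,14.06
120%,15,2,1,14.01
120%,15,2,2,14.03
120%,15,2,3,14.04
120%,15,3,1,14.032
120%,15,3,2,14.07
120%,15,3,3,14.09
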