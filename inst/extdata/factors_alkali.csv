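name,low,high,units
alkali_strength,0.01,0.1,mol/L
temperature,55,80,degC
time,15,30,min
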