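start,end,f_cl
1958,1965,0.003
1965,1975,0.004
1975,1985,0.005
1985,1995,0.005
1995,2006,0.007
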