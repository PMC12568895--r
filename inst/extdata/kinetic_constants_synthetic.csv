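"congener","k1","k2"
"2,3,7,8-TeCDF",22000,0.1
"OCDF",460000,0.1
"1,2,3,6,7,8-HxCDD",33000,0.1
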