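congener,scheme,tef
"2,3,7,8-TeCDD",WHO2005,1
"1,2,3,7,8-PeCDD",WHO2005,1
"1,2,3,4,7,8-HxCDD",WHO2005,0.1
"1,2,3,6,7,8-HxCDD",WHO2005,0.1
"1,2,3,7,8,9-HxCDD",WHO2005,0.1
"1,2,3,4,6,7,8-HpCDD",WHO2005,0.01
OCDD,WHO2005,0.0003
"2,3,7,8-TeCDF",WHO2005,0.1
"1,2,3,7,8-PeCDF",WHO2005,0.03
"2,3,4,7,8-PeCDF",WHO2005,0.3
"1,2,3,4,7,8-HxCDF",WHO2005,0.1
"1,2,3,6,7,8-HxCDF",WHO2005,0.1
"1,2,3,7,8,9-HxCDF",WHO2005,0.1
"2,3,4,6,7,8-HxCDF",WHO2005,0.1
"1,2,3,4,6,7,8-HpCDF",WHO2005,0.01
"1,2,3,4,7,8,9-HpCDF",WHO2005,0.01
OCDF,WHO2005,0.0003
"2,3,7,8-TeCDD",WHO2022,1
"1,2,3,7,8-PeCDD",WHO2022,0.4
"1,2,3,4,7,8-HxCDD",WHO2022,0.09
"1,2,3,6,7,8-HxCDD",WHO2022,0.09
"1,2,3,7,8,9-HxCDD",WHO2022,0.09
"1,2,3,4,6,7,8-HpCDD",WHO2022,0.01
OCDD,WHO2022,0.001
"2,3,7,8-TeCDF",WHO2022,0.05
"1,2,3,7,8-PeCDF",WHO2022,0.03
"2,3,4,7,8-PeCDF",WHO2022,0.2
"1,2,3,4,7,8-HxCDF",WHO2022,0.1
"1,2,3,6,7,8-HxCDF",WHO2022,0.1
"1,2,3,7,8,9-HxCDF",WHO2022,0.1
"2,3,4,6,7,8-HxCDF",WHO2022,0.1
"1,2,3,4,6,7,8-HpCDF",WHO2022,0.01
"1,2,3,4,7,8,9-HpCDF",WHO2022,0.01
OCDF,WHO2022,0.001
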