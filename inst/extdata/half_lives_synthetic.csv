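"congener","half_life_years"
"2,3,7,8-TeCDD",12
"1,2,3,7,8-PeCDD",17
"1,2,3,4,7,8-HxCDD",25
"1,2,3,6,7,8-HxCDD",25
"1,2,3,7,8,9-HxCDD",25
"1,2,3,4,6,7,8-HpCDD",35
"OCDD",50
"2,3,7,8-TeCDF",10
"1,2,3,7,8-PeCDF",15
"2,3,4,7,8-PeCDF",15
"1,2,3,4,7,8-HxCDF",22
"1,2,3,6,7,8-HxCDF",22
"1,2,3,7,8,9-HxCDF",22
"2,3,4,6,7,8-HxCDF",22
"1,2,3,4,6,7,8-HpCDF",30
"1,2,3,4,7,8,9-HpCDF",30
"OCDF",45
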