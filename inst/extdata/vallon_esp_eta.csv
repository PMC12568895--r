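"congener","phase","eta","units"
"2,3,7,8-TeCDD","gaseous",-173,"percent"
"1,2,3,7,8-PeCDD","gaseous",-479,"percent"
"1,2,3,4,7,8-HxCDD","gaseous",-631,"percent"
"1,2,3,6,7,8-HxCDD","gaseous",-857,"percent"
"1,2,3,7,8,9-HxCDD","gaseous",-610,"percent"
"1,2,3,4,6,7,8-HpCDD","gaseous",-719,"percent"
"OCDD","gaseous",-380,"percent"
"2,3,7,8-TeCDF","gaseous",-265,"percent"
"1,2,3,7,8-PeCDF","gaseous",-363,"percent"
"2,3,4,7,8-PeCDF","gaseous",-429,"percent"
"1,2,3,4,7,8-HxCDF","gaseous",-484,"percent"
"1,2,3,6,7,8-HxCDF","gaseous",-470,"percent"
"1,2,3,7,8,9-HxCDF","gaseous",-403,"percent"
"2,3,4,6,7,8-HxCDF","gaseous",-320,"percent"
"1,2,3,4,6,7,8-HpCDF","gaseous",-283,"percent"
"1,2,3,4,7,8,9-HpCDF","gaseous",-312,"percent"
"OCDF","gaseous",-180,"percent"
"2,3,7,8-TeCDD","particulate",54,"percent"
"1,2,3,7,8-PeCDD","particulate",1,"percent"
"1,2,3,4,7,8-HxCDD","particulate",-29,"percent"
"1,2,3,6,7,8-HxCDD","particulate",-71,"percent"
"1,2,3,7,8,9-HxCDD","particulate",-37,"percent"
"1,2,3,4,6,7,8-HpCDD","particulate",-46,"percent"
"OCDD","particulate",11,"percent"
"2,3,7,8-TeCDF","particulate",27,"percent"
"1,2,3,7,8-PeCDF","particulate",15,"percent"
"2,3,4,7,8-PeCDF","particulate",-11,"percent"
"1,2,3,4,7,8-HxCDF","particulate",0,"percent"
"1,2,3,6,7,8-HxCDF","particulate",-3,"percent"
"1,2,3,7,8,9-HxCDF","particulate",-17,"percent"
"2,3,4,6,7,8-HxCDF","particulate",-8,"percent"
"1,2,3,4,6,7,8-HpCDF","particulate",18,"percent"
"1,2,3,4,7,8,9-HpCDF","particulate",1,"percent"
"OCDF","particulate",29,"percent"
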